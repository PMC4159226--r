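# Signature-type diversity vs. group composition: Gaussian identity-link
# GAMs with penalized regression splines (mgcv), GCV smoothing selection
# and nested-model ANOVA comparison.

#' Per-encounter signature-type diversity table
#'
#' The response is the number of unique signature whistle types detected
#' per encounter; encounters with no signature whistles are retained with
#' a count of 0. Covariates (group size, calf presence, recording minutes)
#' are joined from the encounter metadata; encounters without metadata are
#' excluded with a warning.
#'
#' @param whistles list of classified `whistle` objects (copy removal does
#'   not change the distinct-type count, so either list works).
#' @param signature_types character vector of signature type ids.
#' @param encounters encounter metadata data.frame.
#' @return data.frame: `encounter_id`, `n_types`, `group_size`,
#'   `calves_present`, `recording_minutes`.
#' @export
build_diversity_table <- function(whistles, signature_types, encounters) {
  tab <- whistle_table(whistles)
  tab <- tab[!is.na(tab$type_label) & tab$type_label %in% signature_types, ,
             drop = FALSE]
  orphan <- setdiff(unique(tab$encounter_id), encounters$encounter_id)
  if (length(orphan)) {
    warnf("excluding whistles from %d encounter(s) without metadata: %s",
          length(orphan), paste(orphan, collapse = ", "))
    tab <- tab[!tab$encounter_id %in% orphan, , drop = FALSE]
  }
  counts <- tapply(tab$type_label, tab$encounter_id,
                   function(x) length(unique(x)))
  out <- data.frame(encounter_id = encounters$encounter_id,
                    n_types = as.integer(counts[encounters$encounter_id]),
                    group_size = encounters$group_size,
                    calves_present = as.logical(encounters$calves_present),
                    recording_minutes = encounters$recording_minutes,
                    stringsAsFactors = FALSE)
  out$n_types[is.na(out$n_types)] <- 0L
  out
}

diversity_formula <- function(model, k_gs, k_rec) {
  switch(as.character(model),
    "1" = n_types ~ group_size,
    "2" = substitute(n_types ~ s(group_size, bs = "cr", k = KG),
                     list(KG = k_gs)),
    "3" = substitute(n_types ~ calves_present + s(group_size, bs = "cr", k = KG),
                     list(KG = k_gs)),
    "4" = substitute(n_types ~ calves_present + s(group_size, bs = "cr", k = KG) +
                       s(recording_minutes, bs = "cr", k = KR),
                     list(KG = k_gs, KR = k_rec)),
    "5" = substitute(n_types ~ calves_present + s(group_size, bs = "cr", k = KG) +
                       s(gs_x_mins, bs = "cr", k = KR),
                     list(KG = k_gs, KR = k_rec)),
    "6" = substitute(n_types ~ calves_present + s(group_size, bs = "cr", k = KG) +
                       s(group_size, by = calves_f, bs = "cr", k = KG),
                     list(KG = k_gs)),
    stopf("unknown model tag %s (expected 1-6)", model))
}

#' Fit a signature-type diversity GAM
#'
#' Fits one of six candidate models of per-encounter signature-type
#' diversity with a Gaussian distribution and identity link, smooth terms
#' as penalized cubic regression splines and the smoothing parameter
#' chosen by generalised cross-validation:
#'
#' 1. `n_types ~ group_size` (linear)
#' 2. `~ s(group_size)`
#' 3. `~ calves_present + s(group_size)`
#' 4. `~ calves_present + s(group_size) + s(recording_minutes)`
#' 5. `~ calves_present + s(group_size) + s(group_size x recording_minutes)`
#' 6. `~ calves_present + s(group_size) + s(group_size, by = calves)`
#'
#' A Gaussian identity link on a count response is a deliberate fidelity
#' choice; `family = "poisson"` switches to a log-link Poisson alternative.
#'
#' @param data diversity table from [build_diversity_table()].
#' @param model integer 1-6 selecting the formula.
#' @param k spline basis dimension (default 10, reduced automatically when
#'   a covariate has too few unique values).
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return object of class `diversity_gam`: list with the `mgcv::gam`
#'   `fit`, `model`, `formula`, `aic`, `gcv`, `dev_expl`, `edf`.
#' @export
fit_gam <- function(data, model = 3, k = 10, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (nrow(data) < 10L) stopf("need at least 10 encounters to fit a GAM")
  for (v in c("group_size", "recording_minutes")) {
    if (length(unique(data[[v]])) < 2L)
      stopf("covariate %s is constant; model is rank deficient", v)
  }
  data$calves_f <- factor(data$calves_present, levels = c(FALSE, TRUE))
  data$gs_x_mins <- data$group_size * data$recording_minutes
  cap <- function(v) max(3L, min(as.integer(k), length(unique(v)) - 1L))
  form <- stats::as.formula(diversity_formula(model,
                                              cap(data$group_size),
                                              cap(data$recording_minutes)))
  fam <- if (family == "gaussian") stats::gaussian()
         else stats::poisson(link = "log")
  fit <- mgcv::gam(form, data = data, family = fam, method = "GCV.Cp")
  sm <- summary(fit)
  structure(list(fit = fit, model = model, formula = form,
                 aic = stats::AIC(fit),
                 gcv = as.numeric(fit$gcv.ubre),
                 dev_expl = as.numeric(sm$dev.expl),
                 edf = if (length(fit$smooth)) sm$edf else numeric(0),
                 data = data),
            class = "diversity_gam")
}

#' @export
print.diversity_gam <- function(x, ...) {
  cat(sprintf("<diversity_gam model %s> AIC %.3f | GCV %.3f | deviance explained %.1f%%\n",
              x$model, x$aic, x$gcv, 100 * x$dev_expl))
  invisible(x)
}

#' Evaluate a fitted smooth with its 95\% confidence band
#'
#' Returns the centred smooth-term contribution for a covariate over a
#' grid, with pointwise 95\% confidence limits - the response-curve data
#' behind the usual diversity-vs-group-size plot.
#'
#' @param fit a `diversity_gam`.
#' @param term covariate name of the smooth (default `"group_size"`).
#' @param grid evaluation points (default: 100 points over the observed
#'   range).
#' @return data.frame: `x`, `est`, `se`, `lo`, `hi`.
#' @export
evaluate_smooth <- function(fit, term = "group_size", grid = NULL) {
  data <- fit$data
  grid <- grid %||% seq(min(data[[term]]), max(data[[term]]),
                        length.out = 100)
  nd <- data.frame(group_size = stats::median(data$group_size),
                   recording_minutes = stats::median(data$recording_minutes),
                   calves_f = factor(FALSE, levels = c(FALSE, TRUE)),
                   calves_present = FALSE)
  nd <- nd[rep(1L, length(grid)), , drop = FALSE]
  nd[[term]] <- grid
  nd$gs_x_mins <- nd$group_size * nd$recording_minutes
  pr <- stats::predict(fit$fit, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep(paste0("s\\(", term, "\\)"), colnames(pr$fit))
  if (length(col) != 1L)
    stopf("no unique smooth term for %s in model %s", term, fit$model)
  est <- pr$fit[, col]; se <- pr$se.fit[, col]
  data.frame(x = grid, est = est, se = se,
             lo = est - 1.96 * se, hi = est + 1.96 * se)
}

# covariates entering a fit, with smooth wrappers stripped: a linear term
# is treated as nested within a smooth of the same covariate
model_vars <- function(x) {
  labs <- attr(stats::terms(x$formula), "term.labels")
  unique(unlist(lapply(labs, function(l) all.vars(str2lang(l)))))
}

#' Compare candidate diversity GAMs
#'
#' Ranks fits by AIC and GCV and, for the requested nested pairs, runs the
#' standard nested-GAM analysis of deviance (F-test on the change in
#' residual deviance over the change in effective degrees of freedom).
#' Non-nested pairs are refused an F-test and compared by AIC only.
#'
#' @param fits list of `diversity_gam` objects.
#' @param pairs list of length-2 integer vectors indexing `fits`
#'   (smaller model first); default compares consecutive fits.
#' @return list with `ranking` (data.frame: model, aic, gcv, dev_expl,
#'   best flag) and `tests` (data.frame: pair, F, p, nested).
#' @export
compare_models <- function(fits, pairs = NULL) {
  ranking <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, aic = f$aic, gcv = f$gcv,
               dev_expl = f$dev_expl, stringsAsFactors = FALSE)))
  ranking$best <- seq_len(nrow(ranking)) == which.min(ranking$aic)
  pairs <- pairs %||% lapply(seq_len(length(fits) - 1L),
                             function(i) c(i, i + 1L))
  tests <- lapply(pairs, function(p) {
    small <- fits[[p[1L]]]; big <- fits[[p[2L]]]
    nested <- all(model_vars(small) %in% model_vars(big))
    if (!nested) {
      return(data.frame(model_small = small$model, model_big = big$model,
                        nested = FALSE, F = NA_real_, p = NA_real_,
                        delta_aic = big$aic - small$aic,
                        stringsAsFactors = FALSE))
    }
    a <- stats::anova(small$fit, big$fit, test = "F")
    data.frame(model_small = small$model, model_big = big$model,
               nested = TRUE,
               F = a$F[2L] %||% NA_real_, p = a$`Pr(>F)`[2L] %||% NA_real_,
               delta_aic = big$aic - small$aic, stringsAsFactors = FALSE)
  })
  list(ranking = ranking, tests = do.call(rbind, tests))
}
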