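# Inter-observer agreement for the visual classification task: Fleiss'
# kappa with its large-sample Z statistic, stage-1/stage-2 consistency and
# agreement against reference labels.

#' Fleiss' kappa for multi-rater nominal agreement
#'
#' Chance-corrected agreement for `m` raters assigning `N` items to
#' nominal categories: kappa = (P_bar - P_bar_e) / (1 - P_bar_e), where
#' P_bar is the mean per-item pairwise agreement and P_bar_e the chance
#' agreement from the marginal category proportions. The Z statistic uses
#' the Fleiss (1971) large-sample variance of the estimator under the null
#' of chance agreement, with a two-sided normal p-value.
#'
#' An ordinal-weighted variant (linear weights on category distance) is
#' available via `weights = "linear"`, useful when the categories are a
#' graded similarity scale; the nominal statistic is the default.
#'
#' @param assignments matrix of category labels, items in rows and judges
#'   in columns (complete: no missing cells).
#' @param categories optional category universe; defaults to the observed
#'   labels.
#' @param weights `"nominal"` (default) or `"linear"`.
#' @return object of class `kappa_result`: list with `kappa`, `z`, `p`,
#'   `n_items`, `n_judges`, `n_categories`, `weights`, `degenerate`.
#' @examples
#' m <- matrix("A", nrow = 10, ncol = 3)
#' m[1, 1] <- "B"
#' fleiss_kappa(m, categories = c("A", "B"))
#' @export
fleiss_kappa <- function(assignments, categories = NULL,
                         weights = c("nominal", "linear")) {
  weights <- match.arg(weights)
  assignments <- as.matrix(assignments)
  if (anyNA(assignments)) stopf("rating table has missing cells")
  N <- nrow(assignments); m <- ncol(assignments)
  if (N < 1L || m < 2L) stopf("need at least 1 item and 2 judges")
  categories <- categories %||% sort(unique(as.vector(assignments)))
  k <- length(categories)
  counts <- t(apply(assignments, 1L, function(r)
    tabulate(match(r, categories), nbins = k)))
  if (k == 1L) counts <- matrix(counts, nrow = N)
  if (any(rowSums(counts) != m))
    stopf("assignments outside the supplied category set")
  p_j <- colSums(counts) / (N * m)
  if (weights == "nominal") {
    P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
    P_bar <- mean(P_i)
    P_e <- sum(p_j^2)
  } else {
    # linear weights on category rank distance, pairwise between raters
    wmat <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    P_i <- vapply(seq_len(N), function(i) {
      cnt <- counts[i, ]
      tot <- sum(cnt %o% cnt * wmat) - m   # subtract self-pairs (weight 1)
      tot / (m * (m - 1))
    }, numeric(1))
    P_bar <- mean(P_i)
    P_e <- sum((p_j %o% p_j) * wmat)
  }
  degenerate <- (1 - P_e) < .Machine$double.eps^0.5
  if (degenerate) {
    return(structure(list(kappa = NA_real_, z = NA_real_, p = NA_real_,
                          n_items = N, n_judges = m, n_categories = k,
                          weights = weights, degenerate = TRUE),
                     class = "kappa_result"))
  }
  kap <- (P_bar - P_e) / (1 - P_e)
  if (weights == "nominal") {
    # Fleiss (1971) large-sample SE under the null
    se <- sqrt(2 / (N * m * (m - 1))) *
      sqrt(P_e - (2 * m - 3) * P_e^2 + 2 * (m - 2) * sum(p_j^3)) / (1 - P_e)
    z <- kap / se
  } else {
    z <- NA_real_   # the Fleiss variance applies to the nominal statistic
  }
  structure(list(kappa = kap, z = z, p = 2 * stats::pnorm(-abs(z)),
                 n_items = N, n_judges = m, n_categories = k,
                 weights = weights, degenerate = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Fleiss' kappa: degenerate (all ratings in one category)\n")
  } else {
    cat(sprintf("Fleiss' kappa = %.3f, Z = %.1f, p %s (n judges = %d, n items = %d, %d categories%s)\n",
                x$kappa, x$z,
                if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p),
                x$n_judges, x$n_items, x$n_categories,
                if (x$weights == "linear") ", linear weights" else ""))
  }
  invisible(x)
}

#' Kappa on the two stages of a rating task
#'
#' `kappa_stage2` scores the forced-choice template assignments; each item
#' is one rated whistle. `kappa_stage1` treats every (item, template)
#' similarity rating as one item with the 1-5 scale as five nominal
#' categories, as the plain Fleiss statistic requires.
#'
#' @param rt a `rating_tensor` (from [generate_rating_task()] or
#'   [read_rating_task()]).
#' @param exclude_judges judge ids to drop (e.g. an author judge).
#' @param weights passed to [fleiss_kappa()].
#' @return a `kappa_result`.
#' @export
kappa_stage2 <- function(rt, exclude_judges = NULL, weights = "nominal") {
  keep <- setdiff(rt$judges, exclude_judges)
  fleiss_kappa(rt$stage2[, keep, drop = FALSE],
               categories = rt$templates, weights = weights)
}

#' @rdname kappa_stage2
#' @export
kappa_stage1 <- function(rt, exclude_judges = NULL, weights = "nominal") {
  keep <- which(rt$judges %in% setdiff(rt$judges, exclude_judges))
  a <- rt$stage1[keep, , , drop = FALSE]
  # (item, template) pairs in rows, judges in columns
  flat <- matrix(aperm(a, c(2, 3, 1)), ncol = length(keep))
  fleiss_kappa(flat, categories = 1:5, weights = weights)
}

#' Stage-1 to stage-2 consistency rate
#'
#' Fraction of (judge, item) pairs whose forced-choice assignment is among
#' that pair's highest (or joint-highest) stage-1 similarity ratings.
#' Missing stage-2 cells are excluded and counted.
#'
#' @param rt a `rating_tensor` with both stages.
#' @return list with `rate`, `n`, `n_consistent`, `n_missing`.
#' @export
consistency_rate <- function(rt) {
  n_j <- length(rt$judges); n_i <- length(rt$items)
  consistent <- 0L; total <- 0L; missing <- 0L
  for (j in seq_len(n_j)) {
    for (i in seq_len(n_i)) {
      pick <- rt$stage2[i, j]
      if (is.na(pick)) { missing <- missing + 1L; next }
      ratings <- rt$stage1[j, i, ]
      total <- total + 1L
      if (ratings[match(pick, rt$templates)] == max(ratings))
        consistent <- consistent + 1L
    }
  }
  list(rate = if (total) consistent / total else NA_real_,
       n = total, n_consistent = consistent, n_missing = missing)
}

#' Agreement of judge assignments with reference labels
#'
#' Fraction of stage-2 assignments matching the reference (e.g. the
#' catalogue author's) label, with a per-category disagreement breakdown
#' flagging the most-confused type.
#'
#' @param stage2 matrix of assignments, items in rows, judges in columns.
#' @param reference character vector of reference labels, one per item.
#' @return list with `rate`, `n`, `disagreements` (counts by reference
#'   category) and `most_confused` (reference category causing the largest
#'   share of disagreements, with its share).
#' @export
author_agreement <- function(stage2, reference) {
  stage2 <- as.matrix(stage2)
  if (length(reference) != nrow(stage2))
    stopf("reference labels must cover all %d items", nrow(stage2))
  match_mat <- stage2 == matrix(reference, nrow = nrow(stage2),
                                ncol = ncol(stage2))
  dis <- tapply(rowSums(!match_mat), reference, sum)
  dis <- dis[dis > 0]
  most <- if (length(dis)) names(which.max(dis)) else NA_character_
  list(rate = mean(match_mat),
       n = length(match_mat),
       disagreements = dis,
       most_confused = most,
       most_confused_share = if (length(dis)) max(dis) / sum(dis)
                             else NA_real_)
}
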