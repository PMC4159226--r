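# Published reference summaries for the Walvis Bay bottlenose dolphin
# population, shipped as plain-text tables so the catalogue- and
# parameter-summary operations can be exercised on real printed values.

#' Walvis Bay signature whistle catalogue summary
#'
#' The published occurrence summary of the 28 signature whistle types
#' identified in the Walvis Bay bottlenose dolphin population (2009-2013
#' field seasons): per-type category size after copy removal, number of
#' days the type appeared exactly once, encounter count (encounters and
#' days coincide for these data), years and sites of occurrence, and the
#' loop-structure split (single element / connected multi-loop /
#' disconnected multi-loop, integer percent of category size). Feed to
#' [summarize_catalogue()] for the catalogue-level statistics.
#'
#' @return data.frame with 28 rows and the catalogue columns.
#' @examples
#' summarize_catalogue(walvis_catalogue())$total_whistles
#' @export
walvis_catalogue <- function() {
  read_catalogue(system.file("extdata", "walvis_bay_catalogue.tsv",
                             package = "sigwhistle", mustWork = TRUE))
}

#' Walvis Bay per-type acoustic parameter summary
#'
#' The published per-type acoustic parameter panel for the 20 Walvis Bay
#' signature whistle types produced in sequences of 4 or more high-quality
#' whistles: per-type sample size and mean/SD of start, end, minimum,
#' maximum and peak frequency (kHz), frequency range (kHz), start/end
#' slope aspect, duration (s) and inflection count. Feed to
#' [summarize_parameters()] for the population summary; CVs are
#' recomputed from mean and SD.
#'
#' @return data.frame with 20 rows in the [measure_type_parameters()]
#'   layout.
#' @export
walvis_type_parameters <- function() {
  path <- system.file("extdata", "walvis_bay_type_parameters.tsv",
                      package = "sigwhistle", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(type_id = "character"))
}
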