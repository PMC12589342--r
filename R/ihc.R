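# Semiquantitative IHC composite scoring for RUNX3 with Pos/Neg grouping.
#
# Two components are rated on 0-2 point scales and summed into a 0-4 composite:
#   * percent positively stained cells:  <10% -> 0; 10-50% -> 1; >50% -> 2
#   * staining intensity: none/weak -> 0; moderate -> 1; strong -> 2
# Specimens with composite 0-2 form the RUNX3_Neg group, 3-4 the RUNX3_Pos
# group. Both interval endpoints of the 10-50% bin score 1 point.

IHC_INTENSITY_LEVELS <- c("none", "weak", "moderate", "strong")

#' Rate the percentage of positively stained cells
#'
#' Converts a percent-positive value in `[0, 100]` into 0-2 rating points:
#' below 10% scores 0, 10% up to and including 50% scores 1, and above 50%
#' scores 2.
#'
#' @param percent_positive Numeric vector of percentages in `[0, 100]`.
#' @return Integer vector of points in `{0, 1, 2}`.
#' @examples
#' rate_percentage(c(8, 50, 75))
#' @export
rate_percentage <- function(percent_positive) {
  .assert(is.numeric(percent_positive) && length(percent_positive) > 0 &&
            !anyNA(percent_positive),
          "percent_positive must be numeric and non-missing")
  .assert(all(percent_positive >= 0 & percent_positive <= 100),
          "percent_positive must lie in [0, 100]")
  ifelse(percent_positive < 10, 0L,
         ifelse(percent_positive <= 50, 1L, 2L))
}

#' Rate staining intensity
#'
#' Converts a categorical staining intensity into 0-2 rating points: no or weak
#' staining (light yellow) scores 0, moderate staining (yellow-brown) scores 1,
#' strong staining (brown) scores 2.
#'
#' @param intensity Character vector with values among
#'   `c("none", "weak", "moderate", "strong")`.
#' @return Integer vector of points in `{0, 1, 2}`.
#' @examples
#' rate_intensity(c("weak", "moderate", "strong"))
#' @export
rate_intensity <- function(intensity) {
  .assert(is.character(intensity) && length(intensity) > 0 && !anyNA(intensity),
          "intensity must be a character vector without missing values")
  bad <- setdiff(unique(intensity), IHC_INTENSITY_LEVELS)
  .assert(length(bad) == 0,
          sprintf("unknown intensity label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(IHC_INTENSITY_LEVELS, collapse = ", ")))
  unname(c(none = 0L, weak = 0L, moderate = 1L, strong = 2L)[intensity])
}

#' Score specimens and assign RUNX3 expression groups
#'
#' Completes a specimen table with component points, the 0-4 composite score,
#' and the RUNX3_Neg (composite 0-2) / RUNX3_Pos (composite 3-4) group label.
#'
#' @param specimens Data frame with columns `specimen_id`, `percent_positive`
#'   and `intensity`.
#' @return The input with added integer columns `percent_points`,
#'   `intensity_points`, `overall_score`, and character column `group`.
#' @examples
#' score_and_group(data.frame(specimen_id = "P1",
#'                            percent_positive = 60, intensity = "strong"))
#' @export
score_and_group <- function(specimens) {
  .assert(is.data.frame(specimens) && nrow(specimens) > 0,
          "specimens must be a non-empty data frame")
  .assert(all(c("specimen_id", "percent_positive", "intensity") %in%
                names(specimens)),
          "specimens needs columns specimen_id, percent_positive, intensity")
  out <- specimens
  out$percent_points <- vapply(seq_len(nrow(out)), function(i) {
    tryCatch(rate_percentage(out$percent_positive[[i]]),
             tmeatlas_error = function(e) .stop_tme(sprintf(
               "specimen %s: %s", out$specimen_id[[i]], conditionMessage(e))))
  }, integer(1))
  out$intensity_points <- vapply(seq_len(nrow(out)), function(i) {
    tryCatch(rate_intensity(as.character(out$intensity[[i]])),
             tmeatlas_error = function(e) .stop_tme(sprintf(
               "specimen %s: %s", out$specimen_id[[i]], conditionMessage(e))))
  }, integer(1))
  out$overall_score <- out$percent_points + out$intensity_points
  out$group <- ifelse(out$overall_score <= 2L, "RUNX3_Neg", "RUNX3_Pos")
  out
}

#' Read and write specimen tables
#'
#' Tab-separated with a header; `write_ihc()` writes the completed table
#' produced by [score_and_group()].
#'
#' @param path File path.
#' @param specimens Completed specimen data frame.
#' @return `read_ihc()` returns a data frame.
#' @export
read_ihc <- function(path) {
  .assert(file.exists(path), sprintf("IHC table not found: %s", path))
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_ihc
#' @export
write_ihc <- function(specimens, path) {
  write_tsv_strict(specimens, path)
  invisible(path)
}
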