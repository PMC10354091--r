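#' Normalize a reporter signal to percent activity
#'
#' Luminescence reporter readings are normalized between the cell-blank
#' background (0 percent) and the vehicle (DMSO) control (100 percent):
#' \code{((signal - blank_mean) / (dmso_mean - blank_mean)) * 100}.
#'
#' @param signal Raw luminescence reading(s).
#' @param dmso_mean Mean signal of the DMSO vehicle-control wells.
#' @param blank_mean Mean signal of the cell-blank wells.
#' @return Percent activity (vectorized over \code{signal}).
#' @export
percent_irf <- function(signal, dmso_mean, blank_mean) {
  if (!(dmso_mean > blank_mean)) {
    rlang::abort("normalization undefined: DMSO mean must exceed blank mean",
                 class = "competeMS_norm_error")
  }
  (signal - blank_mean) / (dmso_mean - blank_mean) * 100
}

#' Construct and validate a reporter plate
#'
#' @param df Data frame with columns \code{well}, \code{treatment},
#'   \code{dose_uM}, \code{signal}. Vehicle-control wells carry
#'   \code{treatment == dmso_label}; cell blanks carry
#'   \code{treatment == blank_label}.
#' @param dmso_label,blank_label Treatment tokens designating the DMSO
#'   control and cell-blank wells.
#' @return A \code{reporter_plate} tibble with reference means attached.
#' @export
reporter_plate <- function(df, dmso_label = "DMSO", blank_label = "blank") {
  df <- tibble::as_tibble(df)
  required <- c("well", "treatment", "dose_uM", "signal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("plate is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "competeMS_parse_error")
  }
  if (any(df$signal < 0)) {
    rlang::abort("luminescence signals must be nonnegative",
                 class = "competeMS_parse_error")
  }
  dmso <- df$signal[df$treatment == dmso_label]
  blank <- df$signal[df$treatment == blank_label]
  if (length(dmso) == 0 || length(blank) == 0) {
    rlang::abort(sprintf("plate needs >= 1 %s well and >= 1 %s well",
                         dmso_label, blank_label),
                 class = "competeMS_norm_error")
  }
  dmso_mean <- mean(dmso); blank_mean <- mean(blank)
  if (!(dmso_mean > blank_mean)) {
    rlang::abort("normalization undefined: DMSO mean must exceed blank mean",
                 class = "competeMS_norm_error")
  }
  structure(df, dmso_label = dmso_label, blank_label = blank_label,
            dmso_mean = dmso_mean, blank_mean = blank_mean,
            class = c("reporter_plate", class(df)))
}

#' Read a reporter plate from a tab-separated file
#' @param path File with header columns \code{well}, \code{treatment},
#'   \code{dose_uM}, \code{signal}.
#' @inheritParams reporter_plate
#' @return A \code{\link{reporter_plate}}.
#' @export
read_plate <- function(path, dmso_label = "DMSO", blank_label = "blank") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  reporter_plate(df, dmso_label = dmso_label, blank_label = blank_label)
}

#' Summarize percent activity per treatment and dose
#'
#' Applies \code{\link{percent_irf}} to every non-blank well and reports,
#' per (treatment, dose), the mean percent activity, the replicate count
#' and the sample range (max - min). Doses are reported in ascending
#' order within treatment.
#'
#' @param plate A \code{\link{reporter_plate}}.
#' @return Tibble with columns \code{treatment}, \code{dose_uM},
#'   \code{mean_percent}, \code{n}, \code{range_percent}.
#' @export
summarize_doses <- function(plate) {
  stopifnot(inherits(plate, "reporter_plate"))
  blank_label <- attr(plate, "blank_label")
  dm <- attr(plate, "dmso_mean"); bm <- attr(plate, "blank_mean")
  wells <- plate[plate$treatment != blank_label, , drop = FALSE]
  wells$percent <- percent_irf(wells$signal, dm, bm)
  out <- wells |>
    dplyr::group_by(.data$treatment, .data$dose_uM) |>
    dplyr::summarise(mean_percent = mean(.data$percent),
                     n = dplyr::n(),
                     range_percent = max(.data$percent) - min(.data$percent),
                     .groups = "drop") |>
    dplyr::arrange(.data$treatment, .data$dose_uM)
  out
}
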