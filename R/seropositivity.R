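#' Calibrate per-antigen seropositivity cutoffs on healthy donors
#'
#' The cutoff for each antigen is the empirical quantile of healthy-donor
#' values at the target specificity, using the inverted-empirical-CDF
#' convention (quantile type 1): the fraction of healthy training values
#' strictly above the cutoff never exceeds `1 - specificity`. With
#' `specificity = 1` the cutoff is the healthy maximum.
#'
#' @param healthy Signal table restricted to healthy donors (normalized or
#'   raw; the same representation must be used when calling).
#' @param specificity Target specificity in (0.5, 1]; default 0.99.
#' @param min_donors Minimum number of healthy donors required.
#' @return A `sero_cutoffs` tibble (`antigen`, `cutoff`) with attributes
#'   `specificity` and `n_reference`.
#' @export
fit_cutoffs <- function(healthy, specificity = 0.99, min_donors = 20) {
  healthy <- check_signal_table(healthy, allow_negative = TRUE)
  if (length(specificity) != 1L || !is.finite(specificity) ||
      specificity <= 0.5 || specificity > 1) {
    abort("`specificity` must lie in (0.5, 1]")
  }
  if (nrow(healthy) < min_donors) {
    abort(paste0("need at least ", min_donors, " healthy donors, got ",
                 nrow(healthy)))
  }
  m <- signal_matrix(healthy)
  cuts <- apply(m, 2, quantile, probs = specificity, type = 1, names = FALSE)
  out <- tibble::tibble(antigen = colnames(m), cutoff = unname(cuts))
  class(out) <- c("sero_cutoffs", class(out))
  attr(out, "specificity") <- specificity
  attr(out, "n_reference") <- nrow(healthy)
  attr(out, "reference_samples") <- healthy$sample
  out
}

#' Call binary seropositivity from signals and calibrated cutoffs
#'
#' A sample is called positive for an antigen iff its signal is strictly
#' greater than the antigen's cutoff; ties at the cutoff stay negative.
#'
#' @param signals Signal table (same representation the cutoffs were fit on).
#' @param cutoffs A `sero_cutoffs` table covering every antigen in `signals`.
#' @return Wide 0/1 call table with a `cutoffs` provenance attribute.
#' @export
call_positivity <- function(signals, cutoffs) {
  signals <- check_signal_table(signals, allow_negative = TRUE)
  stopifnot(is.data.frame(cutoffs), all(c("antigen", "cutoff") %in% names(cutoffs)))
  ags <- antigen_ids(signals)
  miss <- first_missing(ags, cutoffs$antigen)
  if (!is.null(miss)) abort(paste0("no cutoff for antigen: ", miss))
  m <- signal_matrix(signals)
  cut <- setNames(cutoffs$cutoff, cutoffs$antigen)[colnames(m)]
  calls <- 1L * sweep(m, 2, cut, ">")
  out <- signals_from_matrix(calls)
  attr(out, "cutoffs") <- cutoffs
  out
}

prevalence_band <- function(pct) {
  # left-closed bands: [0,5), [5,10), [10,100]
  cut(pct, breaks = c(-Inf, 5, 10, Inf), labels = c("<5%", "5-10%", ">10%"),
      right = FALSE)
}

#' Tabulate seropositivity prevalence per antigen and cohort group
#'
#' Computes per antigen x group the seropositive fraction and assigns the
#' prevalence band used for atlas shading: `<5%`, `5-10%`, `>10%`
#' (left-closed boundaries).
#'
#' @param calls Wide 0/1 call table.
#' @param annotation Sample annotation with `sample` and `group` columns.
#' @return A `sero_prevalence` tibble: `antigen`, `group`, `n`, `n_pos`,
#'   `prevalence_pct`, `band`.
#' @export
prevalence_table <- function(calls, annotation) {
  calls <- check_signal_table(calls, binary = TRUE)
  stopifnot(all(c("sample", "group") %in% names(annotation)))
  miss <- first_missing(calls$sample, annotation$sample)
  if (!is.null(miss)) abort(paste0("sample without group annotation: ", miss))
  long <- tidyr::pivot_longer(calls, -"sample", names_to = "antigen",
                              values_to = "call")
  long <- dplyr::left_join(long, annotation[, c("sample", "group")], by = "sample")
  out <- long |>
    dplyr::group_by(.data$antigen, .data$group) |>
    dplyr::summarise(n = dplyr::n(), n_pos = sum(.data$call), .groups = "drop") |>
    dplyr::mutate(prevalence_pct = 100 * .data$n_pos / .data$n,
                  band = prevalence_band(.data$prevalence_pct))
  class(out) <- c("sero_prevalence", class(out))
  out
}
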