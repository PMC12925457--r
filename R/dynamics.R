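#' Autoantibody repertoire diversity per sample
#'
#' Counts how many antigens each sample is seropositive for (row sums of the
#' call matrix). Group contrasts of these counts (e.g. end-stage vs early
#' disease) reuse the Mann-Whitney machinery of the association atlas.
#'
#' @param calls Wide 0/1 call table.
#' @return Tibble (`sample`, `n_reactive`).
#' @export
diversity_count <- function(calls) {
  calls <- check_signal_table(calls, binary = TRUE)
  m <- signal_matrix(calls)
  tibble::tibble(sample = calls$sample, n_reactive = unname(rowSums(m)))
}

conversion_levels <- c("seropositive-conversion", "seronegative-conversion",
                       "stable-positive", "stable-negative")

#' Classify seroconversion between two paired call matrices
#'
#' For every patient x antigen pair with calls at both timepoints, assigns
#' one of four categories: 0 to 1 is a seropositive conversion, 1 to 0 a
#' seronegative conversion, 1 to 1 stable positive and 0 to 0 stable
#' negative. The first timepoint must precede the second (caller's
#' contract); patients and antigens are matched by id.
#'
#' @param calls_t0,calls_t1 Wide 0/1 call tables with identical patients
#'   (rows, matched on the `sample` column) and antigens.
#' @return A `sero_conversions` tibble (`patient`, `antigen`, `category`)
#'   with `category` a factor over the four categories.
#' @export
classify_conversion <- function(calls_t0, calls_t1) {
  calls_t0 <- check_signal_table(calls_t0, binary = TRUE)
  calls_t1 <- check_signal_table(calls_t1, binary = TRUE)
  miss <- first_missing(calls_t0$sample, calls_t1$sample) %||%
    first_missing(calls_t1$sample, calls_t0$sample)
  if (!is.null(miss)) abort(paste0("unmatched patient: ", miss))
  miss <- first_missing(antigen_ids(calls_t0), antigen_ids(calls_t1)) %||%
    first_missing(antigen_ids(calls_t1), antigen_ids(calls_t0))
  if (!is.null(miss)) abort(paste0("unmatched antigen: ", miss))
  m0 <- signal_matrix(calls_t0)
  m1 <- signal_matrix(calls_t1)[rownames(m0), colnames(m0), drop = FALSE]
  code <- 2L * m0 + m1          # 00->0, 01->1, 10->2, 11->3
  cat <- c("stable-negative", "seropositive-conversion",
           "seronegative-conversion", "stable-positive")[code + 1L]
  out <- tibble::tibble(
    patient = rep(rownames(m0), times = ncol(m0)),
    antigen = rep(colnames(m0), each = nrow(m0)),
    category = factor(cat, levels = conversion_levels))
  class(out) <- c("sero_conversions", class(out))
  out
}

#' Summarize seroconversion records
#'
#' Reports the fraction of patients with at least one seropositive
#' conversion, category proportions over all patient x antigen slots and
#' over positive-involved slots only (slots that are stable negative carry
#' no reactivity information, so both denominators are emitted and
#' labelled), and a per-patient category breakdown.
#'
#' @param records A `sero_conversions` tibble.
#' @return A `sero_conversion_summary` list: `any_seropositive_conversion`
#'   (fraction of patients), `n_patients`, `proportions_all_slots`,
#'   `proportions_positive_slots`, `per_patient` (wide counts).
#' @export
summarize_conversions <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("patient", "antigen", "category") %in% names(records)))
  if (!nrow(records)) abort("no conversion records")
  per_patient <- records |>
    dplyr::count(.data$patient, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0)
  any_pos <- mean(per_patient[["seropositive-conversion"]] > 0)
  tab_all <- prop.table(table(records$category))
  pos_involved <- records[records$category != "stable-negative", , drop = FALSE]
  tab_pos <- if (nrow(pos_involved)) prop.table(table(droplevels(
    factor(pos_involved$category, levels = conversion_levels)))) else NULL
  structure(list(
    any_seropositive_conversion = any_pos,
    n_patients = nrow(per_patient),
    proportions_all_slots = tab_all,
    proportions_positive_slots = tab_pos,
    per_patient = per_patient
  ), class = "sero_conversion_summary")
}

#' @export
print.sero_conversion_summary <- function(x, ...) {
  cat(sprintf("%d patients; %.1f%% with >=1 seropositive conversion\n",
              x$n_patients, 100 * x$any_seropositive_conversion))
  print(round(x$proportions_all_slots, 4))
  invisible(x)
}
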