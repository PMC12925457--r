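#' Composite panel positivity flag
#'
#' A patient is AAB+ for a panel when positive for at least one of the panel
#' antigens.
#'
#' @param calls Wide 0/1 call table.
#' @param panel Character vector of panel antigen ids (non-empty, all present
#'   in `calls`).
#' @return Tibble (`sample`, `aab_pos`) with `aab_pos` in 0/1.
#' @export
composite_flag <- function(calls, panel) {
  calls <- check_signal_table(calls, binary = TRUE)
  if (!length(panel)) abort("panel is empty")
  miss <- first_missing(panel, antigen_ids(calls))
  if (!is.null(miss)) abort(paste0("panel antigen not in calls: ", miss))
  m <- signal_matrix(calls)[, panel, drop = FALSE]
  tibble::tibble(sample = calls$sample, aab_pos = as.integer(rowSums(m) >= 1))
}

#' Build a 2x2 contingency table from a test flag and an outcome
#'
#' Layout: rows are test result (positive, negative), columns are outcome
#' (present, absent): `a` = TP, `b` = FP, `c` = FN, `d` = TN.
#'
#' @param flag 0/1 test-positive indicator.
#' @param outcome 0/1 outcome indicator (pairwise-complete, `NA` dropped).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
contingency_table <- function(flag, outcome) {
  keep <- !is.na(flag) & !is.na(outcome)
  f <- as.integer(flag[keep]); o <- as.integer(outcome[keep])
  c(a = sum(f == 1 & o == 1), b = sum(f == 1 & o == 0),
    c = sum(f == 0 & o == 1), d = sum(f == 0 & o == 0))
}

#' Odds ratio with Altman standard error, confidence interval and p value
#'
#' Computes `OR = ad/bc`, the log-scale standard error
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, the confidence interval
#' `exp(log OR +/- z * SE)`, and the two-sided normal p value from
#' `z = log(OR)/SE`. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) so the estimate and its error stay finite; a table
#' with two empty cells in a margin is flagged undefined.
#'
#' @param table 2x2 counts as `c(a, b, c, d)` (see [contingency_table()]) or
#'   a 2x2 matrix in the same layout.
#' @param level Confidence level (default 0.95).
#' @return One-row `sero_or` tibble: counts, `or`, `se_log_or`, `ci_low`,
#'   `ci_high`, `p`, `corrected`, `defined`, `level`.
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  if (is.matrix(table)) table <- c(a = table[1, 1], b = table[1, 2],
                                   c = table[2, 1], d = table[2, 2])
  stopifnot(length(table) == 4, all(is.finite(table)), all(table >= 0))
  a <- table[[1]]; b <- table[[2]]; c <- table[[3]]; d <- table[[4]]
  if (a + b + c + d == 0) abort("empty table")
  defined <- !((a == 0 && b == 0) || (c == 0 && d == 0) ||
               (a == 0 && c == 0) || (b == 0 && d == 0))
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]],
    or = or, se_log_or = se,
    ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
    p = 2 * pnorm(-abs(log(or) / se)),
    corrected = corrected, defined = defined, level = level)
  if (!defined) {
    out$or <- NA_real_; out$se_log_or <- NA_real_
    out$ci_low <- NA_real_; out$ci_high <- NA_real_; out$p <- NA_real_
  }
  class(out) <- c("sero_or", class(out))
  out
}

#' Positive and negative predictive values of a binary test
#'
#' `PPV = a/(a+b)` over the test-positive row and `NPV = d/(c+d)` over the
#' test-negative row. A zero margin leaves that value undefined; the other
#' is still returned.
#'
#' @inheritParams odds_ratio_ci
#' @return One-row tibble (`ppv`, `npv`).
#' @export
predictive_values <- function(table) {
  if (is.matrix(table)) table <- c(a = table[1, 1], b = table[1, 2],
                                   c = table[2, 1], d = table[2, 2])
  stopifnot(length(table) == 4, all(table >= 0))
  a <- table[[1]]; b <- table[[2]]; c <- table[[3]]; d <- table[[4]]
  tibble::tibble(
    ppv = if (a + b > 0) a / (a + b) else NA_real_,
    npv = if (c + d > 0) d / (c + d) else NA_real_)
}

#' Logistic-regression ROC curve and AUC
#'
#' Fits a logistic regression of the outcome on a single predictor (no
#' interactions), sweeps thresholds over the unique fitted probabilities,
#' and integrates the curve by the trapezoidal rule. For a single predictor
#' this AUC equals the rank (Mann-Whitney) AUC `U/(n1*n2)`. ROC curves here
#' depict association strength, not validated clinical classifiers.
#'
#' @param predictor Numeric (or 0/1) predictor, one value per sample.
#' @param outcome 0/1 outcome; both classes must be present.
#' @return A `sero_roc` object: `auc`, `curve` (threshold, sensitivity,
#'   specificity, fpr), class sizes, and the fitted coefficients.
#' @export
roc_auc <- function(predictor, outcome) {
  keep <- !is.na(predictor) & !is.na(outcome)
  x <- as.numeric(predictor[keep]); y <- as.integer(outcome[keep])
  if (length(unique(y)) < 2) abort("outcome must contain both classes")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  prob <- fit$fitted.values
  thr <- sort(unique(prob))
  pts <- purrr::map(thr, function(t) {
    pred <- as.integer(prob >= t)
    tibble::tibble(threshold = t,
                   sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
                   specificity = sum(pred == 0 & y == 0) / sum(y == 0))
  }) |> dplyr::bind_rows()
  curve <- dplyr::bind_rows(
    tibble::tibble(threshold = -Inf, sensitivity = 1, specificity = 0),
    pts,
    tibble::tibble(threshold = Inf, sensitivity = 0, specificity = 1))
  curve$fpr <- 1 - curve$specificity
  curve <- curve[order(curve$fpr, curve$sensitivity), ]
  auc <- sum(diff(curve$fpr) *
               (utils::head(curve$sensitivity, -1) +
                utils::tail(curve$sensitivity, -1)) / 2)
  structure(list(auc = auc, curve = tibble::as_tibble(curve),
                 coefficients = stats::coef(fit),
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "sero_roc")
}

#' @export
print.sero_roc <- function(x, ...) {
  cat(sprintf("Logistic-regression ROC: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

hb_cancer_labels <- c("CCA", "gallbladder cancer", "hepatocellular carcinoma",
                      "HB cancer")

pool_event_label <- function(event) {
  dplyr::case_when(
    event %in% c("none", "") | is.na(event) ~ "none",
    event == "transplantation" ~ "transplantation",
    event %in% hb_cancer_labels ~ "HB cancer",
    TRUE ~ "death")
}

#' Assign each patient the single event that occurred first
#'
#' Patients reported with multiple severe events are assigned to the earliest
#' one. Raw labels are pooled first: cholangiocarcinoma, gallbladder cancer
#' and hepatocellular carcinoma become `"HB cancer"`; any other non-transplant
#' event becomes `"death"`. Same-date ties are resolved by the precedence
#' transplantation > HB cancer > death, and flagged.
#'
#' @param events Tibble with columns `event` (raw label) and `date`
#'   (comparable, e.g. `Date` or numeric day); optionally a `patient` column
#'   for per-patient assignment.
#' @return With a `patient` column: tibble (`patient`, `event`, `tie`);
#'   otherwise a single pooled event label (`"none"` when no events).
#' @export
assign_event <- function(events) {
  precedence <- c(transplantation = 1, `HB cancer` = 2, death = 3)
  one <- function(ev) {
    ev <- ev[!is.na(ev$event) & ev$event != "none", , drop = FALSE]
    if (!nrow(ev)) return(list(event = "none", tie = FALSE))
    ev$pooled <- pool_event_label(ev$event)
    first <- ev[ev$date == min(ev$date), , drop = FALSE]
    tie <- length(unique(first$pooled)) > 1
    list(event = first$pooled[order(precedence[first$pooled])][1], tie = tie)
  }
  if ("patient" %in% names(events)) {
    events |>
      dplyr::group_by(.data$patient) |>
      dplyr::group_modify(function(g, key) {
        r <- one(g)
        tibble::tibble(event = r$event, tie = r$tie)
      }) |>
      dplyr::ungroup()
  } else {
    one(events)$event
  }
}
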