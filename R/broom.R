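#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy_seroatlas
#' @title Tidy and glance methods for seroatlas results
#' @description Broom-style accessors: `tidy()` returns the per-unit result
#'   table, `glance()` a one-row summary.
#' @param x A fitted seroatlas object.
#' @param ... Unused.
#' @method tidy sero_atlas
#' @export
tidy.sero_atlas <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sero_atlas")
  tibble::as_tibble(out)
}

#' @rdname tidy_seroatlas
#' @method glance sero_atlas
#' @export
glance.sero_atlas <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_tested = sum(x$tested),
    n_sig_05 = sum(x$p < 0.05, na.rm = TRUE),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    n_antigens = dplyr::n_distinct(x$antigen),
    n_features = dplyr::n_distinct(x$feature))
}

#' @rdname tidy_seroatlas
#' @method tidy sero_roc
#' @export
tidy.sero_roc <- function(x, ...) x$curve

#' @rdname tidy_seroatlas
#' @method glance sero_roc
#' @export
glance.sero_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy_seroatlas
#' @method tidy sero_or
#' @export
tidy.sero_or <- function(x, ...) {
  tibble::tibble(estimate = x$or, std_error_log = x$se_log_or,
                 conf_low = x$ci_low, conf_high = x$ci_high, p_value = x$p)
}

#' @rdname tidy_seroatlas
#' @method glance sero_or
#' @export
glance.sero_or <- function(x, ...) {
  tibble::tibble(or = x$or, p = x$p, n = x$a + x$b + x$c + x$d,
                 corrected = x$corrected, defined = x$defined)
}

#' @rdname tidy_seroatlas
#' @method tidy sero_cutoffs
#' @export
tidy.sero_cutoffs <- function(x, ...) {
  tibble::tibble(antigen = x$antigen, cutoff = x$cutoff,
                 specificity = attr(x, "specificity"),
                 n_reference = attr(x, "n_reference"))
}

#' @rdname tidy_seroatlas
#' @method tidy sero_conversion_summary
#' @export
tidy.sero_conversion_summary <- function(x, ...) {
  tibble::tibble(category = names(x$proportions_all_slots),
                 proportion_all_slots = as.numeric(x$proportions_all_slots),
                 proportion_positive_slots =
                   as.numeric(x$proportions_positive_slots[
                     names(x$proportions_all_slots)]))
}

#' @rdname tidy_seroatlas
#' @method glance sero_conversion_summary
#' @export
glance.sero_conversion_summary <- function(x, ...) {
  tibble::tibble(n_patients = x$n_patients,
                 any_seropositive_conversion = x$any_seropositive_conversion)
}
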