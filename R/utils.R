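#' @importFrom rlang %||% .data abort warn
#' @importFrom stats median mad quantile qnorm pnorm phyper p.adjust rbinom
#'   rlnorm runif rnorm chisq.test wilcox.test glm binomial predict cutree
#'   hclust dist cor.test IQR setNames
#' @importFrom utils combn write.table
NULL

# A signal/call table is a wide tibble: first column `sample` (character),
# remaining columns numeric, one per antigen. Metadata (assay, channel) is
# carried in attributes so the table stays pipe-friendly.

#' Tag a samples-by-antigens table as an array signal matrix
#'
#' Validates a wide table of reactivity intensities (one row per sample, one
#' numeric column per antigen, sample identifiers in a `sample` column) and
#' records which assay and detection channel produced it.
#'
#' @param x A data frame with a `sample` character column and one numeric
#'   column per antigen.
#' @param assay `"planar"` or `"bead"`.
#' @param channel `"IgG"`, `"IgA"`, or `"IgG-minus-IgA"`.
#' @param allow_negative Permit negative values (normalized scores are
#'   signed; raw fluorescence intensities are not).
#' @return The input as a tibble with `assay` and `channel` attributes.
#' @export
sero_signals <- function(x, assay = c("bead", "planar"),
                         channel = c("IgG", "IgA", "IgG-minus-IgA"),
                         allow_negative = FALSE) {
  assay <- match.arg(assay)
  channel <- match.arg(channel)
  x <- check_signal_table(x, allow_negative = allow_negative)
  attr(x, "assay") <- assay
  attr(x, "channel") <- channel
  x
}

check_signal_table <- function(x, allow_negative = FALSE, binary = FALSE) {
  if (!is.data.frame(x)) abort("expected a data frame of signals")
  if (!"sample" %in% names(x)) abort("signal table needs a `sample` column")
  x <- tibble::as_tibble(x)
  vals <- x[setdiff(names(x), "sample")]
  if (ncol(vals) == 0L) abort("signal table has no antigen columns")
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("all antigen columns must be numeric")
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) abort("signal values must be finite")
  if (!allow_negative && any(m < 0)) abort("signal values must be non-negative")
  if (binary && !all(m %in% c(0, 1))) abort("calls must be 0/1")
  if (anyDuplicated(x$sample)) abort("duplicated sample ids in signal table")
  x
}

# numeric matrix with sample rownames
signal_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample")])
  rownames(m) <- x$sample
  m
}

signals_from_matrix <- function(m, assay = NULL, channel = NULL) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)), out)
  if (!is.null(assay)) attr(out, "assay") <- assay
  if (!is.null(channel)) attr(out, "channel") <- channel
  out
}

antigen_ids <- function(x) setdiff(names(x), "sample")

# first element of `want` not present in `have`, or NULL
first_missing <- function(want, have) {
  miss <- setdiff(want, have)
  if (length(miss)) miss[[1]] else NULL
}

check_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    abort(paste0("`", name, "` must be a single positive integer"))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(paste0("`", name, "` must lie in [", lo, ", ", hi, "]"))
  }
  x
}
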