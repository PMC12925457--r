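#' Subtract the IgA channel from the IgG channel of a planar array
#'
#' Planar antigen arrays are scanned once after the anti-IgA detection step
#' and again after the anti-IgG step; subtracting the IgA scan from the IgG
#' scan estimates reactivity unique to IgG. Differences below zero are
#' clipped to zero, since reactivity is non-negative.
#'
#' @param igg,iga Planar signal tables over the same samples and antigens
#'   (matched by id, order-independent).
#' @return A planar signal table tagged `IgG-minus-IgA`.
#' @export
subtract_channel <- function(igg, iga) {
  igg <- check_signal_table(igg)
  iga <- check_signal_table(iga)
  for (x in list(igg, iga)) {
    if (!is.null(attr(x, "assay")) && attr(x, "assay") != "planar") {
      abort("channel subtraction applies to planar arrays")
    }
  }
  miss <- first_missing(igg$sample, iga$sample) %||%
    first_missing(iga$sample, igg$sample)
  if (!is.null(miss)) abort(paste0("unmatched sample id: ", miss))
  miss <- first_missing(antigen_ids(igg), antigen_ids(iga)) %||%
    first_missing(antigen_ids(iga), antigen_ids(igg))
  if (!is.null(miss)) abort(paste0("unmatched antigen id: ", miss))

  mg <- signal_matrix(igg)
  ma <- signal_matrix(iga)[rownames(mg), colnames(mg), drop = FALSE]
  out <- pmax(mg - ma, 0)
  signals_from_matrix(out, assay = "planar", channel = "IgG-minus-IgA")
}

#' Normalize bead-array signals against a healthy reference
#'
#' The default method first divides each sample row by its median signal
#' (probe-loading correction, making rows invariant to per-sample scale),
#' then converts each antigen to a robust z score against an explicit healthy
#' reference population: subtract the reference median and divide by the
#' reference MAD (scaled by 1.4826 for normal consistency). When the MAD is
#' zero the scale falls back to IQR/1.349; antigens whose reference spread is
#' zero by both measures are flagged non-informative and set to zero.
#'
#' @param raw Raw bead signal table.
#' @param reference Character vector of sample ids forming the healthy
#'   reference population (must be rows of `raw`).
#' @param method `"median-robust-z"` (default) or `"none"` (pass-through).
#' @return Normalized signal table (signed values) with attributes
#'   `normalization`, `reference` and `noninformative` (flagged antigens).
#' @export
normalize_signals <- function(raw, reference,
                              method = c("median-robust-z", "none")) {
  method <- match.arg(method)
  raw <- check_signal_table(raw)
  if (method == "none") {
    attr(raw, "normalization") <- "none"
    return(raw)
  }
  miss <- first_missing(reference, raw$sample)
  if (!is.null(miss)) abort(paste0("reference sample not found: ", miss))
  m <- signal_matrix(raw)
  med <- apply(m, 1, median)
  if (any(med == 0)) {
    abort(paste0("zero sample median for: ", rownames(m)[med == 0][1]))
  }
  m <- m / med
  ref <- m[reference, , drop = FALSE]
  center <- apply(ref, 2, median)
  scale <- apply(ref, 2, mad)           # includes the 1.4826 constant
  iqr_scale <- apply(ref, 2, IQR) / 1.349
  use_iqr <- scale == 0 & iqr_scale > 0
  scale[use_iqr] <- iqr_scale[use_iqr]
  flagged <- colnames(m)[scale == 0]
  scale[scale == 0] <- 1                # flagged antigens end up all-zero
  z <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  z[, flagged] <- 0
  out <- signals_from_matrix(z, assay = attr(raw, "assay"), channel = attr(raw, "channel"))
  attr(out, "normalization") <- "median-robust-z"
  attr(out, "reference") <- reference
  attr(out, "noninformative") <- flagged
  out
}

#' Select candidate antigens by highest pooled titers
#'
#' For each pool (row) the `k` antigens with the highest signal are taken;
#' the union over pools is returned. Within-pool ties are broken by
#' lexicographic antigen id so the selection is reproducible.
#'
#' @param pool_signals Pooled signal table (one channel; run once per
#'   channel and combine the unions for a dual-channel design).
#' @param k Number of antigens to keep per pool.
#' @return Sorted character vector of unique selected antigen ids.
#' @export
select_top_reactive <- function(pool_signals, k) {
  pool_signals <- check_signal_table(pool_signals, allow_negative = TRUE)
  if (length(k) != 1L || !is.finite(k) || k <= 0 || k != floor(k)) {
    abort("`k` must be a single positive integer")
  }
  m <- signal_matrix(pool_signals)
  if (k > ncol(m)) abort("`k` exceeds the number of antigens")
  ids <- colnames(m)
  picked <- lapply(seq_len(nrow(m)), function(i) {
    ord <- order(-m[i, ], ids)          # value desc, then antigen id
    ids[ord[seq_len(k)]]
  })
  sort(unique(unlist(picked)))
}
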