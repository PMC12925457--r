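#' Classify expression specificity with four-fold rules
#'
#' Assigns each gene one of five categories from its per-tissue (or
#' per-cell-type) TPM profile, in order of precedence:
#' \itemize{
#'   \item \emph{not detected}: below the detection floor (TPM < 1) in every
#'     tissue;
#'   \item \emph{tissue enriched}: at least four-fold higher in one tissue
#'     than in any other tissue;
#'   \item \emph{group enriched}: at least four-fold higher average level in
#'     a group of 2-5 tissues (2-10 cell types) than in any tissue outside
#'     the group;
#'   \item \emph{tissue enhanced}: at least four-fold higher in one tissue
#'     than the average of all other tissues;
#'   \item \emph{low tissue specificity} otherwise.
#' }
#' Only the k highest-expressing tissues can form a qualifying group of size
#' k (any qualifying group must dominate every outside tissue, so the top-k
#' set qualifies whenever any size-k set does); the smallest qualifying k is
#' reported. A tissue whose competitors are all zero counts as infinitely
#' enriched.
#'
#' @param expression Tibble with a `gene` column and one numeric TPM column
#'   per tissue (at least 3 tissues).
#' @param mode `"tissue"` (groups of 2-5) or `"cell_type"` (groups of 2-10).
#' @param detection_limit Detection floor in TPM (default 1).
#' @return Tibble (`gene`, `category`, `target`) where `target` is the
#'   semicolon-separated target tissue set (empty for the unspecific
#'   categories).
#' @export
classify_specificity <- function(expression, mode = c("tissue", "cell_type"),
                                 detection_limit = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(expression), "gene" %in% names(expression))
  tissues <- setdiff(names(expression), "gene")
  if (length(tissues) < 3) abort("need at least 3 tissues")
  m <- as.matrix(expression[tissues])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("TPM values must be finite and non-negative")
  }
  max_group <- min(if (mode == "tissue") 5L else 10L, length(tissues) - 1L)
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    classify_row(m[i, ], tissues, max_group, detection_limit)
  })
  dplyr::bind_cols(tibble::tibble(gene = expression$gene),
                   dplyr::bind_rows(res))
}

classify_row <- function(v, tissues, max_group, detection_limit) {
  if (max(v) < detection_limit) {
    return(tibble::tibble(category = "not detected", target = ""))
  }
  ord <- order(-v, tissues)             # value desc, tie by tissue name
  vs <- v[ord]
  ts <- tissues[ord]
  T <- length(v)
  if (vs[1] >= 4 * vs[2]) {
    return(tibble::tibble(category = "tissue enriched", target = ts[1]))
  }
  for (k in 2:max_group) {
    if (mean(vs[1:k]) >= 4 * vs[k + 1]) {
      return(tibble::tibble(category = "group enriched",
                            target = paste(sort(ts[1:k]), collapse = ";")))
    }
  }
  if (vs[1] >= 4 * mean(vs[-1])) {
    return(tibble::tibble(category = "tissue enhanced", target = ts[1]))
  }
  tibble::tibble(category = "low tissue specificity", target = "")
}

#' Tissue overrepresentation among autoantigen targets
#'
#' Tests whether genes with elevated expression in a tissue (tissue
#' enriched, group enriched or tissue enhanced with the tissue in the target
#' set) are overrepresented among autoantigens relative to a background
#' universe, with a one-sided hypergeometric (Fisher) test.
#'
#' @param labels Classification table (from [classify_specificity()]) for the
#'   autoantigen set.
#' @param background Classification table for the background universe; the
#'   autoantigen genes must be a subset of it.
#' @param tissue Tissue (or cell-type) id to test.
#' @return One-row tibble: set and universe sizes, elevated counts, the
#'   fold enrichment and the one-sided hypergeometric p value.
#' @export
overrepresentation <- function(labels, background, tissue) {
  elevated_cats <- c("tissue enriched", "group enriched", "tissue enhanced")
  check_lab <- function(x) {
    stopifnot(is.data.frame(x),
              all(c("gene", "category", "target") %in% names(x)))
  }
  check_lab(labels); check_lab(background)
  if (!nrow(background)) abort("empty background universe")
  miss <- first_missing(labels$gene, background$gene)
  if (!is.null(miss)) {
    abort(paste0("autoantigen gene not in background universe: ", miss))
  }
  elevated_in <- function(x) {
    x$category %in% elevated_cats &
      vapply(strsplit(x$target, ";", fixed = TRUE),
             function(t) tissue %in% t, logical(1))
  }
  N <- nrow(background)
  K <- sum(elevated_in(background))
  n <- nrow(labels)
  x <- sum(elevated_in(labels))
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(tissue = tissue, n_set = n, k_set = x,
                 n_universe = N, k_universe = K,
                 fold_enrichment = if (K > 0) (x / n) / (K / N) else NA_real_,
                 p = p)
}

#' Tissue-restricted co-expression with an anchor gene
#'
#' Correlates an anchor autoantigen with candidate partner genes across
#' samples of one tissue (Spearman by default, Pearson optionally) and
#' returns correlation estimates with two-sided p values, ranked by p.
#'
#' @param expr Tibble of samples x genes for one tissue: a `sample` column
#'   plus one numeric column per gene; at least 10 samples.
#' @param anchor_gene Anchor gene column name.
#' @param partner_genes Character vector of partner gene columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble (`partner`, `estimate`, `p`), p ascending.
#' @export
tissue_coexpression <- function(expr, anchor_gene, partner_genes,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(expr))
  if (nrow(expr) < 10) abort("need at least 10 samples of the tissue")
  miss <- first_missing(c(anchor_gene, partner_genes), names(expr))
  if (!is.null(miss)) abort(paste0("gene not in expression table: ", miss))
  anchor <- expr[[anchor_gene]]
  if (length(unique(anchor)) < 2) abort("anchor gene is constant")
  res <- purrr::map(partner_genes, function(g) {
    ct <- suppressWarnings(cor.test(anchor, expr[[g]], method = method,
                                    exact = FALSE))
    tibble::tibble(partner = g, estimate = unname(ct$estimate), p = ct$p.value)
  }) |> dplyr::bind_rows()
  dplyr::arrange(res, .data$p, .data$partner)
}
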