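#' Chi-squared association test between an antibody call and a binary feature
#'
#' Builds the 2x2 table of seropositivity call against the feature on
#' pairwise-complete observations (missing feature values are dropped,
#' never imputed) and applies Pearson's chi-squared test, with Yates
#' continuity correction by default. A table with a zero margin is not
#' tested; the result is returned flagged `"degenerate margin"`.
#'
#' @param calls_for_antigen 0/1 vector of calls, one per sample.
#' @param feature 0/1 (or logical) feature vector over the same samples;
#'   `NA` allowed.
#' @param correct Apply Yates continuity correction (default `TRUE`).
#' @return One-row tibble: `test`, `statistic`, `p`, the 2x2 counts
#'   (`a` = AAB+/feature+, `b` = AAB+/feature-, `c` = AAB-/feature+,
#'   `d` = AAB-/feature-), per-arm sizes and feature proportions, `tested`,
#'   `reason`.
#' @export
test_binary <- function(calls_for_antigen, feature, correct = TRUE) {
  keep <- !is.na(feature) & !is.na(calls_for_antigen)
  call <- as.integer(calls_for_antigen[keep])
  feat <- as.integer(feature[keep])
  base <- tibble::tibble(test = "chi-square", statistic = NA_real_, p = NA_real_,
                         a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                         n_pos = sum(call == 1L), n_neg = sum(call == 0L),
                         prop_pos = NA_real_, prop_neg = NA_real_,
                         tested = FALSE, reason = NA_character_)
  if (!length(call)) {
    base$reason <- "no non-missing observations"
    return(base)
  }
  a <- sum(call == 1L & feat == 1L); b <- sum(call == 1L & feat == 0L)
  c <- sum(call == 0L & feat == 1L); d <- sum(call == 0L & feat == 0L)
  base$a <- a; base$b <- b; base$c <- c; base$d <- d
  base$prop_pos <- if (a + b > 0) a / (a + b) else NA_real_
  base$prop_neg <- if (c + d > 0) c / (c + d) else NA_real_
  tab <- matrix(c(a, c, b, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    base$reason <- "degenerate margin"
    return(base)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  base$statistic <- unname(ht$statistic)
  base$p <- ht$p.value
  base$tested <- TRUE
  base
}

#' Two-sided Mann-Whitney U test
#'
#' For combined sample sizes up to `exact_max` the null distribution of U is
#' obtained by full enumeration of all group assignments over the observed
#' (possibly tied) values, and the two-sided p value is twice the smaller
#' tail, capped at 1. Above `exact_max` the tie-corrected normal
#' approximation is used without continuity correction.
#'
#' @param x,y Numeric samples (AAB+ and AAB- arms).
#' @param exact_max Largest combined size for the exact path (default 20).
#' @return List with `statistic` (U of `x`), `p.value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) abort("both arms must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    idx <- combn(n, n1)
    uall <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(uall <= u), mean(uall >= u)))
    method <- "exact (enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1            # all values tied
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation, tie corrected"
  }
  list(statistic = u, p.value = p, method = method)
}

#' Mann-Whitney association test between an antibody call and a continuous
#' feature
#'
#' Compares the feature between seropositive (AAB+) and seronegative (AAB-)
#' samples on pairwise-complete observations. Arms smaller than `min_arm`
#' are not tested (small arms produce unstable p values). Effect summaries
#' are the per-arm medians and the fold-change of medians.
#'
#' @inheritParams test_binary
#' @param feature Numeric feature vector; `NA` allowed.
#' @param min_arm Minimum non-missing observations per arm (default 3).
#' @param exact_max Passed to [mann_whitney()].
#' @return One-row tibble: `test`, `statistic` (U of the AAB+ arm), `p`,
#'   `median_pos`, `median_neg`, `fold_change`, `direction`, arm sizes,
#'   `tested`, `reason`.
#' @export
test_continuous <- function(calls_for_antigen, feature, min_arm = 3,
                            exact_max = 20) {
  keep <- !is.na(feature) & !is.na(calls_for_antigen)
  call <- as.integer(calls_for_antigen[keep])
  feat <- as.numeric(feature[keep])
  xp <- feat[call == 1L]; xn <- feat[call == 0L]
  base <- tibble::tibble(test = "Mann-Whitney", statistic = NA_real_,
                         p = NA_real_, median_pos = NA_real_,
                         median_neg = NA_real_, fold_change = NA_real_,
                         direction = NA_character_,
                         n_pos = length(xp), n_neg = length(xn),
                         tested = FALSE, reason = NA_character_)
  if (length(xp) < min_arm || length(xn) < min_arm) {
    base$reason <- if (length(xp) == 0 || length(xn) == 0) "empty arm"
                   else paste0("arm smaller than ", min_arm)
    return(base)
  }
  mw <- mann_whitney(xp, xn, exact_max = exact_max)
  mp <- median(xp); mn <- median(xn)
  base$statistic <- mw$statistic
  base$p <- mw$p.value
  base$median_pos <- mp
  base$median_neg <- mn
  base$fold_change <- if (mn != 0) mp / mn else NA_real_
  base$direction <- if (mp > mn) "higher in AAB+"
                    else if (mp < mn) "lower in AAB+" else "equal"
  base$tested <- TRUE
  base
}

#' Screen every antibody against every clinical feature
#'
#' Runs the appropriate association test (chi-squared for binary features,
#' Mann-Whitney for continuous) for each antigen x feature pair and collects
#' the results in a long-format atlas. Untested cells carry the reason they
#' were skipped. Raw p values are reported; Benjamini-Hochberg q values per
#' feature are attached as optional metadata.
#'
#' @param calls Wide 0/1 call table.
#' @param annotation Sample annotation holding the feature columns.
#' @param schema Named character vector mapping feature name to `"binary"` or
#'   `"continuous"`, e.g. `c(sex = "binary", ap = "continuous")`.
#' @param correct Yates correction for the binary tests.
#' @param min_arm,exact_max Passed to [test_continuous()].
#' @param adjust Compute per-feature Benjamini-Hochberg q values.
#' @return A `sero_atlas` tibble, one row per antigen x feature.
#' @export
build_atlas <- function(calls, annotation, schema, correct = TRUE,
                        min_arm = 3, exact_max = 20, adjust = TRUE) {
  calls <- check_signal_table(calls, binary = TRUE)
  if (is.null(names(schema)) || !all(schema %in% c("binary", "continuous"))) {
    abort("`schema` must be a named vector of \"binary\"/\"continuous\"")
  }
  miss <- first_missing(names(schema), names(annotation))
  if (!is.null(miss)) abort(paste0("feature not in annotation: ", miss))
  miss <- first_missing(calls$sample, annotation$sample)
  if (!is.null(miss)) abort(paste0("sample not annotated: ", miss))
  ann <- annotation[match(calls$sample, annotation$sample), ]
  m <- signal_matrix(calls)

  cells <- purrr::map(names(schema), function(f) {
    kind <- schema[[f]]
    fv <- ann[[f]]
    res <- purrr::map(colnames(m), function(a) {
      r <- if (kind == "binary") test_binary(m[, a], fv, correct = correct)
           else test_continuous(m[, a], fv, min_arm = min_arm,
                                exact_max = exact_max)
      dplyr::bind_cols(tibble::tibble(antigen = a, feature = f, kind = kind), r)
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(cells)
  if (adjust) {
    out <- out |>
      dplyr::group_by(.data$feature) |>
      dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  class(out) <- c("sero_atlas", class(out))
  attr(out, "schema") <- schema
  out
}

#' Restrict annotation and calls to the severe-event comparison
#'
#' Event analyses compare samples taken close to a severe event
#' (`timepoint == "event"`) with inclusion samples of patients who never
#' developed an event.
#'
#' @param annotation Sample annotation with `timepoint` and `event` columns.
#' @return The subset of `annotation` entering the comparison, with a logical
#'   `event_proximal` column.
#' @export
event_analysis_samples <- function(annotation) {
  stopifnot(all(c("sample", "timepoint", "event") %in% names(annotation)))
  keep_event <- annotation$timepoint == "event"
  event_free <- !annotation$patient %in% annotation$patient[annotation$event != "none"]
  keep_incl <- annotation$timepoint == "inclusion" & event_free
  out <- annotation[keep_event | keep_incl, , drop = FALSE]
  out$event_proximal <- out$timepoint == "event"
  out
}

#' Cluster antibodies on their association profiles
#'
#' Antigens are clustered with Ward's method (the `ward.D2` variant of
#' agglomerative linkage on Euclidean distances) over their profiles of
#' `-log10 p` across features; untested cells contribute zero signal.
#' An alternative feature space is binary co-occurrence of calls across
#' samples. Antigens are sorted by id before clustering so the result does
#' not depend on input order.
#'
#' @param atlas A `sero_atlas`.
#' @param n_clusters Number of clusters to cut the tree into.
#' @param space `"neglog10p"` (default) or `"cooccurrence"`.
#' @param calls Required for `space = "cooccurrence"`: the call table.
#' @return A `sero_clusters` tibble (`antigen`, `cluster`) with the `hclust`
#'   object and merge heights in attributes.
#' @export
cluster_atlas <- function(atlas, n_clusters,
                          space = c("neglog10p", "cooccurrence"),
                          calls = NULL) {
  space <- match.arg(space)
  stopifnot(inherits(atlas, "sero_atlas"))
  if (space == "neglog10p") {
    prof <- atlas |>
      dplyr::mutate(score = ifelse(is.na(.data$p), 0, -log10(pmax(.data$p, 1e-300)))) |>
      dplyr::select("antigen", "feature", "score") |>
      tidyr::pivot_wider(names_from = "feature", values_from = "score")
    prof <- prof[order(prof$antigen), ]
    m <- as.matrix(prof[, -1])
    rownames(m) <- prof$antigen
  } else {
    if (is.null(calls)) abort("co-occurrence space needs `calls`")
    calls <- check_signal_table(calls, binary = TRUE)
    m <- t(signal_matrix(calls))
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 antigens to cluster")
  if (all(rowSums(is.finite(m)) == 0)) abort("no finite association profile")
  if (n_clusters > nrow(m)) abort("`n_clusters` exceeds the number of antigens")
  hc <- hclust(dist(m), method = "ward.D2")
  cl <- cutree(hc, k = n_clusters)
  out <- tibble::tibble(antigen = names(cl), cluster = unname(cl))
  class(out) <- c("sero_clusters", class(out))
  attr(out, "hclust") <- hc
  attr(out, "heights") <- hc$height
  attr(out, "space") <- space
  out
}

#' Select the top antibodies of a cluster for one feature
#'
#' Within each cluster, keeps the members with the smallest p value for the
#' feature, at most `max_k` of them (default 6); ties are broken by antigen
#' id.
#'
#' @param atlas A `sero_atlas`.
#' @param clusters A `sero_clusters` assignment.
#' @param feature Feature name.
#' @param max_k Panel size cap (default 6).
#' @param cluster Optional single cluster id; if given and the cluster has no
#'   tested member for the feature an error is raised.
#' @return Tibble (`cluster`, `antigen`, `p`, `rank`).
#' @export
top_per_cluster <- function(atlas, clusters, feature, max_k = 6, cluster = NULL) {
  stopifnot(inherits(atlas, "sero_atlas"))
  cells <- atlas[atlas$feature == feature & atlas$tested, c("antigen", "p")]
  joined <- dplyr::inner_join(clusters, cells, by = "antigen")
  if (!is.null(cluster)) {
    joined <- joined[joined$cluster %in% cluster, , drop = FALSE]
    if (!nrow(joined)) {
      abort(paste0("cluster ", cluster, " has no tested member for `",
                   feature, "`"))
    }
  } else {
    empty <- setdiff(unique(clusters$cluster), unique(joined$cluster))
    if (length(empty)) {
      warn(paste0("clusters with no tested member for `", feature, "`: ",
                  paste(empty, collapse = ", ")))
    }
  }
  joined |>
    dplyr::arrange(.data$cluster, .data$p, .data$antigen) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= max_k) |>
    dplyr::ungroup()
}

#' Rank antibodies by group-median contrast on a continuous feature
#'
#' For each antigen, compares the feature (e.g. disease duration) between
#' AAB+ and AAB- patients with the Mann-Whitney test and reports the top
#' `top_k` antigens by p value together with the per-arm medians, their
#' ratio, and a direction tag relative to the AAB- median.
#'
#' @param calls Wide 0/1 call table.
#' @param annotation Sample annotation holding the feature.
#' @param feature Name of a continuous feature column.
#' @param top_k Number of antigens to return (default 50).
#' @param min_arm,exact_max Passed to [test_continuous()].
#' @return Tibble (`antigen`, `p`, `median_pos`, `median_neg`, `ratio`,
#'   `direction`), ordered by p; fewer than `top_k` rows (with a warning) if
#'   fewer antigens are testable.
#' @export
rank_by_group_median <- function(calls, annotation, feature, top_k = 50,
                                 min_arm = 3, exact_max = 20) {
  calls <- check_signal_table(calls, binary = TRUE)
  if (!feature %in% names(annotation)) {
    abort(paste0("feature not in annotation: ", feature))
  }
  if (top_k == 0) {
    return(tibble::tibble(antigen = character(), p = numeric(),
                          median_pos = numeric(), median_neg = numeric(),
                          ratio = numeric(), direction = character()))
  }
  ann <- annotation[match(calls$sample, annotation$sample), ]
  m <- signal_matrix(calls)
  res <- purrr::map(colnames(m), function(a) {
    r <- test_continuous(m[, a], ann[[feature]], min_arm = min_arm,
                         exact_max = exact_max)
    tibble::tibble(antigen = a, p = r$p, median_pos = r$median_pos,
                   median_neg = r$median_neg, ratio = r$fold_change,
                   direction = r$direction, tested = r$tested)
  }) |> dplyr::bind_rows()
  res <- res[res$tested, setdiff(names(res), "tested")]
  if (nrow(res) < top_k) {
    warn(paste0("only ", nrow(res), " testable antigens for `", feature, "`"))
  }
  res |>
    dplyr::arrange(.data$p, .data$antigen) |>
    dplyr::slice_head(n = top_k)
}
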