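#' Configure a synthetic serology cohort
#'
#' Describes a synthetic antigen-array study: cohort sizes, per-antigen
#' healthy baseline reactivity (log-normal, heavy right tail), low-prevalence
#' planted seropositivity in cases, planted antibody-feature associations,
#' longitudinal conversion rates and an optional pooling design. Every
#' downstream module can then be exercised against the recorded ground truth.
#'
#' Baseline reactivity for antigen *a* is log-normal with log-scale location
#' `baseline_location[a]` and scale `baseline_scale[a]`; a seropositive
#' sample's latent titer is multiplied by `seropos_fold`. Clinical features
#' with planted dependence are generated conditionally on the true latent
#' seropositive state (not the called state), so cutoff errors propagate into
#' downstream association tests the way they would in a real screen.
#'
#' @param n_cases,n_healthy,n_disease_controls Cohort group sizes. Disease
#'   controls are split evenly between IBD and liver-disease control groups.
#' @param n_antigens Number of antigens on the array.
#' @param baseline_location,baseline_scale Per-antigen log-normal parameters
#'   (scalar recycled, or vector of length `n_antigens`). Defaults spread
#'   locations over \eqn{[4, 6]} and scales over \eqn{[0.3, 0.6]} so antigens
#'   differ in both brightness and tail weight.
#' @param planted_prevalence Per-antigen probability that a case is truly
#'   seropositive (scalar recycled). Healthy donors and disease controls are
#'   drawn from baseline only.
#' @param seropos_fold Multiplicative titer shift applied to seropositive
#'   signals.
#' @param planted_associations List of [planted_association()] records.
#' @param antigen_blocks Optional list of co-occurrence blocks, each a list
#'   with `antigens` (integer indices) and `prevalence`: the listed antigens
#'   share one latent seropositive state per case, so they co-occur in the
#'   same patients (the way antibodies against a shared driver do). Block
#'   membership overrides the independent per-antigen prevalence.
#' @param n_null_binary,n_null_continuous Numbers of clinical features with
#'   no dependence on any antigen (named `bin_f*` / `cont_f*`).
#' @param binary_rate Baseline rate of binary features.
#' @param conversion_rates Named vector `c(pos = ..., neg = ...)`: per
#'   antigen-slot probabilities that a negative call turns positive (and vice
#'   versa) between two timepoints.
#' @param pool_groups Optional named list giving the member count of each
#'   serum pool; counts must be between 6 and 8, the group size at which a
#'   single positive donor is still detectable after dilution.
#' @param batch_offset Optional additive offset applied to all raw signals.
#' @param seed Integer seed; fixes all generated artifacts end-to-end.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cases = 419, n_healthy = 91, n_disease_controls = 124,
                       n_antigens = 200,
                       baseline_location = NULL, baseline_scale = NULL,
                       planted_prevalence = 0.08, seropos_fold = 8,
                       planted_associations = list(),
                       antigen_blocks = list(),
                       n_null_binary = 5, n_null_continuous = 5,
                       binary_rate = 0.3,
                       conversion_rates = c(pos = 0.1, neg = 0.05),
                       pool_groups = NULL, batch_offset = 0, seed = 1L) {
  n_cases <- check_scalar_count(n_cases, "n_cases")
  n_healthy <- check_scalar_count(n_healthy, "n_healthy")
  n_disease_controls <- check_scalar_count(n_disease_controls, "n_disease_controls")
  n_antigens <- check_scalar_count(n_antigens, "n_antigens")

  baseline_location <- baseline_location %||% seq(4, 6, length.out = n_antigens)
  baseline_scale <- baseline_scale %||% seq(0.3, 0.6, length.out = n_antigens)
  baseline_location <- rep_len(baseline_location, n_antigens)
  baseline_scale <- rep_len(baseline_scale, n_antigens)
  if (any(!is.finite(baseline_location)) || any(!is.finite(baseline_scale)) ||
      any(baseline_location <= 0) || any(baseline_scale <= 0)) {
    abort("baseline location/scale must be finite and positive")
  }

  planted_prevalence <- rep_len(planted_prevalence, n_antigens)
  check_fraction(planted_prevalence, "planted_prevalence")
  if (!is.finite(seropos_fold) || seropos_fold <= 0) {
    abort("`seropos_fold` must be finite and positive")
  }
  check_fraction(binary_rate, "binary_rate")

  if (is.null(names(conversion_rates))) names(conversion_rates) <- c("pos", "neg")
  if (!all(c("pos", "neg") %in% names(conversion_rates))) {
    abort("`conversion_rates` needs elements `pos` and `neg`")
  }
  check_fraction(conversion_rates, "conversion_rates")

  if (!is.null(pool_groups)) {
    sizes <- unlist(pool_groups)
    if (is.null(names(pool_groups)) || any(!nzchar(names(pool_groups)))) {
      abort("`pool_groups` must be a named list of member counts")
    }
    if (any(!is.finite(sizes)) || any(sizes != floor(sizes)) ||
        any(sizes < 6) || any(sizes > 8)) {
      abort("pool group sizes must be whole numbers between 6 and 8")
    }
  }

  for (bl in antigen_blocks) {
    if (!all(c("antigens", "prevalence") %in% names(bl))) {
      abort("each antigen block needs `antigens` and `prevalence`")
    }
    if (any(bl$antigens < 1) || any(bl$antigens > n_antigens)) {
      abort("antigen block refers to an antigen outside 1..n_antigens")
    }
    check_fraction(bl$prevalence, "block prevalence")
  }
  blocked <- unlist(lapply(antigen_blocks, `[[`, "antigens"))
  if (anyDuplicated(blocked)) abort("an antigen belongs to two blocks")

  for (pa in planted_associations) {
    if (!inherits(pa, "planted_association")) {
      abort("`planted_associations` must be built with planted_association()")
    }
    if (any(pa$antigens > n_antigens) || any(pa$antigens < 1)) {
      abort("planted association refers to an antigen outside 1..n_antigens")
    }
  }
  if (!is.finite(batch_offset)) abort("`batch_offset` must be finite")
  if (length(seed) != 1L || !is.finite(seed)) abort("`seed` must be one integer")

  structure(list(
    n_cases = n_cases, n_healthy = n_healthy,
    n_disease_controls = n_disease_controls, n_antigens = n_antigens,
    baseline_location = baseline_location, baseline_scale = baseline_scale,
    planted_prevalence = planted_prevalence, seropos_fold = seropos_fold,
    planted_associations = planted_associations,
    antigen_blocks = antigen_blocks,
    n_null_binary = as.integer(n_null_binary),
    n_null_continuous = as.integer(n_null_continuous),
    binary_rate = binary_rate,
    conversion_rates = conversion_rates[c("pos", "neg")],
    pool_groups = pool_groups, batch_offset = batch_offset,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Declare a planted antibody-feature association
#'
#' @param antigens Integer indices of the antigens driving the feature.
#' @param feature Feature name.
#' @param kind `"binary"` or `"continuous"`.
#' @param effect Binary: odds ratio of feature-positivity given true
#'   seropositivity for any listed antigen. Continuous: location shift (in
#'   standard-deviation units) added for truly seropositive samples.
#' @param baseline Binary only: feature rate among latent-negative samples.
#' @export
planted_association <- function(antigens, feature, kind = c("binary", "continuous"),
                                effect, baseline = 0.3) {
  kind <- match.arg(kind)
  antigens <- as.integer(antigens)
  if (!length(antigens)) abort("association needs at least one antigen")
  if (!is.finite(effect)) abort("association effect must be finite")
  if (kind == "binary" && effect <= 0) abort("odds-ratio effect must be positive")
  check_fraction(baseline, "baseline")
  structure(list(antigens = antigens, feature = as.character(feature),
                 kind = kind, effect = effect, baseline = baseline),
            class = "planted_association")
}

#' Generate a synthetic bead-array cohort with ground truth
#'
#' Draws raw single-channel IgG reactivities for cases, healthy donors and
#' disease controls, plants low-prevalence seropositivity in cases, generates
#' clinical features (with configured dependence on the true latent
#' seropositive state), and returns the truth record needed for
#' parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `sero_cohort`: `signals` (raw bead IgG
#'   intensities), `annotation` (sample, patient, group, timepoint, event and
#'   all features), and `truth` (latent positivity matrix, per-group true
#'   prevalence, planted association table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_ibd <- config$n_disease_controls %/% 2L
  n_liv <- config$n_disease_controls - n_ibd
  groups <- c(rep("PSC", config$n_cases), rep("HD", config$n_healthy),
              rep("IBD-control", n_ibd), rep("liver-disease-control", n_liv))
  n <- length(groups)
  samples <- sprintf("S%04d", seq_len(n))
  patients <- sprintf("P%04d", seq_len(n))
  antigens <- sprintf("ag%04d", seq_len(config$n_antigens))

  # latent seropositivity: cases only
  latent <- matrix(0L, n, config$n_antigens, dimnames = list(samples, antigens))
  is_case <- groups == "PSC"
  for (a in seq_len(config$n_antigens)) {
    latent[is_case, a] <- rbinom(sum(is_case), 1L, config$planted_prevalence[a])
  }
  # co-occurrence blocks: members share one latent state per case
  for (bl in config$antigen_blocks) {
    shared <- rbinom(sum(is_case), 1L, bl$prevalence)
    for (a in bl$antigens) latent[is_case, a] <- shared
  }

  sig <- matrix(0, n, config$n_antigens, dimnames = list(samples, antigens))
  for (a in seq_len(config$n_antigens)) {
    sig[, a] <- rlnorm(n, config$baseline_location[a], config$baseline_scale[a])
  }
  sig <- sig * ifelse(latent == 1L, config$seropos_fold, 1)
  sig <- sig + config$batch_offset

  ann <- tibble::tibble(sample = samples, patient = patients, group = groups,
                        timepoint = "inclusion", event = "none")

  assoc_truth <- list()
  for (pa in config$planted_associations) {
    s <- as.integer(rowSums(latent[, pa$antigens, drop = FALSE]) > 0)
    if (pa$kind == "binary") {
      odds0 <- pa$baseline / (1 - pa$baseline)
      p1 <- (pa$effect * odds0) / (1 + pa$effect * odds0)
      ann[[pa$feature]] <- rbinom(n, 1L, ifelse(s == 1L, p1, pa$baseline))
    } else {
      ann[[pa$feature]] <- rnorm(n) + pa$effect * s
    }
    assoc_truth[[length(assoc_truth) + 1L]] <- tibble::tibble(
      antigen = antigens[pa$antigens], feature = pa$feature,
      kind = pa$kind, effect = pa$effect)
  }
  if (config$n_null_binary > 0) {
    for (j in seq_len(config$n_null_binary)) {
      ann[[paste0("bin_f", j)]] <- rbinom(n, 1L, config$binary_rate)
    }
  }
  if (config$n_null_continuous > 0) {
    for (j in seq_len(config$n_null_continuous)) {
      ann[[paste0("cont_f", j)]] <- rnorm(n)
    }
  }

  true_prev <- tibble::as_tibble(expand.grid(
    antigen = antigens, group = unique(groups),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  true_prev$prevalence <- mapply(function(a, g) {
    mean(latent[groups == g, a])
  }, true_prev$antigen, true_prev$group)

  truth <- list(
    latent = signals_from_matrix(latent),
    prevalence = true_prev,
    associations = if (length(assoc_truth)) dplyr::bind_rows(assoc_truth)
                   else tibble::tibble(antigen = character(), feature = character(),
                                       kind = character(), effect = numeric()),
    config = config
  )

  structure(list(signals = sero_signals(signals_from_matrix(sig),
                                        assay = "bead", channel = "IgG"),
                 annotation = ann, truth = truth),
            class = "sero_cohort")
}

#' Generate a paired second-timepoint call matrix
#'
#' Flips each negative call to positive with probability
#' `conversion_rates["pos"]` and each positive call to negative with
#' probability `conversion_rates["neg"]`, independently per patient and
#' antigen, emulating paired longitudinal sampling.
#'
#' @param config A [sim_config()]; supplies the conversion rates and seed.
#' @param calls_t0 Baseline call matrix (wide 0/1 table with `sample` column).
#' @return The follow-up call matrix, with a `truth` attribute recording every
#'   flip (`sample`, `antigen`, `direction`).
#' @export
generate_longitudinal <- function(config, calls_t0) {
  stopifnot(inherits(config, "sim_config"))
  calls_t0 <- check_signal_table(calls_t0, allow_negative = FALSE, binary = TRUE)
  rates <- config$conversion_rates
  # operation-specific stream: keeps flip draws independent of anything the
  # same seed generated upstream
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  m0 <- signal_matrix(calls_t0)
  u <- matrix(runif(length(m0)), nrow(m0), ncol(m0))
  m1 <- m0
  m1[m0 == 0 & u < rates[["pos"]]] <- 1
  m1[m0 == 1 & u < rates[["neg"]]] <- 0
  out <- signals_from_matrix(m1)
  flips <- which(m1 != m0, arr.ind = TRUE)
  attr(out, "truth") <- tibble::tibble(
    sample = rownames(m0)[flips[, 1]],
    antigen = colnames(m0)[flips[, 2]],
    direction = ifelse(m0[flips] == 0, "pos", "neg"))
  attr(out, "conversion_rates") <- rates
  out
}

#' Generate an expression atlas with planted specificity categories
#'
#' Builds a genes-by-tissues TPM table such that the four-fold
#' specificity rules of [classify_specificity()] recover each planted label
#' exactly. Value patterns keep a safety margin around every four-fold
#' boundary so jitter never flips a category.
#'
#' @param n_genes Number of genes; must equal `length(planted_labels)` when
#'   both are given.
#' @param tissues Character vector of at least 3 tissue (or cell-type) names.
#' @param planted_labels Character vector of categories drawn from
#'   `"tissue enriched"`, `"group enriched"`, `"tissue enhanced"`,
#'   `"low tissue specificity"`, `"not detected"`.
#' @param mode `"tissue"` (group sizes 2-5) or `"cell_type"` (group sizes
#'   2-10).
#' @param seed Integer seed.
#' @return A list: `expression` (tibble with `gene` column plus one TPM column
#'   per tissue) and `truth` (tibble `gene`, `category`, `target` with
#'   semicolon-separated target tissues).
#' @export
generate_expression_atlas <- function(n_genes = length(planted_labels), tissues,
                                      planted_labels,
                                      mode = c("tissue", "cell_type"),
                                      seed = 1L) {
  mode <- match.arg(mode)
  T <- length(tissues)
  if (T < 3) abort("need at least 3 tissues")
  if (anyDuplicated(tissues)) abort("duplicated tissue names")
  valid <- c("tissue enriched", "group enriched", "tissue enhanced",
             "low tissue specificity", "not detected")
  if (!all(planted_labels %in% valid)) {
    abort(paste("labels must be one of:", paste(valid, collapse = ", ")))
  }
  if (n_genes != length(planted_labels)) {
    abort("`n_genes` must match `length(planted_labels)`")
  }
  max_group <- min(if (mode == "tissue") 5L else 10L, T - 1L)
  if (max_group < 2 && "group enriched" %in% planted_labels) {
    abort("`group enriched` is unreachable with so few tissues")
  }
  set.seed(seed)

  expr <- matrix(0, n_genes, T,
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)), tissues))
  target <- character(n_genes)
  for (i in seq_len(n_genes)) {
    lab <- planted_labels[i]
    if (lab == "not detected") {
      expr[i, ] <- runif(T, 0, 0.5)
      target[i] <- ""
    } else if (lab == "low tissue specificity") {
      expr[i, ] <- runif(T, 4, 6)
      target[i] <- ""
    } else if (lab == "tissue enriched") {
      t <- sample.int(T, 1)
      row <- runif(T, 0.5, 10)
      row[t] <- runif(1, 48, 60)
      expr[i, ] <- row
      target[i] <- tissues[t]
    } else if (lab == "group enriched") {
      g <- if (max_group == 2L) 2L else sample(2:max_group, 1)
      members <- sample.int(T, g)
      row <- runif(T, 0.5, 8)
      row[members] <- runif(g, 40, 44)
      expr[i, ] <- row
      target[i] <- paste(tissues[sort(members)], collapse = ";")
    } else { # tissue enhanced
      # fixed shape with margins on both sides of every four-fold rule,
      # scaled by a common factor (the rules are scale invariant)
      shape <- if (T == 3) c(12, 3.5, 2.2) else c(12, 4, 2.5, rep(2, T - 3))
      perm <- sample.int(T, T)
      row <- numeric(T)
      row[perm] <- shape
      expr[i, ] <- row * runif(1, 1, 3)
      target[i] <- tissues[perm[1]]
    }
  }
  expression <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(expr)),
    tibble::as_tibble(as.data.frame(expr, check.names = FALSE)))
  truth <- tibble::tibble(gene = rownames(expr), category = planted_labels,
                          target = target)
  list(expression = expression, truth = truth)
}

#' Pool member serum signals into group-level pooled signals
#'
#' Models pooling as the arithmetic mean of member signals: one positive donor
#' in a pool of size *g* contributes its excess titer diluted by *g*, which is
#' exactly the dilution arithmetic behind the minimum detectable prevalence of
#' `100/g` percent.
#'
#' @param member_signals Signal table of individual donors.
#' @param groups Named list mapping pool name to member sample ids (each pool
#'   needs at least 2 distinct members present in `member_signals`).
#' @return Pooled signal table, one row per pool, same antigen columns and
#'   assay/channel metadata as the input.
#' @export
pool_samples <- function(member_signals, groups) {
  member_signals <- check_signal_table(member_signals, allow_negative = TRUE)
  if (!length(groups)) abort("no pool groups given")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named list of member sample ids")
  }
  m <- signal_matrix(member_signals)
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (!length(members)) abort(paste0("pool `", g, "` is empty"))
    if (length(members) < 2) abort(paste0("pool `", g, "` has fewer than 2 members"))
    if (anyDuplicated(members)) {
      abort(paste0("pool `", g, "` lists a member twice: ",
                   members[duplicated(members)][1]))
    }
    miss <- first_missing(members, rownames(m))
    if (!is.null(miss)) abort(paste0("pool `", g, "` member not found: ", miss))
    colMeans(m[members, , drop = FALSE])
  })
  pooled <- do.call(rbind, rows)
  rownames(pooled) <- names(groups)
  signals_from_matrix(pooled, assay = attr(member_signals, "assay"),
                      channel = attr(member_signals, "channel"))
}

#' Minimum within-group prevalence detectable by a pooled screen
#'
#' A pool of `group_size` donors contains at least `min_positive` seropositive
#' members only when the within-group prevalence is at least
#' `min_positive / group_size`; with pools of 8 a single positive donor
#' corresponds to a prevalence of 12.5%.
#'
#' @param group_size Number of donors per pool.
#' @param min_positive Minimum number of seropositive donors the pool must
#'   contain.
#' @return The prevalence as a percentage.
#' @export
min_detectable_prevalence <- function(group_size, min_positive = 1) {
  group_size <- check_scalar_count(group_size, "group_size")
  min_positive <- check_scalar_count(min_positive, "min_positive")
  if (min_positive > group_size) {
    abort("`min_positive` cannot exceed `group_size`")
  }
  100 * min_positive / group_size
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `signals.tsv`, `annotation.tsv` and `truth.json` (latent matrix,
#' true prevalences and planted associations) into a directory.
#'
#' @param cohort A `sero_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sero_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(cohort$signals, file.path(dir, "signals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$planted_associations <-
    lapply(truth$config$planted_associations, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
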