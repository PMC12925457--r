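# vectors realizing the 2x2 table [[a, b], [c, d]] of call x feature
table_vectors <- function(a, b, c, d) {
  list(call = c(rep(1, a + b), rep(0, c + d)),
       feature = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

test_that("chi-squared matches the closed Pearson and Yates formulas", {
  tv <- table_vectors(30, 10, 10, 30)
  raw <- test_binary(tv$call, tv$feature, correct = FALSE)
  yat <- test_binary(tv$call, tv$feature, correct = TRUE)
  expect_equal(raw$statistic, 20.0, tolerance = 1e-12)
  expect_equal(yat$statistic, 18.05, tolerance = 1e-12)
  expect_equal(raw$p, oracle_chisq(30, 10, 10, 30)$p, tolerance = 1e-12)
  expect_equal(yat$p, oracle_chisq(30, 10, 10, 30, yates = TRUE)$p,
               tolerance = 1e-12)

  flat <- table_vectors(10, 10, 10, 10)
  r <- test_binary(flat$call, flat$feature, correct = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("uncorrected chi-squared equals N phi^2 and is swap invariant", {
  set.seed(10)
  for (i in 1:50) {
    t <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    tv <- table_vectors(t[1], t[2], t[3], t[4])
    r <- test_binary(tv$call, tv$feature, correct = FALSE)
    if (!r$tested) next
    phi2 <- (t[1] * t[4] - t[2] * t[3])^2 /
      ((t[1] + t[2]) * (t[3] + t[4]) * (t[1] + t[3]) * (t[2] + t[4]))
    expect_equal(r$statistic, sum(t) * phi2, tolerance = 1e-9)
    sw <- table_vectors(t[3], t[4], t[1], t[2])   # swap rows
    expect_equal(test_binary(sw$call, sw$feature, correct = FALSE)$statistic,
                 r$statistic, tolerance = 1e-9)
  }
})

test_that("degenerate margins and all-missing features are skipped with reasons", {
  r <- test_binary(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_false(r$tested)
  expect_match(r$reason, "degenerate margin")
  r2 <- test_binary(c(1, 0, 1, 0), c(NA, NA, NA, NA))
  expect_false(r2$tested)
  expect_match(r2$reason, "no non-missing")
})

test_that("exact Mann-Whitney agrees with full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- round(rnorm(n1), if (i %% 2) 3 else 0)   # even i: heavy ties
    y <- round(rnorm(n2), if (i %% 2) 3 else 0)
    got <- mann_whitney(x, y)
    expect_equal(got$p.value, oracle_mw_exact(x, y), tolerance = 1e-9)
    # U1 + U2 = n1 * n2
    u2 <- mann_whitney(y, x)$statistic
    expect_equal(got$statistic + u2, n1 * n2, tolerance = 1e-9)
  }
})

test_that("tie-free exact Mann-Whitney reproduces wilcox.test", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal path", {
  set.seed(13)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.4), 1)
  got <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_match(got$method, "normal")
})

test_that("continuous test reports medians, fold change and direction", {
  r <- test_continuous(c(1, 1, 1, 0, 0, 0), c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$median_pos, 2)
  expect_equal(r$fold_change, 2 / 5)
  expect_equal(r$direction, "lower in AAB+")

  same <- test_continuous(rep(c(1, 0), each = 4), rep(1:4, 2))
  expect_equal(same$p, 1)
  expect_equal(same$fold_change, 1)
  expect_equal(same$direction, "equal")

  r3 <- test_continuous(c(1, 1, 1, 0, 0, 0), c(3, 3, 3, 9, 9, 9))
  expect_equal(r3$fold_change, 1 / 3)

  small <- test_continuous(c(1, 1, 0, 0, 0), c(1, 2, 3, 4, 5))
  expect_false(small$tested)
  expect_match(small$reason, "arm smaller")
  empty <- test_continuous(rep(0, 6), 1:6)
  expect_false(empty$tested)
  expect_match(empty$reason, "empty arm")
})

make_cohort_calls <- function(n_cases = 250, n_healthy = 120, n_antigens = 30,
                              prevalence = 0.12, assoc = list(),
                              blocks = list(), seed = 1) {
  cfg <- sim_config(n_cases = n_cases, n_healthy = n_healthy,
                    n_disease_controls = 2, n_antigens = n_antigens,
                    planted_prevalence = prevalence,
                    planted_associations = assoc, antigen_blocks = blocks,
                    n_null_binary = 2, n_null_continuous = 2, seed = seed)
  co <- generate_cohort(cfg)
  healthy <- co$signals[co$annotation$group == "HD", ]
  norm <- normalize_signals(co$signals, reference = healthy$sample)
  cuts <- fit_cutoffs(norm[norm$sample %in% healthy$sample, ], 0.99)
  cases <- co$annotation$group == "PSC"
  list(calls = call_positivity(norm[cases, ], cuts),
       annotation = co$annotation[cases, ], truth = co$truth)
}

test_that("a one-antigen one-feature atlas reduces to the single test", {
  cc <- make_cohort_calls(n_antigens = 4, seed = 21)
  calls1 <- cc$calls[, c("sample", "ag0001")]
  atlas <- build_atlas(calls1, cc$annotation, c(bin_f1 = "binary"))
  expect_equal(nrow(atlas), 1)
  direct <- test_binary(calls1$ag0001,
                        cc$annotation$bin_f1[match(calls1$sample,
                                                   cc$annotation$sample)])
  expect_equal(atlas$p, direct$p)
  expect_equal(atlas$statistic, direct$statistic)

  expect_error(build_atlas(calls1, cc$annotation, c(bin_f1 = "ordinal")),
               "binary")
  expect_error(build_atlas(calls1, cc$annotation, c(nope = "binary")),
               "nope")
})

test_that("a planted association dominates its feature's p-values", {
  pa <- planted_association(1, "cirr", "binary", effect = 8)
  cc <- make_cohort_calls(n_cases = 400, n_antigens = 25, prevalence = 0.1,
                          assoc = list(pa), seed = 22)
  atlas <- build_atlas(cc$calls, cc$annotation,
                       c(cirr = "binary", bin_f1 = "binary"))
  cirr <- atlas[atlas$feature == "cirr", ]
  expect_equal(cirr$antigen[which.min(cirr$p)], "ag0001")
  expect_lt(min(cirr$p, na.rm = TRUE), 1e-4)
})

test_that("Ward clustering groups identical profiles and planted blocks", {
  p <- tibble::tibble(
    antigen = rep(c("a1", "a2", "a3"), each = 2),
    feature = rep(c("f1", "f2"), 3),
    p = c(1e-6, 0.5, 1e-6, 0.5, 0.5, 1e-6),
    tested = TRUE)
  class(p) <- c("sero_atlas", class(p))
  cl <- cluster_atlas(p, 2)
  expect_equal(cl$cluster[cl$antigen == "a1"], cl$cluster[cl$antigen == "a2"])
  expect_false(cl$cluster[cl$antigen == "a1"] == cl$cluster[cl$antigen == "a3"])
  # the identical pair merges at height 0
  expect_equal(min(attr(cl, "heights")), 0)
  expect_error(cluster_atlas(p, 4), "exceeds")

  # input order invariance
  set.seed(14)
  cl2 <- cluster_atlas(p[sample(nrow(p)), ], 2)
  expect_identical(dplyr::arrange(as.data.frame(cl), antigen)$cluster,
                   dplyr::arrange(as.data.frame(cl2), antigen)$cluster)
})

test_that("planted association blocks are recovered by clustering", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    assoc <- list(planted_association(1:5, "f1", "binary", 8),
                  planted_association(6:10, "f2", "binary", 8),
                  planted_association(11:15, "f3", "continuous", 1.5))
    blocks <- lapply(list(1:5, 6:10, 11:15), function(a)
      list(antigens = a, prevalence = 0.15))
    cc <- make_cohort_calls(n_cases = 350, n_antigens = 15, prevalence = 0.15,
                            assoc = assoc, blocks = blocks, seed = 100 + s)
    atlas <- build_atlas(cc$calls, cc$annotation,
                         c(f1 = "binary", f2 = "binary", f3 = "continuous"))
    cl <- cluster_atlas(atlas, 3)
    truth <- rep(1:3, each = 5)[match(cl$antigen, sprintf("ag%04d", 1:15))]
    mclust::adjustedRandIndex(cl$cluster, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("top-per-cluster panels are capped at six with deterministic ties", {
  atl <- tibble::tibble(
    antigen = sprintf("ag%02d", 1:13),
    feature = "f",
    p = c(rep(0.001, 3), rep(0.02, 7), 0.5, 0.5, 0.5),
    tested = c(rep(TRUE, 12), FALSE))
  class(atl) <- c("sero_atlas", class(atl))
  cl <- tibble::tibble(antigen = atl$antigen,
                       cluster = c(rep(1, 10), 2, 2, 3))
  expect_warning(top <- top_per_cluster(atl, cl, "f", max_k = 6),
                 "no tested member")
  expect_equal(sum(top$cluster == 1), 6)
  # tie block 0.02 ranks lexicographically: ag04..ag06 kept, ag07+ dropped
  expect_setequal(top$antigen[top$cluster == 1],
                  sprintf("ag%02d", 1:6))
  expect_equal(sum(top$cluster == 2), 2)       # small cluster kept whole
  expect_error(top_per_cluster(atl, cl, "f", cluster = 3), "no tested member")
})

test_that("group-median ranking reports ratios, direction and top-k", {
  m <- cbind(agA = c(1, 1, 1, 0, 0, 0), agB = c(0, 1, 0, 1, 0, 1))
  rownames(m) <- paste0("s", 1:6)
  calls <- seroatlas:::signals_from_matrix(m)
  ann <- tibble::tibble(sample = paste0("s", 1:6),
                        duration = c(16, 16, 16, 8, 8, 8))
  expect_warning(rk <- rank_by_group_median(calls, ann, "duration", top_k = 10),
                 "testable")
  a <- rk[rk$antigen == "agA", ]
  expect_equal(a$ratio, 2.0)
  expect_equal(a$direction, "higher in AAB+")
  expect_equal(nrow(rank_by_group_median(calls, ann, "duration", top_k = 0)), 0)
})

test_that("late-stage planted antigens rank as higher-duration", {
  # antigens positive mostly in long-duration simulants
  set.seed(31)
  n <- 300
  duration <- rexp(n, 1 / 8)
  m <- sapply(1:20, function(a) {
    p <- ifelse(duration > stats::median(duration), 0.25, 0.03)
    rbinom(n, 1, p)
  })
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("ag%02d", 1:20))
  calls <- seroatlas:::signals_from_matrix(m)
  ann <- tibble::tibble(sample = rownames(m), duration = duration)
  rk <- rank_by_group_median(calls, ann, "duration", top_k = 20)
  expect_gte(mean(rk$direction == "higher in AAB+"), 0.9)
})

test_that("event comparison keeps event-proximal and event-free inclusion samples", {
  ann <- tibble::tibble(
    sample = paste0("s", 1:5),
    patient = c("p1", "p1", "p2", "p3", "p4"),
    timepoint = c("inclusion", "event", "inclusion", "inclusion", "event"),
    event = c("none", "transplantation", "none", "none", "HB cancer"))
  sub <- event_analysis_samples(ann)
  expect_setequal(sub$sample, c("s2", "s3", "s4", "s5"))
  expect_equal(sum(sub$event_proximal), 2)
})
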