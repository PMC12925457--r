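# Independent brute-force oracles used across the suite. These deliberately
# take different computational routes than the package implementations.

# Pearson / Yates chi-squared on a 2x2 by the closed formulas
oracle_chisq <- function(a, b, c, d, yates = FALSE) {
  N <- a + b + c + d
  det <- abs(a * d - b * c)
  if (yates) det <- max(0, det - N / 2)
  num <- N * det^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- num / den
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# exact two-sided Mann-Whitney p by enumeration; U counted pairwise
# (1 per x > y pair, 0.5 per tie), not via ranks
oracle_mw_exact <- function(x, y) {
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  uall <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  u <- u_of(x, y)
  min(1, 2 * min(mean(uall <= u + 1e-9), mean(uall >= u - 1e-9)))
}

# Altman OR / SE / CI by direct evaluation
oracle_or <- function(a, b, c, d, level = 0.95) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  list(or = or, se = se, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       p = 2 * pnorm(abs(log(or) / se), lower.tail = FALSE))
}

# hypergeometric upper tail by explicit summation of choose() terms
oracle_hyper <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force specificity classifier: enumerates every tissue subset of
# allowed size for the group rule; `targets` lists every qualifying minimal
# group (tied values can make several equally valid)
oracle_classify <- function(v, tissues, max_group, detection_limit = 1) {
  T <- length(v)
  if (max(v) < detection_limit) {
    return(list(category = "not detected", targets = ""))
  }
  imax <- order(-v, tissues)[1]
  if (v[imax] >= 4 * max(v[-imax])) {
    return(list(category = "tissue enriched", targets = tissues[imax]))
  }
  for (k in 2:max_group) {
    hits <- Filter(function(cols) mean(v[cols]) >= 4 * max(v[-cols]),
                   utils::combn(T, k, simplify = FALSE))
    if (length(hits)) {
      return(list(category = "group enriched",
                  targets = vapply(hits, function(cols) {
                    paste(sort(tissues[cols]), collapse = ";")
                  }, character(1))))
    }
  }
  if (v[imax] >= 4 * mean(v[-imax])) {
    return(list(category = "tissue enhanced", targets = tissues[imax]))
  }
  list(category = "low tissue specificity", targets = "")
}

# random expression rows covering all five categories
random_expression_rows <- function(n_rows, seed) {
  set.seed(seed)
  lapply(seq_len(n_rows), function(i) {
    T <- sample(3:8, 1)
    kind <- sample(5, 1)
    v <- switch(kind,
      round(rlnorm(T, 1, 2), 2),                     # generic heavy-tailed
      { z <- round(runif(T, 0, 0.99), 2); z },        # mostly undetected
      { z <- round(runif(T, 0, 3), 1); z[sample(T, 1)] <- round(runif(1, 5, 60), 1); z },
      { z <- rep(round(runif(1, 1, 9), 1), T); z },   # flat, tie-heavy
      { z <- round(runif(T, 0, 2), 1)                 # dominant small group
        g <- sample(2:min(5, T - 1), 1)
        z[sample(T, g)] <- round(runif(g, 20, 30), 1); z })
    v
  })
}

# small random signal table
rand_signals <- function(n, p, seed = 1, prefix = "S") {
  set.seed(seed)
  m <- matrix(rlnorm(n * p, 5, 0.5), n, p,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("ag%03d", seq_len(p))))
  seroatlas:::signals_from_matrix(m)
}

# exact central binomial interval (as counts) at the given level
binom_interval <- function(n, p, level = 0.99) {
  c(qbinom((1 - level) / 2, n, p), qbinom(1 - (1 - level) / 2, n, p))
}
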