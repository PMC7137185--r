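# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: brute-force enumeration, grid search,
# and direct formula evaluation.

# exhaustive grid search over (f, Dstar) with D held fixed; returns the
# minimal residual sum of squares. RSS is quadratic in f for each
# Dstar, which lets the declared dense grid be evaluated exactly.
oracle_grid_rss <- function(signals, b, s0, D,
                            f_grid = seq(0, 1, by = 0.001),
                            ds_grid = seq(0, 0.1, by = 2e-4)) {
  E0 <- exp(-b * D)
  best <- Inf
  for (ds in ds_grid) {
    A <- signals - s0 * E0
    B <- s0 * (exp(-b * (D + ds)) - E0)
    rss <- sum(A^2) - 2 * f_grid * sum(A * B) + f_grid^2 * sum(B^2)
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# concordant-pair AUC with ties counted one half
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact r x c Fisher p by recursive enumeration of all tables with the
# observed margins (small tables only)
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logfact <- lgamma(seq_len(sum(tab) + 1))
  lf <- function(x) logfact[x + 1]
  log_prob <- function(m) sum(lf(rs)) + sum(lf(cs)) - lf(sum(m)) - sum(lf(m))
  p_obs <- log_prob(tab)
  total <- 0
  recurse <- function(row, col_left) {
    if (row == nrow(tab)) {
      m <- rbind(partial_env$rows_done, col_left)
      lp <- log_prob(m)
      if (lp <= p_obs + 1e-9) total <<- total + exp(lp)
      return(invisible())
    }
    cells <- enumerate_row(rs[row], col_left)
    for (i in seq_len(nrow(cells))) {
      partial_env$rows_done <- rbind(partial_env$rows_done, cells[i, ])
      recurse(row + 1, col_left - cells[i, ])
      partial_env$rows_done <-
        partial_env$rows_done[-nrow(partial_env$rows_done), , drop = FALSE]
    }
  }
  enumerate_row <- function(s, caps) {
    if (length(caps) == 1L) {
      if (s <= caps) return(matrix(s, 1)) else return(matrix(numeric(0), 0, 1))
    }
    out <- NULL
    for (v in 0:min(s, caps[1])) {
      rest <- enumerate_row(s - v, caps[-1])
      if (nrow(rest)) out <- rbind(out, cbind(v, rest))
    }
    if (is.null(out)) matrix(numeric(0), 0, length(caps)) else out
  }
  partial_env <- new.env()
  partial_env$rows_done <- matrix(numeric(0), 0, ncol(tab))
  recurse(1, cs)
  total
}

# Kruskal-Wallis H from the raw rank formula with tie correction
oracle_kw_h <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# consistency-type ICC(3,1) from the same mean squares, for contrast
# with the absolute-agreement form
oracle_icc_consistency <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE)
}

# Rician-corrupted decay curve for a single voxel
rician_curve <- function(s_true, sigma) {
  n <- length(s_true)
  sqrt((s_true + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

# small phantom spec used by several fixture-hungry tests
tiny_phantom <- function(snr = Inf, shape = c(8, 8, 2)) {
  phantom_spec(shape = shape, centre = (shape + 1) / 2,
               semi_axes = c(2.6, 2.6, 0.9), snr = snr)
}
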