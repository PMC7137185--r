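#' Kruskal-Wallis rank test across nodal groups
#'
#' Rank-based omnibus comparison of a feature across two or more
#' patient groups, with the usual tie correction; the p-value comes
#' from the chi-square approximation with k - 1 degrees of freedom
#' (via [stats::kruskal.test]). The fully degenerate case in which
#' every pooled observation is tied is returned as H = 0, p = 1 with
#' `degenerate = TRUE` instead of propagating 0/0.
#'
#' @param groups A list of numeric vectors, one per group, each
#'   non-empty.
#' @return An object of class `"htest"` with an extra `degenerate`
#'   element.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_groups = 2L)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    out <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                parameter = c(df = length(groups) - 1L), p.value = 1,
                method = "Kruskal-Wallis rank sum test (degenerate: all values tied)",
                data.name = "groups", degenerate = TRUE)
    class(out) <- "htest"
    return(out)
  }
  ht <- stats::kruskal.test(groups)
  ht$degenerate <- FALSE
  ht
}

check_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop(sprintf("need a list of at least %d groups", min_groups), call. = FALSE)
  n <- vapply(groups, length, 0L)
  if (any(n == 0L)) stop("every group must be non-empty", call. = FALSE)
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("group values must be finite", call. = FALSE)
  invisible(n)
}

#' Nemenyi all-pairs post-hoc test
#'
#' Pairwise rank comparisons after a Kruskal-Wallis omnibus test.
#' For groups i and j the statistic is the difference of mean ranks
#' scaled by `sqrt(C * N(N+1)/12 * (1/n_i + 1/n_j))`, where C is the
#' tie-correction factor `1 - sum(t^3 - t)/(N^3 - N)`, referred to the
#' studentized range distribution with k means and infinite degrees of
#' freedom (large-sample approximation, valid for equal or unequal
#' group sizes). If all rank means coincide (e.g. identical groups)
#' every pairwise p is 1 by construction.
#'
#' @param groups A list of at least 3 numeric vectors.
#' @return An object of class `"nemenyi_test"`: symmetric matrix
#'   `p.value` with unit diagonal, matrix `statistic`, and the mean
#'   ranks.
#' @export
nemenyi_pairwise <- function(groups) {
  n <- check_groups(groups, min_groups = 3L)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_len(k), times = n)
  rbar <- tapply(r, g, mean)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  stat <- p <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  diag(p) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      se2 <- C * N * (N + 1) / 12 * (1 / n[i] + 1 / n[j])
      q <- if (se2 > 0) abs(rbar[i] - rbar[j]) / sqrt(se2) else 0
      pv <- if (q == 0) 1 else stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                                             lower.tail = FALSE)
      stat[i, j] <- stat[j, i] <- q
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(statistic = stat, p.value = p, mean_ranks = rbar,
                 method = "Nemenyi all-pairs rank comparison (studentized range)"),
            class = "nemenyi_test")
}

#' @export
print.nemenyi_test <- function(x, ...) {
  cat(x$method, "\n\nPairwise p-values:\n")
  print(signif(x$p.value, 4))
  invisible(x)
}

#' Fisher's exact test for r x c contingency tables
#'
#' Exact association test for counts. 2 x 2 tables use the classical
#' two-sided definition (sum of hypergeometric probabilities of tables
#' no more probable than the observed one). Larger tables are
#' enumerated exactly while the grand total is at most `exact_max`;
#' beyond that a Monte-Carlo p-value with a fixed seed and a reported
#' replicate count is returned. Tables with a zero margin carry no
#' information about association and return p = 1, flagged degenerate.
#'
#' @param x A matrix of non-negative integer counts, at least 2 x 2.
#' @param exact_max Largest grand total fitted exactly (default 40).
#' @param B Monte-Carlo replicates for large tables.
#' @param seed Seed for the Monte-Carlo mode.
#' @return An `"htest"` with extra elements `degenerate`, `simulated`
#'   and (when simulated) `B`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # p = 2/252
#' @export
fisher_exact <- function(x, exact_max = 40, B = 10000L, seed = 1L) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    out <- list(p.value = 1, method = "Fisher's exact test (degenerate: zero margin)",
                data.name = "x", degenerate = TRUE, simulated = FALSE)
    class(out) <- "htest"
    return(out)
  }
  simulate <- sum(x) > exact_max && (nrow(x) > 2L || ncol(x) > 2L)
  ht <- if (simulate) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    stats::fisher.test(x, simulate.p.value = TRUE, B = B)
  } else {
    stats::fisher.test(x)
  }
  ht$degenerate <- FALSE
  ht$simulated <- simulate
  if (simulate) ht$B <- B
  ht
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Interobserver agreement: two-way random-effects ICC
#'
#' Single-rater, absolute-agreement intraclass correlation, ICC(2,1),
#' from the standard two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects and k raters. The agreement band follows the usual
#' reliability guideline: below 0.50 poor, 0.50-0.75 moderate,
#' 0.75-0.90 good, above 0.90 excellent (boundaries 0.50, 0.75 and
#' 0.90 fall in the lower band).
#'
#' @param ratings Numeric matrix or data frame, one row per subject,
#'   one column per rater (n >= 3 subjects, no missing values).
#' @return An object of class `"icc_estimate"` with elements `icc`,
#'   `band`, the mean squares, `n`, `k`, and `defined` (FALSE when
#'   both raters are constant, where the ICC is undefined).
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  defined <- denom > 0
  icc <- if (defined) (MSR - MSE) / denom else NA_real_
  structure(list(icc = icc, band = if (defined) icc_band(icc) else NA_character_,
                 MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k,
                 defined = defined),
            class = "icc_estimate")
}

icc_band <- function(icc) {
  if (icc > 0.90) "excellent"
  else if (icc > 0.75) "good"
  else if (icc >= 0.50) "moderate"
  else "poor"
}

#' @export
print.icc_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("ICC(2,1): undefined (no between-subject variance)\n")
  } else {
    cat(sprintf("ICC(2,1) absolute agreement: %.3f (%s), n = %d subjects, k = %d raters\n",
                x$icc, x$band, x$n, x$k))
  }
  invisible(x)
}

#' Group-association table for the cohort features
#'
#' Runs the Kruskal-Wallis test of each feature across the nodal
#' groups and returns a tidy table (one row per feature: group means
#' and SDs, the H statistic and the unadjusted p-value, mirroring the
#' usual parameter-by-group layout). No multiple-testing correction is
#' applied across features; p-values are reported raw.
#'
#' @param cohort A cohort data frame (see [simulate_cohort]).
#' @param features Feature column names to test.
#' @param group Name of the grouping column.
#' @return A data frame, plus the per-feature [nemenyi_pairwise]
#'   results in attribute `"nemenyi"`.
#' @export
cohort_association_stats <- function(cohort,
                                     features = c("dtv", "adc", "d", "f"),
                                     group = "group") {
  stopifnot(is.data.frame(cohort), group %in% names(cohort),
            all(features %in% names(cohort)))
  g <- factor(cohort[[group]])  # unused levels drop: only observed groups are tested
  if (nlevels(g) < 2L) stop("need at least 2 observed groups", call. = FALSE)
  rows <- list(); nem <- list()
  for (feat in features) {
    by_g <- split(cohort[[feat]], g)
    kw <- kruskal_wallis(by_g)
    nem[[feat]] <- if (nlevels(g) >= 3L) nemenyi_pairwise(by_g)
    means <- vapply(by_g, mean, 0); sds <- vapply(by_g, stats::sd, 0)
    row <- data.frame(feature = feat, t(means), t(sds),
                      statistic = unname(kw$statistic), p.value = kw$p.value)
    names(row) <- c("feature", paste0("mean_", levels(g)), paste0("sd_", levels(g)),
                    "statistic", "p.value")
    rows[[feat]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nemenyi") <- nem
  out
}
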