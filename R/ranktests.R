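# Exact rank tests with midrank tie handling.
#
# Both tests enumerate the exact conditional null distribution of the
# rank statistic given the observed (mid)ranks, via dynamic programming on
# doubled ranks (midranks are multiples of 1/2, so doubling gives integers).
# Above `exact_max` observations they fall back to the normal approximation
# with tie-corrected variance and continuity correction.

# distribution of the signed-rank statistic W+ = sum of ranks with + sign,
# over all 2^m sign assignments; returns counts indexed by doubled sum 0..S2
signed_rank_counts <- function(r2) {
  S2 <- sum(r2)
  dp <- numeric(S2 + 1)
  dp[1] <- 1
  for (a in r2) {
    shifted <- c(numeric(a), dp[seq_len(S2 + 1 - a)])
    dp <- dp + shifted
  }
  dp
}

#' Wilcoxon signed-rank test on paired samples
#'
#' Two-sided test on the paired differences `x - y`. Zero differences are
#' dropped (Wilcoxon convention); ties among absolute differences get
#' midranks. Exact when the number of nonzero differences is at most
#' `exact_max` (full enumeration of sign assignments, valid under ties);
#' otherwise normal approximation with continuity correction, where the
#' midranks carry the tie correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest number of nonzero pairs for the exact path.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `n_nonzero`, and `exact` (logical). `p_value` is `NA` when every
#'   difference is zero.
#' @export
signed_rank_test <- function(x, y, exact_max = 20) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(r2)
    tot <- 2^m
    W2 <- as.integer(round(2 * W))
    p_lo <- sum(counts[seq_len(W2 + 1)]) / tot
    p_hi <- sum(counts[(W2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, p_value = p, n_nonzero = m, exact = TRUE))
  }
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  if (sigma == 0)
    return(list(statistic = W, p_value = 1, n_nonzero = m, exact = FALSE))
  z <- (W - mu - sign(W - mu) * 0.5) / sigma
  list(statistic = W, p_value = 2 * stats::pnorm(-abs(z)), n_nonzero = m,
       exact = FALSE)
}

# distribution of the rank-sum of group a: dp[k+1, s+1] = number of ways to
# pick k of the doubled ranks summing to s
rank_sum_counts <- function(r2, na) {
  S2 <- sum(r2)
  dp <- matrix(0, nrow = na + 1, ncol = S2 + 1)
  dp[1, 1] <- 1
  for (a in r2) {
    for (k in rev(seq_len(na))) {
      src <- dp[k, seq_len(S2 + 1 - a)]
      dp[k + 1, (a + 1):(S2 + 1)] <- dp[k + 1, (a + 1):(S2 + 1)] + src
    }
  }
  dp[na + 1, ]
}

#' Mann-Whitney U test on two independent samples
#'
#' Two-sided rank-sum test with midranks for ties. Exact when the combined
#' sample size is at most `exact_max` (enumeration of all rank splits,
#' conditional on the observed tie pattern); otherwise normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined size for the exact path.
#' @return List with `statistic` (U for sample `a`), `rank_sum` (W of `a`),
#'   `p_value`, `direction` (+1 if `a` ranks higher on average, -1 lower,
#'   0 tie), and `exact`.
#' @export
mann_whitney_test <- function(a, b, exact_max = 20) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0)
    stop("both samples must be nonempty", call. = FALSE)
  n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  dir <- sign(mean(r[seq_len(na)]) - mean(r[na + seq_len(nb)]))
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- rank_sum_counts(r2, na)
    tot <- choose(n, na)
    W2 <- as.integer(round(2 * W))
    p_lo <- sum(counts[seq_len(W2 + 1)]) / tot
    p_hi <- sum(counts[(W2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = U, rank_sum = W, p_value = p, direction = dir,
                exact = TRUE))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  if (sigma == 0)
    return(list(statistic = U, rank_sum = W, p_value = 1, direction = dir,
                exact = FALSE))
  z <- (W - mu - sign(W - mu) * 0.5) / sigma
  list(statistic = U, rank_sum = W, p_value = 2 * stats::pnorm(-abs(z)),
       direction = dir, exact = FALSE)
}
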