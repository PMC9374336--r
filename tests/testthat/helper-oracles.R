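# Independent brute-force oracles used across the suite.  These stay naive
# on purpose: they must not share code paths with the implementation.

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exhaustive shuffled transient-change distribution: every ordering of the
# intertransient intervals, reconstructed from the first event's offset
enumerate_shuffled_changes <- function(times, boundary, total) {
  times <- sort(times)
  d <- diff(times)
  if (length(d) < 1) stop("need >= 2 events")
  P <- all_perms(length(d))
  apply(P, 1, function(o) {
    tms <- times[1] + cumsum(c(0, d[o]))
    tms <- tms[tms < total]
    sum(tms >= boundary) - sum(tms < boundary)
  })
}

# total-variation distance between two empirical distributions on integers
tv_distance <- function(a, b) {
  vals <- sort(union(unique(a), unique(b)))
  pa <- tabulate(match(a, vals), length(vals)) / length(a)
  pb <- tabulate(match(b, vals), length(vals)) / length(b)
  0.5 * sum(abs(pa - pb))
}

# exact two-sided signed-rank p by direct enumeration of sign assignments
naive_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= W + 1e-12), mean(ws >= W - 1e-12)))
}

# exact two-sided Mann-Whitney p by direct enumeration of group splits
naive_mann_whitney_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  splits <- utils::combn(n, na)
  ws <- apply(splits, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= W + 1e-12), mean(ws >= W - 1e-12)))
}

# deconvolution objective in spike space
deconv_objective <- function(y, s, gamma, lambda) {
  cfit <- as.numeric(stats::filter(s, gamma, method = "recursive"))
  0.5 * sum((y - cfit)^2) + lambda * sum(s)
}

# global optimum by exhaustive active-set enumeration (n <= 12 frames):
# the solution of the nonnegative LASSO-type QP has some support set; try
# them all and keep the best feasible candidate
brute_force_deconv_exhaustive <- function(y, gamma, lambda = 0) {
  n <- length(y)
  G <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(i >= j, gamma^(i - j), 0))
  best <- list(obj = 0.5 * sum(y^2), s = numeric(n))  # empty support
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    GS <- G[, S, drop = FALSE]
    M <- crossprod(GS)
    rhs <- crossprod(GS, y) - lambda
    sS <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sS) || any(sS < 0)) next
    s <- numeric(n); s[S] <- sS
    obj <- 0.5 * sum((y - GS %*% sS)^2) + lambda * sum(sS)
    if (obj < best$obj) best <- list(obj = obj, s = s)
  }
  best
}

# near-optimal reference by bound-constrained quasi-Newton (any n)
brute_force_deconv_lbfgsb <- function(y, gamma, lambda = 0) {
  n <- length(y)
  G <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(i >= j, gamma^(i - j), 0))
  fn <- function(s) 0.5 * sum((y - G %*% s)^2) + lambda * sum(s)
  gr <- function(s) as.numeric(crossprod(G, G %*% s - y)) + lambda
  fit <- stats::optim(rep(0, n), fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 5000, factr = 10))
  list(obj = fit$value, s = fit$par)
}

# match detected to true event times within a frame tolerance (greedy 1-1)
match_events <- function(truth, detected, tol) {
  used <- logical(length(detected))
  hits <- 0L
  for (t in truth) {
    j <- which(!used & abs(detected - t) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; hits <- hits + 1L }
  }
  hits
}
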