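# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity from first principles, not via the package's own
# code paths.

# rank of each distinct positive value by the literal double loop
# r_i = sum_j I(X_j >= z_i)
oracle_zipf <- function(counts) {
  values <- sort(unique(counts[counts > 0]), decreasing = TRUE)
  ranks <- vapply(values, function(z) sum(counts >= z), numeric(1))
  freqs <- vapply(values, function(z) sum(counts == z), numeric(1))
  list(values = values, freqs = freqs, ranks = ranks)
}

# closed-form simple OLS of y on x via the textbook normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# closed-form two-predictor OLS (intercept + x1 + x2) by solving the
# normal equations directly
oracle_ols2 <- function(x1, x2, y) {
  A <- cbind(1, x1, x2)
  drop(solve(crossprod(A), crossprod(A, y)))
}

# exhaustive two-sample KS statistic over every pooled jump point
oracle_ks <- function(x, y) {
  ts <- sort(unique(c(x, y)))
  max(vapply(ts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# trimmed mean of log ratios by explicit sort-and-slice
oracle_tmm_sigma <- function(target, reference, trim = 0.3) {
  keep <- !(target == 0 & reference == 0)
  m <- sort(log(target[keep] / reference[keep]))
  k <- floor(length(m) * trim)
  exp(mean(m[(k + 1):(length(m) - k)]))
}

# a profile whose Zipf plot is an exact straight line:
# distinct values z_i with rank i satisfying log(i) = c + s * log(z_i)
exact_powerlaw_profile <- function(m = 50, slope = -1.7, intercept = 8,
                                   n_zero = 0) {
  z <- exp((log(seq_len(m)) - intercept) / slope)
  c(z, rep(0, n_zero))
}

# zero-inflated integer profile for rank oracle checks (many ties)
random_count_profile <- function(n, zero_fraction = 0.6) {
  x <- rpois(n, 4)
  x[runif(n) < zero_fraction] <- 0
  if (all(x == 0)) x[1] <- 1
  x
}
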