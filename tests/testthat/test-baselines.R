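make_pair <- function(n = 400, zero_fraction = 0.4, seed = 1) {
  set.seed(seed)
  ref <- rpois(n, 20)
  ref[runif(n) < zero_fraction] <- 0
  tgt <- rpois(n, 35)
  tgt[runif(n) < zero_fraction] <- 0
  list(target = tgt, reference = ref)
}

test_that("every baseline returns sigma = 1 for self and c for exact multiples", {
  p <- make_pair()
  for (m in c("tc", "med", "uq", "tmm", "rle")) {
    expect_equal(baseline_factor(m, p$reference, p$reference)$sigma, 1,
                 info = m)
    out <- baseline_factor(m, 2 * p$reference, p$reference)
    expect_equal(out$sigma, 2, tolerance = 1e-12, info = m)
    expect_equal(out$gamma, 1)
  }
})

test_that("TMM and RLE factors match the sort-and-slice brute force", {
  for (seed in 1:5) {
    p <- make_pair(seed = seed, zero_fraction = 0.2)
    expect_equal(baseline_factor("tmm", p$target, p$reference)$sigma,
                 oracle_tmm_sigma(p$target, p$reference, 0.3))
    keep <- !(p$target == 0 & p$reference == 0)
    m <- log(p$target[keep] / p$reference[keep])
    expect_equal(baseline_factor("rle", p$target, p$reference)$sigma,
                 exp(median(m)))
  }
  # forced either-zero policy against a positives-only slice oracle
  p <- make_pair(seed = 7, zero_fraction = 0.4)
  both_pos <- p$target > 0 & p$reference > 0
  m <- sort(log(p$target[both_pos] / p$reference[both_pos]))
  k <- floor(length(m) * 0.3)
  expect_equal(
    baseline_factor("tmm", p$target, p$reference,
                    zero_policy = "either_zero")$sigma,
    exp(mean(m[(k + 1):(length(m) - k)])))
})

test_that("all five factors are scale-consistent under c * target", {
  p <- make_pair(seed = 3)
  for (m in c("tc", "med", "uq", "tmm", "rle")) {
    s1 <- baseline_factor(m, p$target, p$reference)$sigma
    s2 <- baseline_factor(m, 2.5 * p$target, p$reference)$sigma
    expect_equal(s2, 2.5 * s1, tolerance = 1e-12, info = m)
  }
})

test_that("TMM with zero trim is the plain mean of M-values", {
  p <- make_pair(seed = 9, zero_fraction = 0)
  m <- log(p$target / p$reference)
  expect_equal(baseline_factor("tmm", p$target, p$reference,
                               trim_fraction = 0)$sigma,
               exp(mean(m)))
})

test_that("the zero-handling cascade falls back from both-zero to either-zero", {
  # median of the target is 0 after dropping only both-zero genes,
  # but positive after dropping genes zero in either profile
  target <- c(0, 0, 0, 0, 0, 4, 6, 8)
  reference <- c(5, 5, 5, 5, 5, 2, 3, 4)
  out <- baseline_factor("med", target, reference)
  expect_equal(out$zero_path, "either_zero")
  expect_equal(out$sigma, 6 / 3)

  # forcing the narrow policy errors instead of cascading
  expect_error(
    baseline_factor("med", target, reference, zero_policy = "both_zero_only"),
    "zero policy exhausted")

  # a clean pair never needs the fallback
  p <- make_pair(zero_fraction = 0.1, seed = 2)
  expect_equal(baseline_factor("med", p$target, p$reference)$zero_path,
               "both_zero")
})

test_that("TMM cascades when infinite M-values survive the trimming", {
  # 40% of genes zero in the target only: -Inf M-values overflow the 30% trim
  set.seed(8)
  reference <- rpois(100, 30) + 1
  target <- reference * 2
  target[1:40] <- 0
  out <- baseline_factor("tmm", target, reference)
  expect_equal(out$zero_path, "either_zero")
  expect_equal(out$sigma, 2, tolerance = 1e-12)
})

test_that("UQ is unusable when zeros exceed the quartile level", {
  target <- c(rep(0, 90), rep(3, 10))
  reference <- c(rep(1, 90), rep(0, 10))
  expect_error(baseline_factor("uq", target, reference),
               "UQ.*zero policy exhausted")
})

test_that("cascade and factor are deterministic across repeated runs", {
  p <- make_pair(seed = 31)
  a <- baseline_factor("rle", p$target, p$reference)
  b <- baseline_factor("rle", p$target, p$reference)
  expect_identical(a, b)
})

test_that("summarize_factors reports quartiles, SD and scaling fractions", {
  params <- data.frame(sample_id = c("a", "b", "c"), sigma = c(0.5, 1, 2),
                       gamma = 1, method = "TC", reference_id = "r")
  s <- summarize_factors(params)
  expect_equal(unname(s["TC", "Scal Up"]), 1 / 3)
  expect_equal(unname(s["TC", "No Chng"]), 1 / 3)
  expect_equal(unname(s["TC", "Median"]), 1)

  all_one <- data.frame(sigma = rep(1, 5), method = "MED")
  s2 <- summarize_factors(all_one)
  expect_equal(unname(s2["MED", "SD"]), 0)
  expect_equal(unname(s2["MED", "No Chng"]), 1)
  expect_equal(colnames(s2),
               c("Min.", "1st Qu.", "Median", "Mean", "3rd Qu.", "Max.",
                 "SD", "Scal Up", "No Chng"))
})

test_that("summarize_factors excludes the reference row by default", {
  params <- data.frame(sample_id = c("r", "a"), sigma = c(1, 2), gamma = 1,
                       method = "TC", reference_id = "r")
  expect_equal(unname(summarize_factors(params)["TC", "Mean"]), 2)
  expect_equal(unname(summarize_factors(params,
                                        exclude_reference = FALSE)["TC", "Mean"]),
               1.5)
})

test_that("baseline_normalize rescales every non-reference column", {
  set.seed(17)
  counts <- cbind(r = rpois(300, 25), s = rpois(300, 50))
  fit <- baseline_normalize(counts, "tc", reference = "r")
  expect_equal(fit$params$sigma[1], 1)
  expect_equal(normalized_counts(fit)[, "s"],
               counts[, "s"] / fit$params$sigma[2],
               ignore_attr = TRUE)
})
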