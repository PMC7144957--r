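test_that("gene_cv computes sd/mean with zeros included and gates eligibility", {
  m <- rbind(const = c(5, 5, 5, 5),
             two = c(2, 4, 2, 4),
             mostly_zero = c(0, 0, 9, 0),
             half_zero = c(0, 0, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  rep <- gene_cv(m)
  expect_equal(unname(rep$gene_cv["const"]), 0)
  expect_equal(unname(rep$gene_cv["two"]), sd(c(2, 4, 2, 4)) / 3)
  expect_true(is.na(rep$gene_cv["mostly_zero"]))  # 75% zeros: ineligible
  expect_true(is.na(rep$gene_cv["half_zero"]))    # exactly 50%: ineligible
  expect_equal(unname(rep$eligible), c(TRUE, TRUE, FALSE, FALSE))

  two_gene <- rbind(g1 = c(2, 4))
  expect_equal(unname(gene_cv(cbind(two_gene, two_gene)[, 1:2,
                                                        drop = FALSE])$gene_cv),
               sqrt(2) / 3)
})

test_that("gene_cv matches a two-pass mean/sd oracle on a random matrix", {
  set.seed(66)
  m <- matrix(rpois(500 * 20, 6), 500, 20)
  m[runif(500 * 20) < 0.3] <- 0
  rep <- gene_cv(m)
  for (i in sample(500, 40)) {
    x <- m[i, ]
    if (mean(x == 0) >= 0.5) {
      expect_true(is.na(rep$gene_cv[i]))
    } else {
      mu <- sum(x) / 20
      s2 <- sum((x - mu)^2) / 19
      expect_equal(unname(rep$gene_cv[i]), sqrt(s2) / mu, tolerance = 1e-12)
    }
  }
})

test_that("CVs, invariant sets and agreement are scale-invariant", {
  set.seed(8)
  m <- matrix(rpois(300 * 6, 15), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  r1 <- select_invariants(gene_cv(m), n = 50)
  r2 <- select_invariants(gene_cv(7.3 * m), n = 50)
  expect_equal(r1$gene_cv, r2$gene_cv, tolerance = 1e-12)
  expect_identical(r1$invariant_ids, r2$invariant_ids)
  expect_equal(agreement(list(a = r1, b = r1)),
               agreement(list(a = r2, b = r2)), tolerance = 1e-12)
})

test_that("select_invariants picks the n smallest CVs, ties by gene order", {
  set.seed(19)
  m <- matrix(rpois(200 * 5, 10) + 1, 200, 5,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  rep <- gene_cv(m)
  sel <- select_invariants(rep, n = 50)
  ord <- names(sort(rep$gene_cv))
  expect_setequal(sel$invariant_ids, ord[1:50])
  expect_equal(sel$cutoff_cv, max(rep$gene_cv[sel$invariant_ids]))
  expect_true(all(rep$gene_cv[setdiff(names(which(rep$eligible)),
                                      sel$invariant_ids)] >= sel$cutoff_cv))

  one <- select_invariants(rep, n = 1)
  expect_equal(one$invariant_ids, names(which.min(rep$gene_cv)))

  all_elig <- select_invariants(rep, n = sum(rep$eligible))
  expect_equal(all_elig$cutoff_cv, max(rep$gene_cv, na.rm = TRUE))
  expect_error(select_invariants(rep, n = 1e6), "eligible")

  # deterministic boundary: equal CVs resolved by gene index
  tied <- rbind(g1 = c(2, 4), g2 = c(4, 8), g3 = c(1, 3))
  colnames(tied) <- c("s1", "s2")
  sel_t <- select_invariants(gene_cv(tied), n = 1)
  expect_equal(sel_t$invariant_ids, "g1")
})

test_that("agreement matrix has overlaps below, cutoffs on, correlations above", {
  set.seed(4)
  m1 <- matrix(rpois(400 * 8, 12) + 1, 400, 8,
               dimnames = list(paste0("g", 1:400), paste0("s", 1:8)))
  m2 <- m1 * matrix(runif(400 * 8, 0.5, 2), 400, 8)
  ra <- select_invariants(gene_cv(m1), 80)
  rb <- select_invariants(gene_cv(m2), 80)
  A <- agreement(list(A = ra, B = rb))
  expect_equal(A["A", "A"], ra$cutoff_cv)
  expect_equal(A["B", "B"], rb$cutoff_cv)
  expect_equal(A["B", "A"], length(intersect(ra$invariant_ids,
                                             rb$invariant_ids)))
  both <- ra$eligible & rb$eligible
  expect_equal(A["A", "B"],
               cor(ra$gene_cv[both], rb$gene_cv[both], method = "spearman"))
  expect_true(A["A", "B"] >= -1 && A["A", "B"] <= 1)

  self <- agreement(list(A = ra, A2 = ra))
  expect_equal(self["A2", "A"], 80)
  expect_equal(self["A", "A2"], 1)
})

test_that("disjoint invariant sets give zero overlap", {
  cv <- c(1:40) / 100
  m <- matrix(rep(1, 40 * 3), 40, 3, dimnames = list(paste0("g", 1:40), NULL))
  ra <- gene_cv(m); rb <- gene_cv(m)
  ra$gene_cv[] <- cv; rb$gene_cv[] <- rev(cv)
  ra <- select_invariants(ra, 10); rb <- select_invariants(rb, 10)
  expect_length(intersect(ra$invariant_ids, rb$invariant_ids), 0)
  expect_equal(agreement(list(a = ra, b = rb))["b", "a"], 0)
})

test_that("ma_data computes M and A over genes positive in both", {
  x <- c(g1 = 4, g2 = 0, g3 = 10, g4 = 2)
  md <- ma_data(x, x)
  expect_equal(md$m, rep(0, 3))
  expect_equal(md$gene_id, c("g1", "g3", "g4"))

  y <- 2 * x
  md2 <- ma_data(x, y)
  expect_equal(md2$m, rep(-log(2), 3))
  expect_equal(md2$a, log(x[x > 0]) + log(2) / 2, ignore_attr = TRUE)

  expect_error(ma_data(c(0, 1), c(2, 0)), "no genes positive in both")
})

test_that("a perfectly normalized pair has mean M near zero", {
  sim <- simulate_zipf_counts(20000, 2, sigma = c(1, 2.4), seed = 44,
                              rounding = "continuous")
  fit <- zipf_normalize(sim$counts, reference = "S1")
  nm <- normalized_counts(fit)
  md <- ma_data(nm[, 1], nm[, 2])
  expect_lt(abs(mean(md$m)), 0.02)
})

test_that("ma_smooth returns a finite loess trend over the A range", {
  set.seed(2)
  md <- data.frame(a = runif(300, 0, 10))
  md$m <- 0.2 * md$a + rnorm(300, 0, 0.1)
  sm <- ma_smooth(md, span = 0.5, n = 50)
  expect_equal(nrow(sm), 50)
  expect_true(all(is.finite(sm$m_smooth)))
  expect_lt(max(abs(sm$m_smooth - 0.2 * sm$a)), 0.15)
})
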