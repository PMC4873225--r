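test_that("log2 fold change works on linear-scale means", {
  # linear means 8 vs 2 (log2 values 3 and 1)
  m <- rbind(g1 = c(3, 3, 1, 1, 1))
  expect_equal(unname(log2_fold_change(m, 1:2, 3:5)), 2.0)
  # equal means
  m2 <- rbind(g1 = c(2, 2, 2, 2))
  expect_equal(unname(log2_fold_change(m2, 1:2, 3:4)), 0.0)
  # zero linear mean in A with pseudocount 1: log2(1/4) = -2
  m3 <- rbind(g1 = c(-Inf, -Inf, log2(3), log2(3)))
  expect_equal(unname(log2_fold_change(m3, 1:2, 3:4, pseudocount = 1)), -2)
  expect_error(log2_fold_change(m2, integer(0), 3:4), "non-empty")
  expect_error(log2_fold_change(m2, 1:2, 3:4, pseudocount = -1),
               "non-negative")
})

test_that("two-group battery matches exact enumeration and symmetry", {
  r <- two_group_tests(c(1.2, 2.3), c(3.1, 4.5, 5.0))
  expect_equal(r$U, 0)
  expect_equal(r$U_p, 0.2)  # 2/10 arrangements at least as extreme

  x <- c(1, 2, 3)
  r2 <- two_group_tests(x, x)
  expect_equal(r2$U, length(x)^2 / 2)
  expect_equal(r2$U_p, 1)

  set.seed(1)
  a <- rnorm(20, 10, 1); b <- rnorm(20, 0, 1)
  r3 <- two_group_tests(a, b)
  expect_lt(r3$t_p, 1e-6)
  expect_lt(r3$z_p, 1e-6)
  expect_lt(r3$U_p, 1e-6)

  r4 <- two_group_tests(c(1, 1, 1), c(1, 1, 1))
  expect_true(r4$zero_variance)
  expect_equal(r4$t_p, 1)
})

test_that("exact Mann-Whitney p equals exhaustive enumeration (<= 6)", {
  set.seed(7)
  for (nA in 2:6) for (nB in 2:6) {
    a <- rnorm(nA); b <- rnorm(nB)
    got <- two_group_tests(a, b)$U_p
    expect_equal(got, mw_exact_enum(a, b),
                 info = sprintf("nA=%d nB=%d", nA, nB))
  }
})

test_that("vectorized contrast agrees with scalar tests gene by gene", {
  set.seed(11)
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  de <- de_contrast(m, 1:6, 7:12, s0 = 0.5)
  for (i in c(1, 7, 20)) {
    ref <- two_group_tests(m[i, 1:6], m[i, 7:12])
    expect_equal(de$t[i], ref$t)
    expect_equal(de$t_p[i], ref$t_p)
    expect_equal(de$z[i], ref$z)
    expect_equal(de$U[i], ref$U)
    expect_equal(de$U_p[i], ref$U_p)
    expect_equal(de$d[i], sam_d(m[i, 1:6], m[i, 7:12], s0 = 0.5))
  }
})

test_that("one-way ANOVA F matches hand computation and stats::oneway.test", {
  # equal means, zero noise
  m0 <- rbind(g = rep(2, 6))
  r0 <- anova_f(m0, rep(c("N", "T", "M"), each = 2))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # three near-degenerate groups separated by 1: tiny jitter
  m1 <- rbind(g = c(1, 1 + 1e-6, 2, 2 - 1e-6, 3, 3 + 1e-6))
  expect_lt(anova_f(m1, rep(c("a", "b", "c"), each = 2))$p, 0.01)

  # hand-computed sums of squares on 6 values:
  # A=(1,2), B=(1,2), C=(4,5): SSB=12, SSW=1.5, F=(12/2)/(1.5/3)=12
  m2 <- rbind(g = c(1, 2, 1, 2, 4, 5))
  r2 <- anova_f(m2, rep(c("A", "B", "C"), each = 2))
  expect_equal(r2$F, 12)

  set.seed(2)
  m3 <- matrix(rnorm(5 * 9), 5, 9)
  g3 <- rep(c("N", "T", "M"), each = 3)
  r3 <- anova_f(m3, g3)
  for (i in 1:5) {
    ref <- stats::oneway.test(m3[i, ] ~ g3, var.equal = TRUE)
    expect_equal(r3$F[i], unname(ref$statistic))
    expect_equal(r3$p[i], ref$p.value)
  }
  expect_error(anova_f(m3, c("N", rep(c("T", "M"), 4))), "at least two")
})

test_that("p-value adjustment: bonferroni clamps, BH steps up monotone", {
  expect_equal(adjust_pvalues(c(0.01, rep(0.5, 4)), "bonferroni")[1], 0.05)
  expect_equal(adjust_pvalues(rep(0.5, 5), "bonferroni")[1], 1.0)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  p <- runif(50)
  expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  q <- adjust_pvalues(p, "bh")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("SAM d statistic: closed forms and s0 damping", {
  expect_equal(sam_d(c(1, 1), c(3, 3), s0 = 1), -2)
  expect_equal(sam_d(c(1, 2, 3), c(1, 2, 3), s0 = 0.1), 0)
  set.seed(4)
  a <- rnorm(5, 1); b <- rnorm(5)
  ds <- vapply(c(0, 0.5, 1, 5, 50), function(s0) abs(sam_d(a, b, s0)),
               numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_error(sam_d(c(1, 1), c(1, 1), s0 = 0), "zero pooled")
})
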