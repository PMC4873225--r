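test_that("top-K selection gates on significance and orders by |FC|", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                   fc = c(3, -4, 2, 5, 1),
                   p_bonf = c(0.01, 0.01, 0.01, 0.2, 0.01),
                   q_bh = c(0.01, 0.01, 0.01, 0.2, 0.01))
  expect_equal(select_top_k(de, K = 3), c("g2", "g1", "g3"))
  # fewer significant than K: no padding
  expect_equal(length(select_top_k(de, K = 10)), 4L)
  # |FC| tie broken lexicographically
  de2 <- data.frame(gene = c("b", "a"), fc = c(2, -2),
                    p_bonf = c(0.01, 0.01), q_bh = c(0.01, 0.01))
  expect_equal(select_top_k(de2, K = 2), c("a", "b"))
})

test_that("combined ranking boosts genes differential in both contrasts", {
  tn <- sprintf("g%02d", 1:12)
  cr <- combined_rank(tn, topMT = "g10", boost = 5)
  expect_equal(cr$effective[cr$gene == "g10"], 5)
  # stable re-sort: ties with g05 (effective 5) keep base order, so the
  # boosted gene lands directly after it and ahead of g06
  expect_equal(cr$gene[5:7], c("g05", "g10", "g06"))

  cr0 <- combined_rank(tn, topMT = "zz", boost = 5)
  expect_equal(cr0$gene, tn)
  expect_error(combined_rank(c("a", "a"), "b"), "deduplicated")
})

test_that("tissue and literature filters apply the stated boundary rules", {
  ts <- data.frame(gene = c("hi", "flat", "edge"),
                   prostate = c(10, 1, 6),
                   breast = c(1, 1, 3), lung = c(1, 1, 3),
                   liver = c(1, 1, 3))
  tf <- tissue_filter(c("hi", "flat", "edge", "absent"), ts,
                      tissue_ratio_min = 2)
  expect_true(tf$pass[tf$gene == "hi"])
  expect_false(tf$pass[tf$gene == "flat"])
  expect_equal(tf$reason[tf$gene == "flat"], "tissue")
  expect_true(tf$pass[tf$gene == "edge"])   # ratio exactly 2: inclusive
  expect_equal(tf$reason[tf$gene == "absent"], "missing tissue scores")

  cit <- data.frame(gene = c("g1", "g2", "g3"), count = c(0L, 5L, 6L))
  lf <- literature_filter(c("g1", "g2", "g3"), cit, citation_max = 5)
  expect_equal(lf$gene[lf$pass], c("g1", "g2"))
  expect_warning(
    lf2 <- literature_filter("gx", cit, citation_max = 5), "treated as 0")
  expect_true(lf2$pass)
  lf3 <- literature_filter(c("g1", "g2"), cit, citation_max = 0)
  expect_equal(lf3$gene[lf3$pass], "g1")
})

test_that("risk stratification assigns round(n * 0.15) highest values", {
  lab <- km_stratify(seq_len(20), risk_quantile = 0.85)
  expect_equal(sum(lab == "high"), 3L)
  expect_true(all(lab[18:20] == "high"))
  expect_equal(sum(km_stratify(rnorm(200)) == "high"), 30L)
  # all-equal values: stable input order picks the first round(0.15 n)
  lab2 <- km_stratify(rep(1, 20))
  expect_equal(which(lab2 == "high"), 1:3)
  expect_error(km_stratify(1), "at least two")
})

test_that("KM curves follow the product-limit estimator", {
  flat <- km_curves(c(5, 10, 15), c(0, 0, 0))$all
  expect_true(all(flat$survival == 1))

  km <- km_curves(c(1, 2), c(1, 1))$all
  expect_equal(km$survival, c(0.5, 0))

  # censoring after the last event leaves the curve value unchanged
  km2 <- km_curves(c(1, 2, 30), c(1, 1, 0))$all
  expect_equal(km2$survival[km2$time == 2], 1 / 3)
  expect_equal(min(km2$survival), 1 / 3)
  expect_true(all(diff(km_curves(rexp(20) ,rbinom(20, 1, 0.7))$all$survival) <= 0))
})

test_that("log-rank test matches hand computation and is label-symmetric", {
  id <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(id$chisq, 0)
  expect_equal(id$p, 1)
  expect_true(is.na(id$worse))

  # A events at t=1,2; B events at t=3,4; O-E and variance give 2.882
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 2.882353, tolerance = 1e-6)
  expect_equal(lr$worse, "A")

  swap <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(swap$chisq, lr$chisq)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")),
               "two non-empty")
})

test_that("cascade returns planted genes, attributes removals, validates input", {
  coh <- small_cohort(seed = 1)
  tr <- run_prioritization(coh)
  planted <- coh$truth$genes$gene[coh$truth$genes$planted]
  expect_setequal(tr$final, planted)
  # the three genes with both effects occupy the top three combined ranks
  both <- coh$truth$planted$gene[coh$truth$planted$lfc_mt > 0]
  expect_setequal(tr$trace$gene[1:3], both)
  # every removal is attributed to exactly one first-failing filter
  removed <- tr$trace[!tr$trace$final, ]
  expect_true(all(removed$first_fail %in% c("tissue", "survival",
                                            "literature")))
  expect_true(all(tr$trace$first_fail[tr$trace$final] == ""))

  # filters are idempotent on the final list
  tf <- tissue_filter(tr$final, coh$tissue_scores, 2)
  lf <- literature_filter(tr$final, coh$citations, 5)
  expect_true(all(tf$pass) && all(lf$pass))

  # alpha = 0: empty final list
  tr0 <- run_prioritization(coh, prioritization_config(alpha = 0))
  expect_length(tr0$final, 0)

  coh2 <- coh
  coh2$citations <- NULL
  expect_error(run_prioritization(coh2), "literature")
})
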