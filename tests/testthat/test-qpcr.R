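test_that("spike-in normalization inverts the recovery and RNA mass", {
  ac <- absolute_copies(2e3, spike_added = 1e6, spike_measured = 5e5,
                        rna_ug = 0.1)
  expect_equal(ac$mean, 4e4)
  expect_equal(absolute_copies(c(7, 8), 100, 100, 1)$replicates, c(7, 8))
  expect_warning(absolute_copies(10, 100, 150, 1), "recovery above 1")
  bad <- absolute_copies(c(1, 2, 3), 100, 0, 1)
  expect_false(bad$quantifiable)
  expect_true(all(is.na(bad$replicates)))
  # scale consistency: doubling rna_ug halves copies/ug
  a1 <- absolute_copies(1000, 100, 50, 1)$mean
  a2 <- absolute_copies(1000, 100, 50, 2)$mean
  expect_equal(a1, 2 * a2)
})

test_that("detection calls require all three replicates strictly above LDL", {
  expect_equal(detection_call(c(10, 12, 11), 5), "positive")
  expect_equal(detection_call(c(10, 4, 11), 5), "negative")
  expect_equal(detection_call(c(5, 6, 7), 5), "negative")
  expect_error(detection_call(c(10, 12), 5), "3 replicates")
  # replicate order cannot matter
  expect_equal(detection_call(c(4, 10, 11), 5), detection_call(c(10, 11, 4), 5))
})

test_that("detection percentages round half away from zero", {
  expect_identical(detection_percent(7, 12), 58L)
  expect_identical(detection_percent(0, 7), 0L)
  expect_identical(detection_percent(12, 12), 100L)
  expect_identical(detection_percent(1, 8), 13L)  # 12.5 -> 13
})

test_that("per-patient reduction prefers the right lobe, then sample id", {
  df <- data.frame(sample = c("S2", "S1"), lobe = c("right", "left"),
                   copies_per_ug = c(5, 9), quantifiable = TRUE)
  expect_equal(per_patient_value(df)$value, 5)
  expect_equal(per_patient_value(df[2, ])$value, 9)
  two_right <- data.frame(sample = c("S9", "S3"), lobe = "right",
                          copies_per_ug = c(1, 2), quantifiable = TRUE)
  expect_equal(per_patient_value(two_right)$sample, "S3")
  none <- data.frame(sample = "S1", lobe = "right", copies_per_ug = NA_real_,
                     quantifiable = FALSE)
  expect_error(per_patient_value(none), "no quantifiable")
})

test_that("group contrasts delegate to the Mann-Whitney battery", {
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      qpcr_row(sprintf("A%d", i), "CP-B", reps = c(100, 110, 120) + i))),
    do.call(rbind, lapply(1:4, function(i)
      qpcr_row(sprintf("B%d", i), "RP-PCa", reps = c(100, 110, 120) + i))))
  q <- as_qpcr(rows)
  gc <- group_compare(q, "G1", c("RP-PCa", "CP-B"))
  expect_equal(gc$p, 1)  # identical arms
  expect_error(group_compare(q, "G1", c("RP-PCa", "XX")), "unknown group")
})

test_that("clinical dichotomizations follow the stated cut points", {
  clin <- data.frame(patient = c("p1", "p2", "p3", "p4"),
                     gleason = c(7, 6, NA, 9),
                     pt_stage = c("pT2", "pT3", "unknown", "pT4"),
                     relapse = c(TRUE, FALSE, NA, FALSE),
                     tumor_content_pct = c(33, 34, 50, NA))
  g <- dichotomize(clin, "gleason")
  expect_equal(g$arm[g$patient == "p1"], "A")  # Gleason 7 is high
  expect_false("p3" %in% g$patient)
  s <- dichotomize(clin, "stage")
  expect_equal(s$arm, c("A", "B", "B"))
  expect_false("p3" %in% s$patient)
  tc <- dichotomize(clin, "tumor_content")
  expect_equal(tc$arm[tc$patient == "p1"], "B")  # exactly 33%: low arm
  expect_equal(tc$arm[tc$patient == "p2"], "A")
  expect_error(dichotomize(clin, "nope"))
})

test_that("ROC AUC equals the pairwise comparison fraction and U/(n1 n2)", {
  r <- roc_auc(c(5, 7, 1, 6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(10, 11, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  # curve ends at (0,0) and (1,1)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)

  set.seed(1)
  v <- rnorm(400); l <- rep(c(TRUE, FALSE), 200)
  expect_lt(abs(roc_auc(v, l)$auc - 0.5), 0.05)

  # identity with U, including ties, against the brute-force oracle
  set.seed(2)
  for (i in 1:25) {
    pos <- sample(1:6, 5, replace = TRUE)
    neg <- sample(1:6, 4, replace = TRUE)
    auc <- roc_auc(c(pos, neg), c(rep(TRUE, 5), rep(FALSE, 4)))$auc
    expect_equal(auc, auc_pairwise(pos, neg))
    expect_equal(auc, two_group_tests(pos, neg)$U / 20)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("rank AUC agrees with pROC on a random dataset", {
  skip_if_not_installed("pROC")
  set.seed(3)
  v <- rnorm(60); l <- rbinom(60, 1, 0.4)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(l, v,
                                                         direction = "<"))))
  expect_equal(roc_auc(v, l)$auc, ref)
})

test_that("validation report assembles detection, contrasts and ROC per gene", {
  cfg <- sim_config(seed = 9, qpcr_genes = c("G1", "G2"))
  q <- gen_qpcr_cohort(cfg)
  rep <- validation_report(q)
  expect_setequal(unique(rep$detection$gene), c("G1", "G2"))
  expect_equal(nrow(rep$detection), 8)  # 2 genes x 4 groups
  expect_true(all(c("CP vs RP", "RP-PCa vs RP-B", "gleason", "relapse") %in%
                    rep$contrasts$contrast))
  expect_equal(nrow(rep$roc), 4)  # 2 genes x 2 comparisons
  expect_true(all(rep$roc$auc >= 0 & rep$roc$auc <= 1))
  # strong cancer effect: near-perfect separation of RP-PCa from CP
  expect_true(all(rep$roc$auc[rep$roc$comparison == "RP-PCa vs CP"] > 0.9))
  # field effect present: cancer-adjacent benign tissue already separates
  expect_true(all(rep$roc$auc[rep$roc$comparison == "RP-B vs CP"] > 0.5))
})

test_that("RP cohort accounting reproduces the paired-sample bookkeeping", {
  acc <- rp_sample_accounting(both_benign = 30, both_cancer = 15, mixed = 45,
                              excluded_benign = 1, excluded_cancer = 1)
  expect_equal(acc$n_patients, 90)
  expect_equal(acc$benign, 104)
  expect_equal(acc$cancer, 74)
  expect_equal(acc$total, 178)
})
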