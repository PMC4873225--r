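test_that("expression cohort generation is deterministic and validated", {
  cfg <- sim_config(seed = 42, n_genes = 300, n_decoy = 10)
  a <- gen_expression_cohort(cfg)
  b <- gen_expression_cohort(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$samples, b$samples)
  expect_identical(a$tissue_scores, b$tissue_scores)
  expect_identical(a$citations, b$citations)

  # a different stream name must not perturb the expression draw
  q <- gen_qpcr_cohort(cfg)
  c2 <- gen_expression_cohort(cfg)
  expect_identical(a$matrix, c2$matrix)

  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(group_sizes = c(N = 0L, T = 5L, M = 5L)), "group sizes")
  expect_error(
    sim_config(planted_genes = rbind(default_planted_panel(),
                                     default_planted_panel()[1, ])),
    "duplicate")
  expect_error(sim_config(recovery_range = c(0, 0.5)), "recovery_range")
})

test_that("null config plants no effects; planted effects are recovered", {
  null_cfg <- sim_config(seed = 3, n_genes = 200, n_decoy = 0,
                         planted_genes = default_planted_panel()[0, ])
  coh0 <- gen_expression_cohort(null_cfg)
  expect_true(all(coh0$truth$genes$lfc_tn == 0))
  expect_true(all(coh0$truth$genes$lfc_mt == 0))

  # planted T-vs-N effect of 2.0 log2 units shows up in the observed FC
  cfg <- sim_config(seed = 1, n_genes = 5000, n_decoy = 0,
                    group_sizes = c(N = 30L, T = 30L, M = 10L),
                    noise_sd = 0.5)
  coh <- gen_expression_cohort(cfg)
  grp <- coh$samples$group
  fc <- log2_fold_change(coh$matrix, which(grp == "T"), which(grp == "N"))
  planted <- coh$truth$genes$gene[coh$truth$genes$planted]
  expect_lt(abs(mean(fc[planted]) - 2.0), 0.2)
})

test_that("qpcr cohort: determinism, null model and field-effect ordering", {
  cfg <- sim_config(seed = 5)
  expect_identical(gen_qpcr_cohort(cfg)$data, gen_qpcr_cohort(cfg)$data)

  null_cfg <- sim_config(seed = 1, field_effect = 1, cancer_effect = 1,
                         ipca_effect = 1, qpcr_genes = "G1")
  q0 <- gen_qpcr_cohort(null_cfg)
  v0 <- qpcr_sample_values(q0)
  p <- group_compare(q0, "G1", c("RP-PCa", "CP-B"), values = v0)$p
  expect_gt(p, 0.01)

  cfg2 <- sim_config(seed = 1, field_effect = 3, cancer_effect = 10,
                     qpcr_group_sizes = c("CP-B" = 20L, "CP-IPCa" = 5L,
                                          "RP-B" = 20L, "RP-PCa" = 20L),
                     qpcr_genes = "G1")
  v <- qpcr_sample_values(gen_qpcr_cohort(cfg2))
  means <- tapply(v$copies_per_ug, v$group, mean)
  expect_true(means[["CP-B"]] < means[["RP-B"]])
  expect_true(means[["RP-B"]] < means[["RP-PCa"]])

  # paired RP samples share patients and carry lobes
  rp <- v[grepl("^RP", v$group), ]
  expect_true(all(rp$lobe %in% c("left", "right")))
  expect_true(any(table(rp$patient) == 2))
})

test_that("organoid image generator honors configuration and ground truth", {
  cfg <- sim_config(seed = 2, n_organoids = 3L, protrusion_count = 0L)
  img <- gen_organoid_image(cfg)
  expect_identical(nrow(img$truth), 3L)
  expect_true(all(img$truth$protrusions == 0))

  img2 <- gen_organoid_image(cfg)
  expect_identical(img$live, img2$live)
  expect_identical(img$dead, img2$dead)

  cfg0 <- sim_config(seed = 2, n_organoids = 2L, dead_fraction = 0)
  img0 <- gen_organoid_image(cfg0)
  expect_true(all(img0$dead == 0))

  expect_error(sim_config(canvas = 40L), "canvas")
})

test_that("wound series closes at the configured rate", {
  base <- sim_config(seed = 1, wound_rate = 0, n_frames = 4L)
  ws0 <- gen_wound_series(base)
  expect_true(all(vapply(ws0$frames[-1], identical, logical(1),
                         y = ws0$frames[[1]])))

  ws1 <- gen_wound_series(sim_config(seed = 1, wound_rate = 1, n_frames = 3L))
  expect_identical(ws1$truth$width_px[2], 0L)
  expect_true(all(ws1$frames[[2]] == 1L))

  ws <- gen_wound_series(sim_config(seed = 1, wound_rate = 0.1,
                                    n_frames = 10L))
  expect_true(all(diff(ws$truth$width_px) < 0))
})
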