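#' Generate a synthetic grouped expression cohort
#'
#' Emulates a normalized log2 expression matrix over three sample groups —
#' N (benign prostate), T (primary prostate cancer), M (metastasis) — with
#' planted marker genes, optional decoy genes, auxiliary tissue-specificity
#' and citation-count tables, and per-sample survival annotations.
#'
#' Planted genes receive the configured log2 offsets in T (vs N) and M
#' (vs T), prostate-specific tissue scores, their configured citation
#' counts, and drive survival: the exponential event rate of each sample is
#' `surv_base_rate * exp(lp)` where `lp` is the mean of
#' `hazard_beta * z` over prognostic planted genes and `z` is the sample's
#' standardized expression of that gene. Decoy genes carry a real T-vs-N
#' effect but non-specific tissue scores and more than five citations, so
#' they populate the top of the fold-change ranking and are then removed by
#' the downstream filters — mimicking well-known, non-specific
#' cancer genes. All remaining genes are null.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `expression_cohort`: a list with elements
#'   `matrix` (genes x samples, log2), `samples` (data.frame: sample, group,
#'   patient, survival_months, event), `tissue_scores` (data.frame: gene +
#'   one column per tissue, including `prostate`), `citations` (data.frame:
#'   gene, count) and `truth` (per-gene planted effects and per-sample
#'   linear predictors).
#' @export
gen_expression_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "expression", {
    gs <- config$group_sizes
    n_samp <- sum(gs)
    groups <- rep(names(gs), gs)
    samples <- sprintf("SAMP%03d", seq_len(n_samp))

    pg <- config$planted_genes
    n_plant <- nrow(pg)
    n_decoy <- config$n_decoy
    n_null <- config$n_genes - n_plant - n_decoy
    genes <- c(pg$gene,
               if (n_decoy > 0) sprintf("DECOY%04d", seq_len(n_decoy)),
               if (n_null > 0) sprintf("GENE%05d", seq_len(n_null)))

    decoy_lfc <- if (n_decoy > 0)
      stats::runif(n_decoy, config$decoy_lfc_range[1], config$decoy_lfc_range[2])
    else numeric(0)

    lfc_tn <- c(pg$lfc_tn, decoy_lfc, rep(0, n_null))
    lfc_mt <- c(pg$lfc_mt, rep(0, n_decoy), rep(0, n_null))

    # group-mean log2 expression: N baseline, T baseline + lfc_tn,
    # M baseline + lfc_tn + lfc_mt
    offset <- matrix(0, config$n_genes, n_samp)
    offset[, groups == "T"] <- lfc_tn
    offset[, groups == "M"] <- lfc_tn + lfc_mt
    mat <- config$baseline_log2 + offset +
      matrix(stats::rnorm(config$n_genes * n_samp, 0, config$noise_sd),
             config$n_genes, n_samp)
    dimnames(mat) <- list(genes, samples)

    # tissue-specificity scores (stand-in for an in-silico transcriptomics
    # database query): log-normal tissue profiles, prostate column scaled
    # up for planted genes
    tissues <- c("prostate", "breast", "lung", "colon", "liver", "kidney")
    ts <- matrix(exp(stats::rnorm(config$n_genes * length(tissues), 0, 1)),
                 config$n_genes, length(tissues),
                 dimnames = list(genes, tissues))
    ts[seq_len(n_plant), "prostate"] <-
      ts[seq_len(n_plant), "prostate"] * pg$tissue_ratio *
      apply(ts[seq_len(n_plant), -1, drop = FALSE], 1, stats::median) /
      ts[seq_len(n_plant), "prostate"]
    tissue_scores <- data.frame(gene = genes, ts, stringsAsFactors = FALSE,
                                row.names = NULL, check.names = FALSE)

    # citation counts (stand-in for a literature co-occurrence query):
    # planted genes as configured, decoys always "well described" (> 5)
    cites <- c(pg$citations,
               if (n_decoy > 0) 6L + stats::rpois(n_decoy, 40),
               if (n_null > 0) stats::rpois(n_null, 1.5))
    citations <- data.frame(gene = genes, count = as.integer(cites),
                            stringsAsFactors = FALSE)

    # survival driven by prognostic planted genes
    prog <- which(pg$hazard_beta != 0)
    if (length(prog) > 0) {
      z <- t(scale(t(mat[prog, , drop = FALSE])))
      z[is.nan(z)] <- 0
      lp <- colMeans(pg$hazard_beta[prog] * z)
    } else {
      lp <- rep(0, n_samp)
    }
    rate <- config$surv_base_rate * exp(lp)
    raw_t <- stats::rexp(n_samp, rate)
    event <- raw_t <= config$surv_horizon
    time <- pmin(raw_t, config$surv_horizon)

    meta <- data.frame(
      sample = samples, group = groups, patient = samples,
      survival_months = round(time, 2), event = event,
      stringsAsFactors = FALSE
    )

    truth <- list(
      genes = data.frame(gene = genes, lfc_tn = lfc_tn, lfc_mt = lfc_mt,
                         planted = genes %in% pg$gene,
                         decoy = grepl("^DECOY", genes),
                         stringsAsFactors = FALSE),
      planted = pg,
      linear_predictor = stats::setNames(lp, samples)
    )

    structure(
      list(matrix = mat, samples = meta, tissue_scores = tissue_scores,
           citations = citations, truth = truth),
      class = "expression_cohort"
    )
  })
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = " "),
      "\n")
  cat("  planted genes:", sum(x$truth$genes$planted),
      "| decoys:", sum(x$truth$genes$decoy), "\n")
  invisible(x)
}
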