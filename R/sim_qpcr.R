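#' Generate a synthetic four-group qRT-PCR validation cohort
#'
#' Emulates a spike-in standardized absolute qRT-PCR study over the four
#' histological groups used in clinical validation of prostate biomarkers:
#' \describe{
#'   \item{CP-B}{cystoprostatectomy, benign — true normal prostate}
#'   \item{CP-IPCa}{cystoprostatectomy with incidental prostate cancer}
#'   \item{RP-B}{radical prostatectomy, histologically benign
#'     (cancer-adjacent) tissue}
#'   \item{RP-PCa}{radical prostatectomy, cancerous tissue}
#' }
#' Per gene, true expression in copies per microgram of total RNA is
#' log-normal around a group mean: `base_copies` in CP-B, multiplied by
#' `ipca_effect` in CP-IPCa, by `field_effect` in RP-B (the cancer-adjacent
#' "field effect") and by `cancer_effect` in RP-PCa, with the study ordering
#' CP-B < RP-B < RP-PCa. Each sample receives a uniform spike-in recovery
#' and an RNA input mass; raw replicate counts are
#' `true_copies_per_ug * recovery * rna_ug` with multiplicative log-normal
#' triplicate noise, so spike-in normalization recovers the true value in
#' expectation.
#'
#' RP samples are paired: benign and cancerous samples are joined into
#' patients (one of each where counts allow, then same-group pairs) with
#' left/right lobe labels; CP samples are one per patient. A clinical table
#' (Gleason score, pathological T stage, PSA relapse, tumor content) is
#' generated for RP patients.
#'
#' @param config a [sim_config()] object.
#' @return object of class `qpcr_dataset`: list with `data` (long-format
#'   data.frame: sample, patient, lobe, group, gene, rep1..rep3,
#'   spike_added, spike_measured, rna_ug, ldl), `clinical` (data.frame per
#'   RP patient) and `truth` (true per-sample copies/ug and recoveries).
#' @export
gen_qpcr_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$qpcr_group_sizes
  need <- c("CP-B", "CP-IPCa", "RP-B", "RP-PCa")
  if (!all(need %in% names(gs)))
    stop("qpcr_group_sizes must be named: ", paste(need, collapse = ", "))
  with_stream(config$seed, "qpcr", {
    layout <- qpcr_sample_layout(gs)
    genes <- config$qpcr_genes
    mult <- c("CP-B" = 1, "CP-IPCa" = config$ipca_effect,
              "RP-B" = config$field_effect, "RP-PCa" = config$cancer_effect)

    n <- nrow(layout)
    recovery <- stats::runif(n, config$recovery_range[1],
                             config$recovery_range[2])
    rna_ug <- stats::runif(n, config$rna_ug_range[1], config$rna_ug_range[2])

    sdlog <- sqrt(log(1 + config$rep_cv^2))
    rows <- vector("list", length(genes))
    truth_rows <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      true_cpug <- config$base_copies * mult[layout$group] *
        2^stats::rnorm(n, 0, config$sample_log2_sd)
      raw_mean <- true_cpug * recovery * rna_ug
      reps <- matrix(raw_mean, n, 3) *
        matrix(stats::rlnorm(3 * n, -sdlog^2 / 2, sdlog), n, 3)
      rows[[gi]] <- data.frame(
        sample = layout$sample, patient = layout$patient,
        lobe = layout$lobe, group = layout$group, gene = genes[gi],
        rep1 = reps[, 1], rep2 = reps[, 2], rep3 = reps[, 3],
        spike_added = config$spike_added,
        spike_measured = config$spike_added * recovery,
        rna_ug = rna_ug, ldl = config$ldl,
        stringsAsFactors = FALSE
      )
      truth_rows[[gi]] <- data.frame(
        sample = layout$sample, gene = genes[gi],
        true_copies_per_ug = true_cpug, recovery = recovery,
        stringsAsFactors = FALSE
      )
    }
    dat <- do.call(rbind, rows)
    rownames(dat) <- NULL

    clinical <- qpcr_clinical_table(layout)

    structure(
      list(data = dat, clinical = clinical,
           truth = list(samples = do.call(rbind, truth_rows),
                        group_multipliers = mult)),
      class = "qpcr_dataset"
    )
  })
}

# Assigns samples to patients and lobes. CP samples: one per patient, lobe
# NA. RP samples: benign/cancer pairs share a patient (mixed pairs first,
# then same-group pairs, then a possible single-sample patient); within a
# patient the first sample is from the right lobe, the second from the left.
qpcr_sample_layout <- function(gs) {
  out <- list()
  sid <- 0L
  nxt_sample <- function() {
    sid <<- sid + 1L
    sprintf("Q%03d", sid)
  }
  for (g in c("CP-B", "CP-IPCa")) {
    for (i in seq_len(gs[[g]])) {
      s <- nxt_sample()
      out[[length(out) + 1L]] <- data.frame(
        sample = s, patient = paste0("P", s), lobe = NA_character_,
        group = g, stringsAsFactors = FALSE)
    }
  }
  nb <- gs[["RP-B"]]; nc <- gs[["RP-PCa"]]
  pid <- 0L
  nxt_patient <- function() {
    pid <<- pid + 1L
    sprintf("RPT%03d", pid)
  }
  add_pair <- function(groups) {
    p <- nxt_patient()
    lobes <- c("right", "left")
    for (k in seq_along(groups)) {
      out[[length(out) + 1L]] <<- data.frame(
        sample = nxt_sample(), patient = p, lobe = lobes[k],
        group = groups[k], stringsAsFactors = FALSE)
    }
  }
  n_mixed <- min(nb, nc)
  for (i in seq_len(n_mixed)) {
    # alternate which lobe carries the cancerous sample
    if (i %% 2L == 1L) add_pair(c("RP-PCa", "RP-B")) else add_pair(c("RP-B", "RP-PCa"))
  }
  rem_b <- nb - n_mixed; rem_c <- nc - n_mixed
  while (rem_b >= 2L) { add_pair(c("RP-B", "RP-B")); rem_b <- rem_b - 2L }
  while (rem_c >= 2L) { add_pair(c("RP-PCa", "RP-PCa")); rem_c <- rem_c - 2L }
  if (rem_b == 1L) add_pair("RP-B")
  if (rem_c == 1L) add_pair("RP-PCa")
  do.call(rbind, out)
}

# Clinical annotations for RP patients (Gleason 4-9, pT stage, PSA relapse,
# tumor content percent). A small fraction of values is left unknown, as in
# real pathology tables.
qpcr_clinical_table <- function(layout) {
  rp <- unique(layout$patient[grepl("^RPT", layout$patient)])
  n <- length(rp)
  if (n == 0L) {
    return(data.frame(patient = character(0), gleason = integer(0),
                      pt_stage = character(0), relapse = logical(0),
                      tumor_content_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  gleason <- sample(4:9, n, replace = TRUE,
                    prob = c(0.05, 0.15, 0.3, 0.3, 0.15, 0.05))
  pt_stage <- sample(c("pT2", "pT3", "pT4"), n, replace = TRUE,
                     prob = c(0.6, 0.35, 0.05))
  relapse <- stats::runif(n) < 0.2
  tumor_content <- round(stats::runif(n, 5, 90))
  unknown <- stats::runif(n) < 0.05
  gleason[unknown] <- NA_integer_
  data.frame(patient = rp, gleason = gleason, pt_stage = pt_stage,
             relapse = relapse, tumor_content_pct = tumor_content,
             stringsAsFactors = FALSE)
}
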