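#' Spike-in standardized absolute quantification
#'
#' Converts raw replicate copy counts to copies per microgram of total RNA
#' using the internal-standard spike-in: `recovery = spike_measured /
#' spike_added`, and `copies_per_ug = raw / (recovery * rna_ug)`. A
#' recovery above 1 is computed normally with a warning; a zero measured
#' spike flags the sample as unquantifiable.
#'
#' @param replicates numeric vector of raw replicate copy counts.
#' @param spike_added,spike_measured spike-in copies added / recovered.
#' @param rna_ug total RNA input, micrograms.
#' @return list: `replicates` (normalized, copies/ug), `mean`, `recovery`,
#'   `quantifiable` (FALSE when `spike_measured` is 0; normalized values
#'   are then `NA`).
#' @export
absolute_copies <- function(replicates, spike_added, spike_measured,
                            rna_ug) {
  if (rna_ug <= 0) stop("rna_ug must be positive")
  if (spike_added <= 0) stop("spike_added must be positive")
  if (any(replicates < 0)) stop("raw copy counts must be non-negative")
  if (spike_measured <= 0) {
    return(list(replicates = rep(NA_real_, length(replicates)),
                mean = NA_real_, recovery = 0, quantifiable = FALSE))
  }
  recovery <- spike_measured / spike_added
  if (recovery > 1)
    warning("spike-in recovery above 1 (", signif(recovery, 3),
            "); computed normally")
  norm <- replicates / (recovery * rna_ug)
  list(replicates = norm, mean = mean(norm), recovery = recovery,
       quantifiable = TRUE)
}

#' Detection call from triplicate measurements
#'
#' A sample is called positive iff all three replicates lie strictly above
#' the lowest assay detection limit (LDL).
#'
#' @param replicates numeric vector of exactly 3 raw replicate counts.
#' @param ldl lowest assay detection limit, copies/reaction.
#' @return `"positive"` or `"negative"`.
#' @export
detection_call <- function(replicates, ldl) {
  if (length(replicates) != 3L) stop("exactly 3 replicates required")
  if (min(replicates) > ldl) "positive" else "negative"
}

#' Nearest-integer percentage (half away from zero)
#'
#' Detection-frequency percentages rounded to the nearest integer, with
#' halves rounded away from zero (so 58.33 -> 58, 84.6 -> 85, 12.5 -> 13).
#'
#' @param positive,n counts.
#' @return integer percent.
#' @export
detection_percent <- function(positive, n) {
  x <- 100 * positive / n
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Detection-frequency table (gene x group)
#'
#' Per gene and histological group: number of samples called positive (all
#' three replicates strictly above the LDL), the group size, and the
#' nearest-integer detection percentage.
#'
#' @param dataset a `qpcr_dataset` (see [gen_qpcr_cohort()]) or compatible
#'   list with the long-format `data` element.
#' @return data.frame: `gene, group, positive, n, percent`.
#' @export
detection_table <- function(dataset) {
  dat <- dataset$data
  pos <- vapply(seq_len(nrow(dat)), function(i) {
    detection_call(c(dat$rep1[i], dat$rep2[i], dat$rep3[i]),
                   dat$ldl[i]) == "positive"
  }, logical(1))
  agg <- stats::aggregate(pos, by = list(gene = dat$gene, group = dat$group),
                          FUN = function(v) c(sum(v), length(v)))
  out <- data.frame(gene = agg$gene, group = agg$group,
                    positive = agg$x[, 1], n = agg$x[, 2],
                    stringsAsFactors = FALSE)
  out$percent <- detection_percent(out$positive, out$n)
  out[order(out$gene, out$group), , drop = FALSE]
}

#' Normalized sample summaries for a qPCR dataset
#'
#' Applies [absolute_copies()] to every sample x gene row and summarizes
#' the normalized triplicate with the mean (default) or median.
#'
#' @param dataset a `qpcr_dataset`.
#' @param summary `"mean"` or `"median"`.
#' @return data.frame: the long table with added `copies_per_ug` (summary
#'   of the normalized triplicate) and `quantifiable`.
#' @export
qpcr_sample_values <- function(dataset, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  dat <- dataset$data
  vals <- numeric(nrow(dat)); quant <- logical(nrow(dat))
  for (i in seq_len(nrow(dat))) {
    ac <- absolute_copies(c(dat$rep1[i], dat$rep2[i], dat$rep3[i]),
                          dat$spike_added[i], dat$spike_measured[i],
                          dat$rna_ug[i])
    quant[i] <- ac$quantifiable
    vals[i] <- if (!ac$quantifiable) NA_real_
               else if (summary == "mean") mean(ac$replicates)
               else stats::median(ac$replicates)
  }
  dat$copies_per_ug <- vals
  dat$quantifiable <- quant
  dat
}

#' Single per-patient expression value
#'
#' Reduces a patient's samples for one gene to a single value: the
#' right-lobe sample when present, otherwise the only available sample;
#' between two same-lobe candidates, the lexicographically smaller sample
#' id wins.
#'
#' @param samples data.frame of one patient's rows for one gene, with
#'   columns `sample`, `lobe`, `copies_per_ug`, `quantifiable`.
#' @return list: `value`, `sample` (chosen id).
#' @export
per_patient_value <- function(samples) {
  q <- samples[isTRUE_vec(samples$quantifiable) &
                 !is.na(samples$copies_per_ug), , drop = FALSE]
  if (nrow(q) == 0L) stop("no quantifiable sample for this patient")
  right <- q[!is.na(q$lobe) & q$lobe == "right", , drop = FALSE]
  pick <- if (nrow(right) > 0L) right else q
  pick <- pick[order(pick$sample), , drop = FALSE]
  list(value = pick$copies_per_ug[1], sample = pick$sample[1])
}

isTRUE_vec <- function(x) !is.na(x) & x

# per-patient reduction over a normalized value table (one gene)
reduce_per_patient <- function(vals_gene) {
  out <- lapply(split(vals_gene, vals_gene$patient), function(df) {
    pv <- per_patient_value(df)
    data.frame(patient = df$patient[1], sample = pv$sample,
               value = pv$value, group = df$group[which(df$sample == pv$sample)][1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mann-Whitney contrast between two sample groups
#'
#' Compares normalized mean copies/ug between the two arms of a named
#' contrast with the Mann-Whitney U test (delegating to
#' [two_group_tests()]). Group labels may be single groups
#' (e.g. `"RP-PCa"`) or unions joined by `+` (e.g. `"CP-B+CP-IPCa"` for
#' all cystoprostatectomy samples).
#'
#' @param dataset a `qpcr_dataset`.
#' @param gene assayed gene name.
#' @param contrast length-2 character vector `c(armA, armB)`.
#' @param values optional precomputed [qpcr_sample_values()] table.
#' @return list: `U`, `p`, `nA`, `nB`.
#' @export
group_compare <- function(dataset, gene, contrast, values = NULL) {
  if (length(contrast) != 2L) stop("contrast must name two arms")
  vals <- values %||% qpcr_sample_values(dataset)
  vals <- vals[vals$gene == gene & !is.na(vals$copies_per_ug), , drop = FALSE]
  known <- unique(vals$group)
  arm <- function(spec) {
    gs <- strsplit(spec, "+", fixed = TRUE)[[1]]
    bad <- setdiff(gs, known)
    if (length(bad))
      stop("unknown group label: ", paste(bad, collapse = ", "))
    vals$copies_per_ug[vals$group %in% gs]
  }
  a <- arm(contrast[1]); b <- arm(contrast[2])
  if (length(a) == 0L || length(b) == 0L) stop("empty contrast arm")
  tt <- two_group_tests(a, b)
  list(U = tt$U, p = tt$U_p, nA = length(a), nB = length(b))
}

#' Clinical dichotomization rules
#'
#' Splits patients into the two arms used by the clinical contrast battery:
#' \describe{
#'   \item{gleason}{Gleason score >= 7 (more aggressive) vs < 7}
#'   \item{stage}{pT2 (organ-confined) vs pT3/pT4 (locally advanced)}
#'   \item{relapse}{PSA relapse vs no relapse}
#'   \item{tumor_content}{strictly over 33% tumor content vs at most 33%}
#' }
#' Patients with unknown values are excluded from both arms.
#'
#' @param clinical data.frame with columns `patient`, `gleason`,
#'   `pt_stage`, `relapse`, `tumor_content_pct`.
#' @param rule one of `"gleason"`, `"stage"`, `"relapse"`,
#'   `"tumor_content"`.
#' @return data.frame: `patient`, `arm` (`"A"` = first-named arm: high
#'   Gleason / pT2 / relapse / high tumor content), unknowns dropped.
#' @export
dichotomize <- function(clinical,
                        rule = c("gleason", "stage", "relapse",
                                 "tumor_content")) {
  rule <- match.arg(rule)
  x <- switch(rule,
    gleason = ifelse(is.na(clinical$gleason), NA,
                     ifelse(clinical$gleason >= 7, "A", "B")),
    stage = ifelse(is.na(clinical$pt_stage) | clinical$pt_stage == "unknown",
                   NA,
                   ifelse(clinical$pt_stage == "pT2", "A", "B")),
    relapse = ifelse(is.na(clinical$relapse), NA,
                     ifelse(clinical$relapse, "A", "B")),
    tumor_content = ifelse(is.na(clinical$tumor_content_pct), NA,
                           ifelse(clinical$tumor_content_pct > 33, "A", "B"))
  )
  out <- data.frame(patient = clinical$patient, arm = x,
                    stringsAsFactors = FALSE)
  out[!is.na(out$arm), , drop = FALSE]
}

#' ROC curve and area under the curve
#'
#' Rank-based AUC with half-credit for ties — identical to
#' `U / (n1 * n2)` from the Mann-Whitney statistic of positives vs
#' negatives — plus the full threshold-sweep curve.
#'
#' @param values numeric marker values (higher = more positive).
#' @param labels logical or 0/1 vector; TRUE/1 = positive class.
#' @return list: `auc`, `curve` (data.frame `threshold, tpr, fpr` over all
#'   distinct cut points, plus the two end points), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) {
    keep <- !is.na(values) & !is.na(labels)
    values <- values[keep]; labels <- labels[keep]
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(values)
  U <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(values[labels] >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(values[!labels] >= t) / n_neg,
                numeric(1))
  list(auc = auc, curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
       n_pos = n_pos, n_neg = n_neg)
}

#' RP cohort sample accounting
#'
#' Bookkeeping of a paired radical-prostatectomy cohort in which every
#' patient contributes two samples: patients with two benign samples, two
#' cancerous samples, or one of each, minus technically excluded samples,
#' give the benign/cancerous/total counts entering the analysis.
#'
#' @param both_benign,both_cancer,mixed patient counts by pair composition.
#' @param excluded_benign,excluded_cancer samples lost to technical
#'   exclusion.
#' @return list: `n_patients`, `benign`, `cancer`, `total`.
#' @export
rp_sample_accounting <- function(both_benign = 30L, both_cancer = 15L,
                                 mixed = 45L, excluded_benign = 1L,
                                 excluded_cancer = 1L) {
  benign <- 2L * both_benign + mixed - excluded_benign
  cancer <- 2L * both_cancer + mixed - excluded_cancer
  list(n_patients = both_benign + both_cancer + mixed,
       benign = benign, cancer = cancer, total = benign + cancer)
}

#' Full clinical validation report
#'
#' Assembles the four validation tables for every assayed gene:
#' \describe{
#'   \item{detection}{gene x group positives, n, percent}
#'   \item{contrasts}{the group-contrast battery (CP vs RP, CP vs RP-PCa,
#'     CP vs RP-B, RP-B vs CP-IPCa, CP-IPCa vs CP-B, RP-PCa vs RP-B) on
#'     all samples, plus the clinical splits (Gleason, stage, relapse,
#'     tumor content) on per-patient reduced values}
#'   \item{roc}{AUCs for RP-PCa vs CP and RP-B vs CP, per-patient reduced
#'     on the RP side}
#' }
#' The per-patient reduction (right lobe preferred) is applied exactly
#' where the corresponding printed tables require it: clinical splits and
#' ROC comparisons; group contrasts use all samples.
#'
#' @param dataset a `qpcr_dataset`.
#' @param clinical optional clinical table (defaults to
#'   `dataset$clinical`).
#' @param summary replicate summary, `"mean"` or `"median"`.
#' @return object of class `validation_report`: list of data.frames
#'   `detection`, `contrasts`, `roc`, plus `problems` (join failures).
#' @export
validation_report <- function(dataset, clinical = NULL,
                              summary = c("mean", "median")) {
  summary <- match.arg(summary)
  clinical <- clinical %||% dataset$clinical
  vals <- qpcr_sample_values(dataset, summary)
  genes <- unique(vals$gene)
  det <- detection_table(dataset)

  group_contrasts <- list(
    "CP vs RP" = c("CP-B+CP-IPCa", "RP-B+RP-PCa"),
    "CP vs RP-PCa" = c("CP-B+CP-IPCa", "RP-PCa"),
    "CP vs RP-B" = c("CP-B+CP-IPCa", "RP-B"),
    "RP-B vs CP-IPCa" = c("RP-B", "CP-IPCa"),
    "CP-IPCa vs CP-B" = c("CP-IPCa", "CP-B"),
    "RP-PCa vs RP-B" = c("RP-PCa", "RP-B")
  )
  clin_rules <- c(gleason = "gleason", stage = "stage", relapse = "relapse",
                  tumor_content = "tumor_content")

  problems <- character(0)
  rows <- list()
  roc_rows <- list()
  for (g in genes) {
    vg <- vals[vals$gene == g & !is.na(vals$copies_per_ug), , drop = FALSE]
    for (cn in names(group_contrasts)) {
      gc <- tryCatch(
        group_compare(dataset, g, group_contrasts[[cn]], values = vals),
        error = function(e) NULL)
      if (is.null(gc)) { problems <- c(problems, paste(g, cn)); next }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = cn, U = gc$U, p = gc$p, nA = gc$nA, nB = gc$nB,
        stringsAsFactors = FALSE)
    }
    # clinical splits on per-patient reduced RP values
    rp <- vg[grepl("^RP", vg$group), , drop = FALSE]
    if (nrow(rp) > 0L && !is.null(clinical) && nrow(clinical) > 0L) {
      red <- reduce_per_patient(rp[, c("sample", "patient", "lobe", "group",
                                       "copies_per_ug", "quantifiable")])
      for (rn in names(clin_rules)) {
        di <- dichotomize(clinical, clin_rules[[rn]])
        m <- merge(red, di, by = "patient")
        if (length(unique(m$arm)) < 2L) {
          problems <- c(problems, paste(g, rn, "(single arm)"))
          next
        }
        tt <- two_group_tests(m$value[m$arm == "A"], m$value[m$arm == "B"])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, contrast = rn, U = tt$U, p = tt$U_p,
          nA = sum(m$arm == "A"), nB = sum(m$arm == "B"),
          stringsAsFactors = FALSE)
      }
    }
    # ROC: per-patient reduced positives vs all CP samples as negatives
    cp <- vg[grepl("^CP", vg$group), , drop = FALSE]
    for (pos_grp in c("RP-PCa", "RP-B")) {
      pg <- vg[vg$group == pos_grp, , drop = FALSE]
      if (nrow(pg) == 0L || nrow(cp) == 0L) next
      red <- reduce_per_patient(pg[, c("sample", "patient", "lobe", "group",
                                       "copies_per_ug", "quantifiable")])
      rr <- roc_auc(c(red$value, cp$copies_per_ug),
                    c(rep(TRUE, nrow(red)), rep(FALSE, nrow(cp))))
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        gene = g, comparison = paste(pos_grp, "vs CP"), auc = rr$auc,
        n_pos = rr$n_pos, n_neg = rr$n_neg, stringsAsFactors = FALSE)
    }
  }

  structure(
    list(detection = det,
         contrasts = do.call(rbind, rows),
         roc = do.call(rbind, roc_rows),
         problems = problems),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:",
      length(unique(x$detection$gene)), "genes;",
      nrow(x$contrasts), "contrast rows;",
      nrow(x$roc), "ROC rows\n")
  invisible(x)
}
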