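#' Prioritization cascade configuration
#'
#' Parameters of the candidate-prioritization cascade: top-list size,
#' significance gate, SAM fudge factor, tissue-specificity ratio,
#' literature-novelty cutoff, survival risk quantile and the combined-rank
#' boost for genes differential in both contrasts.
#'
#' @param K top-list size per contrast (default 300).
#' @param alpha significance level for the gate and the survival filter.
#' @param adjust `"bonferroni"` (default gate) or `"bh"`.
#' @param s0 SAM fudge factor; `NULL` = median per-gene pooled standard
#'   error of the T-vs-N comparison.
#' @param tissue_ratio_min minimum prostate-to-median-other-tissue score
#'   ratio (boundary inclusive).
#' @param citation_max maximum allowed literature citation count (genes
#'   cited strictly more often are excluded as already well described).
#' @param risk_quantile fraction of patients labelled low-risk by the
#'   survival stratification (default 0.85: the highest-expressing 15%
#'   form the high-risk stratum).
#' @param boost combined-rank bonus subtracted from the T-vs-N rank of
#'   genes that also appear in the M-vs-T top list; `NULL` = `K`, which
#'   places every doubly-differential gene ahead of all others.
#' @param pseudocount pseudocount for fold-change computation.
#' @return object of class `prioritization_config`.
#' @export
prioritization_config <- function(K = 300L, alpha = 0.05,
                                  adjust = c("bonferroni", "bh"),
                                  s0 = NULL, tissue_ratio_min = 2,
                                  citation_max = 5L, risk_quantile = 0.85,
                                  boost = NULL, pseudocount = 0) {
  adjust <- match.arg(adjust)
  if (K < 1L) stop("K must be at least 1")
  if (risk_quantile <= 0 || risk_quantile >= 1)
    stop("risk_quantile must lie strictly between 0 and 1")
  if (citation_max < 0L) stop("citation_max must be non-negative")
  structure(list(K = as.integer(K), alpha = alpha, adjust = adjust, s0 = s0,
                 tissue_ratio_min = tissue_ratio_min,
                 citation_max = as.integer(citation_max),
                 risk_quantile = risk_quantile,
                 boost = if (is.null(boost)) as.integer(K) else as.integer(boost),
                 pseudocount = pseudocount),
            class = "prioritization_config")
}

#' Per-gene differential-expression statistics for one contrast
#'
#' Vectorized computation over all genes of: linear-scale log2 fold change,
#' Welch t (with Welch-Satterthwaite p), reference-group z score,
#' Mann-Whitney U (a-side; exact p for `nA*nB <= 400` without ties, else
#' tie-corrected normal approximation), Bonferroni and BH adjustments of
#' the t p-value, and the SAM d statistic. Agrees gene-by-gene with
#' [two_group_tests()] / [sam_d()].
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param idxA,idxB column indices of the two groups (A = later stage).
#' @param s0 SAM fudge factor.
#' @param pseudocount fold-change pseudocount.
#' @return data.frame, one row per gene: `gene, fc, t, t_p, z, z_p, U,
#'   U_p, p_bonf, q_bh, d`.
#' @export
de_contrast <- function(matrix, idxA, idxB, s0 = 0, pseudocount = 0) {
  a <- matrix[, idxA, drop = FALSE]
  b <- matrix[, idxB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  if (nA < 2L || nB < 2L) stop("need at least two samples per group")
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- rowSums((a - mA)^2) / (nA - 1)
  vB <- rowSums((b - mB)^2) / (nB - 1)

  fc <- log2_fold_change(matrix, idxA, idxB, pseudocount)

  se2 <- vA / nA + vB / nB
  t_stat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  t_p <- 2 * stats::pt(-abs(t_stat), df)
  zero <- vA == 0 & vB == 0
  t_stat[zero] <- 0; t_p[zero] <- 1

  z <- (mA - mB) / sqrt(vB)
  z_p <- 2 * stats::pnorm(-abs(z))
  z[zero] <- 0; z_p[zero] <- 1

  U <- apply(cbind(a, b), 1L, function(x) {
    sum(rank(x)[seq_len(nA)]) - nA * (nA + 1) / 2
  })
  ties <- apply(cbind(a, b), 1L, function(x) anyDuplicated(x) > 0L)
  U_p <- mw_pvalue(U, nA, nB, ties)

  ss <- rowSums((a - mA)^2) + rowSums((b - mB)^2)
  s <- sqrt((1 / nA + 1 / nB) * ss / (nA + nB - 2))
  d <- (mA - mB) / (s + s0)

  data.frame(gene = rownames(matrix), fc = fc, t = t_stat, t_p = t_p,
             z = z, z_p = z_p, U = U, U_p = U_p,
             p_bonf = adjust_pvalues(t_p, "bonferroni"),
             q_bh = adjust_pvalues(t_p, "bh"),
             d = d, row.names = NULL, stringsAsFactors = FALSE)
}

# two-sided Mann-Whitney p-values, vectorized; exact where permitted
mw_pvalue <- function(U, nA, nB, ties) {
  n <- length(U)
  p <- numeric(n)
  exact_ok <- (nA * nB <= 400) & !ties
  if (any(exact_ok)) {
    u <- U[exact_ok]
    lower <- 2 * stats::pwilcox(u, nA, nB)
    upper <- 2 * stats::pwilcox(u - 1, nA, nB, lower.tail = FALSE)
    p[exact_ok] <- pmin(1, ifelse(u > nA * nB / 2, upper, lower))
  }
  if (any(!exact_ok)) {
    # tie-corrected normal approximation with continuity correction,
    # as in stats::wilcox.test
    idx <- which(!exact_ok)
    mu <- nA * nB / 2
    sigma2 <- nA * nB * (nA + nB + 1) / 12
    p[idx] <- vapply(idx, function(i) {
      zz <- U[i] - mu
      zz <- zz - sign(zz) * 0.5
      min(1, 2 * stats::pnorm(-abs(zz / sqrt(sigma2))))
    }, numeric(1))
  }
  p
}

#' Differential-expression results for both study contrasts
#'
#' Computes the full per-gene statistic set for T-vs-N and M-vs-T plus the
#' three-group one-way ANOVA F across N/T/M.
#'
#' @param cohort an `expression_cohort` (see [gen_expression_cohort()]) or
#'   a list with `matrix` and `samples` (with `group` in N/T/M).
#' @param config a [prioritization_config()].
#' @return object of class `de_result`: list with data.frames `tn`, `mt`,
#'   `anova`, and the `s0` used.
#' @export
de_results <- function(cohort, config = prioritization_config()) {
  mat <- cohort$matrix
  grp <- cohort$samples$group
  for (g in c("N", "T", "M"))
    if (sum(grp == g) < 2L) stop("group ", g, " needs at least two samples")
  iN <- which(grp == "N"); iT <- which(grp == "T"); iM <- which(grp == "M")
  s0 <- config$s0 %||% sam_s0_default(mat, iT, iN)
  structure(
    list(tn = de_contrast(mat, iT, iN, s0, config$pseudocount),
         mt = de_contrast(mat, iM, iT, s0, config$pseudocount),
         anova = anova_f(mat, grp), s0 = s0),
    class = "de_result"
  )
}

#' Top-K candidate selection for one contrast
#'
#' Applies the significance gate (adjusted t-test p below `alpha`), orders
#' the surviving genes by absolute fold change (descending, ties broken
#' lexicographically by gene id) and truncates to the top `K`.
#'
#' @param de a `de_result` or a single contrast data.frame from
#'   [de_contrast()].
#' @param contrast `"tn"` or `"mt"` (ignored when `de` is a data.frame).
#' @param K top-list size.
#' @param alpha significance level of the gate.
#' @param adjust `"bonferroni"` or `"bh"`.
#' @return character vector of gene ids, ordered, length at most `K`.
#' @export
select_top_k <- function(de, contrast = c("tn", "mt"), K = 300L,
                         alpha = 0.05, adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (K < 1L) stop("K must be at least 1")
  tab <- if (is.data.frame(de)) de else de[[match.arg(contrast)]]
  p_adj <- if (adjust == "bonferroni") tab$p_bonf else tab$q_bh
  keep <- tab[!is.na(p_adj) & p_adj < alpha, , drop = FALSE]
  keep <- keep[order(-abs(keep$fc), keep$gene), , drop = FALSE]
  utils::head(keep$gene, K)
}

#' Combined ranking across the two contrasts
#'
#' The base order is the T-vs-N top list; genes that also appear in the
#' M-vs-T top list have their rank score reduced by `boost`, then the list
#' is stably re-sorted on the effective score. With the default
#' `boost = K`, every doubly-differential gene precedes every singly-
#' differential one.
#'
#' @param topTN,topMT deduplicated ordered gene lists from
#'   [select_top_k()].
#' @param boost rank bonus.
#' @return data.frame in final order: `gene, rank_tn, in_mt, rank_mt,
#'   effective, combined_rank`.
#' @export
combined_rank <- function(topTN, topMT, boost = length(topTN)) {
  if (anyDuplicated(topTN) || anyDuplicated(topMT))
    stop("top lists must be deduplicated")
  in_mt <- topTN %in% topMT
  eff <- seq_along(topTN) - boost * in_mt
  ord <- order(eff)  # stable: preserves TN order on ties
  data.frame(
    gene = topTN[ord],
    rank_tn = seq_along(topTN)[ord],
    in_mt = in_mt[ord],
    rank_mt = match(topTN, topMT)[ord],
    effective = eff[ord],
    combined_rank = seq_along(topTN),
    stringsAsFactors = FALSE
  )
}

#' Tissue-specificity filter
#'
#' Keeps a candidate iff its prostate tissue score divided by the median of
#' its non-prostate scores is at least `tissue_ratio_min` (boundary
#' inclusive). A candidate missing from the score table receives a
#' per-gene error verdict instead of failing the whole run.
#'
#' @param candidates character vector of gene ids.
#' @param tissue_scores data.frame: `gene` column plus one numeric column
#'   per tissue, including `prostate`.
#' @param tissue_ratio_min minimum ratio.
#' @return data.frame: `gene, ratio, pass, reason`.
#' @export
tissue_filter <- function(candidates, tissue_scores, tissue_ratio_min = 2) {
  if (!"prostate" %in% names(tissue_scores))
    stop("tissue [tissue]: score table lacks a 'prostate' column")
  other_cols <- setdiff(names(tissue_scores), c("gene", "prostate"))
  idx <- match(candidates, tissue_scores$gene)
  ratio <- rep(NA_real_, length(candidates))
  ok <- !is.na(idx)
  if (any(ok)) {
    pros <- tissue_scores$prostate[idx[ok]]
    others <- as.matrix(tissue_scores[idx[ok], other_cols, drop = FALSE])
    med <- apply(others, 1L, stats::median)
    ratio[ok] <- pros / med
  }
  pass <- !is.na(ratio) & ratio >= tissue_ratio_min
  reason <- ifelse(!ok, "missing tissue scores",
                   ifelse(pass, "", "tissue"))
  data.frame(gene = candidates, ratio = ratio, pass = pass,
             reason = reason, stringsAsFactors = FALSE)
}

#' Literature-novelty filter
#'
#' Keeps a candidate iff its citation count is at most `citation_max`
#' (genes mentioned strictly more often are excluded as previously
#' described). Missing counts are treated as 0 with a warning.
#'
#' @param candidates character vector of gene ids.
#' @param citations data.frame with columns `gene`, `count`.
#' @param citation_max maximum tolerated count.
#' @return data.frame: `gene, count, pass, reason`.
#' @export
literature_filter <- function(candidates, citations, citation_max = 5L) {
  cnt <- citations$count[match(candidates, citations$gene)]
  if (anyNA(cnt)) {
    warning("missing citation counts treated as 0 for: ",
            paste(candidates[is.na(cnt)], collapse = ", "))
    cnt[is.na(cnt)] <- 0L
  }
  if (any(cnt < 0)) stop("citation counts must be non-negative")
  pass <- cnt <= citation_max
  data.frame(gene = candidates, count = cnt, pass = pass,
             reason = ifelse(pass, "", "literature"),
             stringsAsFactors = FALSE)
}

#' Risk stratification by expression quantile
#'
#' Assigns `round(n * (1 - risk_quantile))` patients — those with the
#' highest expression — to the high-risk stratum; everyone else is
#' low-risk. Ties are broken by stable input order, so with the default
#' quantile of 0.85 exactly 15% of patients (rounded) are high-risk.
#'
#' @param values per-patient expression values.
#' @param risk_quantile fraction labelled low-risk (default 0.85).
#' @return character vector (`"high"` / `"low"`) aligned with `values`.
#' @export
km_stratify <- function(values, risk_quantile = 0.85) {
  n <- length(values)
  if (n < 2L) stop("need at least two patients")
  n_high <- round(n * (1 - risk_quantile))
  lab <- rep("low", n)
  if (n_high > 0) {
    ord <- order(-values, seq_len(n))  # stable under ties
    lab[ord[seq_len(n_high)]] <- "high"
  }
  lab
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimates per group via [survival::survfit()].
#'
#' @param times survival times (months), non-negative.
#' @param events event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param labels group labels; `NULL` for a single pooled curve.
#' @return named list of data.frames `time, n_risk, survival`, one per
#'   group, each step function starting at S(0) = 1.
#' @export
km_curves <- function(times, events, labels = NULL) {
  if (any(times < 0)) stop("survival times must be non-negative")
  events <- as.integer(as.logical(events))
  if (is.null(labels)) labels <- rep("all", length(times))
  labels <- as.character(labels)
  if (any(table(labels) == 0L)) stop("empty group")
  out <- list()
  for (g in unique(labels)) {
    i <- labels == g
    fit <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
    out[[g]] <- data.frame(time = fit$time, n_risk = fit$n.risk,
                           survival = fit$surv)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic via
#' [survival::survdiff()], plus the direction of the difference (which
#' stratum shows worse survival, i.e. more observed than expected events).
#'
#' @param times,events as in [km_curves()].
#' @param labels two-group labels.
#' @return list: `chisq`, `p`, `worse` (label of the stratum with observed
#'   events above expectation, `NA` when the groups are identical).
#' @export
logrank_test <- function(times, events, labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L) stop("need exactly two non-empty groups")
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(survival::Surv(times, events) ~ labels)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  grp_names <- sub("^labels=", "", names(sd$n))
  diff_oe <- sd$obs - sd$exp
  worse <- if (all(diff_oe == 0)) NA_character_ else grp_names[which.max(diff_oe)]
  list(chisq = chisq, p = p, worse = worse,
       obs = stats::setNames(sd$obs, grp_names),
       exp = stats::setNames(sd$exp, grp_names))
}

#' Run the full candidate-prioritization cascade
#'
#' Executes, in order: differential-expression statistics for both
#' contrasts; significance gate + fold-change ranking + top-K truncation
#' per contrast; combined ranking with the M-vs-T boost; tissue-specificity
#' filter; survival filter (a candidate passes iff the log-rank test
#' between its high- and low-expression strata is significant at `alpha`
#' *and* the high-expression stratum has the worse survival); literature-
#' novelty filter. Every removal is attributed to the first failing filter.
#'
#' @param cohort an `expression_cohort` (or compatible list with `matrix`,
#'   `samples`, `tissue_scores`, `citations`).
#' @param config a [prioritization_config()].
#' @return object of class `candidate_trace`: list with `trace` (per-
#'   candidate data.frame: gene, fc_tn, fc_mt, p_tn, p_mt, q, rank_tn,
#'   rank_mt, combined_rank, tissue_pass, survival_pass, literature_pass,
#'   first_fail, final), `final` (ordered character vector of surviving
#'   genes), and `audit` (per-stage bookkeeping).
#' @export
run_prioritization <- function(cohort, config = prioritization_config()) {
  if (is.null(cohort$matrix) || is.null(cohort$samples))
    stop("prioritize [input]: cohort must contain matrix and samples")
  if (is.null(cohort$tissue_scores))
    stop("prioritize [tissue]: tissue score table is missing")
  if (is.null(cohort$citations))
    stop("prioritize [literature]: citation table is missing")
  if (is.null(cohort$samples$survival_months) ||
      is.null(cohort$samples$event))
    stop("prioritize [survival]: survival annotations are missing")

  de <- de_results(cohort, config)
  topTN <- select_top_k(de, "tn", config$K, config$alpha, config$adjust)
  topMT <- select_top_k(de, "mt", config$K, config$alpha, config$adjust)
  audit <- list(config = unclass(config), s0 = de$s0,
                n_genes = nrow(cohort$matrix),
                n_top_tn = length(topTN), n_top_mt = length(topMT))

  if (length(topTN) == 0L) {
    trace <- data.frame(gene = character(0))
    return(structure(list(trace = trace, final = character(0),
                          audit = c(audit, list(n_final = 0L))),
                     class = "candidate_trace"))
  }

  cr <- combined_rank(topTN, topMT, config$boost)
  cand <- cr$gene

  tis <- tissue_filter(cand, cohort$tissue_scores, config$tissue_ratio_min)

  # survival filter: evaluated for every candidate (audit completeness)
  times <- cohort$samples$survival_months
  events <- cohort$samples$event
  surv_pass <- logical(length(cand))
  surv_p <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    vals <- cohort$matrix[cand[k], ]
    lab <- km_stratify(vals, config$risk_quantile)
    if (length(unique(lab)) < 2L) next
    lr <- logrank_test(times, events, lab)
    surv_p[k] <- lr$p
    surv_pass[k] <- is.finite(lr$p) && lr$p < config$alpha &&
      identical(lr$worse, "high")
  }

  lit <- literature_filter(cand, cohort$citations, config$citation_max)

  first_fail <- ifelse(!tis$pass, "tissue",
                       ifelse(!surv_pass, "survival",
                              ifelse(!lit$pass, "literature", "")))
  final_mask <- first_fail == ""

  tn_idx <- match(cand, de$tn$gene)
  mt_idx <- match(cand, de$mt$gene)
  trace <- data.frame(
    gene = cand,
    fc_tn = de$tn$fc[tn_idx], fc_mt = de$mt$fc[mt_idx],
    p_tn = de$tn$t_p[tn_idx], p_mt = de$mt$t_p[mt_idx],
    q = de$tn$q_bh[tn_idx],
    rank_tn = cr$rank_tn, rank_mt = cr$rank_mt,
    combined_rank = cr$combined_rank,
    tissue_ratio = tis$ratio, tissue_pass = tis$pass,
    survival_p = surv_p, survival_pass = surv_pass,
    citation_count = lit$count, literature_pass = lit$pass,
    first_fail = first_fail, final = final_mask,
    stringsAsFactors = FALSE
  )

  audit$n_pass_tissue <- sum(tis$pass)
  audit$n_pass_survival <- sum(tis$pass & surv_pass)
  audit$n_final <- sum(final_mask)

  structure(list(trace = trace, final = cand[final_mask], audit = audit),
            class = "candidate_trace")
}

#' @export
print.candidate_trace <- function(x, ...) {
  cat("candidate_trace:", nrow(x$trace), "candidates,",
      length(x$final), "in final list\n")
  if (length(x$final)) cat("  final:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
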