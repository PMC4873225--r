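#' Per-gene log2 fold change between two sample groups
#'
#' Fold change is computed on linear-scale group means:
#' `log2((meanA + pseudocount) / (meanB + pseudocount))`. The input matrix
#' is log2 expression; values are unlogged before averaging.
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param groupA,groupB column indices or names of the two groups
#'   (A is the "later" disease stage: positive FC = overexpression in A).
#' @param pseudocount non-negative stabilizer added to both linear means.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(matrix, groupA, groupB, pseudocount = 0) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  linA <- rowMeans(2^matrix[, groupA, drop = FALSE])
  linB <- rowMeans(2^matrix[, groupB, drop = FALSE])
  log2((linA + pseudocount) / (linB + pseudocount))
}

#' Two-group test battery: Welch t, z score, Mann-Whitney U
#'
#' Runs the three two-group tests used for candidate ranking on one gene's
#' values. The z score is the difference of means divided by the standard
#' deviation of the reference group `b` (one admissible reading of a
#' "Z-score test"; two-sided normal p). The Mann-Whitney U is reported from
#' the side of `a` (number of (a, b) pairs with a > b, ties counting half);
#' its p-value is exact when `nA * nB <= 400` and the data are tie-free,
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b numeric vectors (a = test group, b = reference group).
#' @return list with `t`, `t_p`, `z`, `z_p`, `U`, `U_p`, and
#'   `zero_variance` (TRUE when both groups are constant; the t and z
#'   p-values are then 1 by convention).
#' @export
two_group_tests <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  nA <- length(a); nB <- length(b)

  # Mann-Whitney U from the a-side via midranks
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (nA * nB <= 400) && !ties
  U_p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )

  zero_var <- FALSE
  if (nA >= 2L && nB >= 2L) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 && sb == 0) {
      zero_var <- TRUE
      t_stat <- 0; t_p <- 1; z <- 0; z_p <- 1
    } else {
      tt <- stats::t.test(a, b)   # Welch
      t_stat <- unname(tt$statistic); t_p <- tt$p.value
      if (sb == 0) {
        z <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
        z_p <- if (is.infinite(z)) 0 else 1
      } else {
        z <- (mean(a) - mean(b)) / sb
        z_p <- 2 * stats::pnorm(-abs(z))
      }
    }
  } else {
    t_stat <- NA_real_; t_p <- NA_real_; z <- NA_real_; z_p <- NA_real_
  }

  list(t = t_stat, t_p = t_p, z = z, z_p = z_p,
       U = U, U_p = U_p, zero_variance = zero_var)
}

#' Per-gene one-way ANOVA F across sample groups
#'
#' Vectorized one-way fixed-effects ANOVA over all genes at once, suitable
#' for the three-group (N/T/M) screen. Genes with zero residual and zero
#' between-group variance are guarded to `F = 0`, `p = 1`.
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param groups factor or character vector, one label per column.
#' @return data.frame with per-gene `F` and `p` (rownames = genes).
#' @export
anova_f <- function(matrix, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs at least two samples")
  n <- ncol(matrix); k <- nlevels(groups)

  grand <- rowMeans(matrix)
  ss_between <- 0
  ss_within <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    m_g <- rowMeans(matrix[, cols, drop = FALSE])
    ss_between <- ss_between + length(cols) * (m_g - grand)^2
    ss_within <- ss_within +
      rowSums((matrix[, cols, drop = FALSE] - m_g)^2)
  }
  df1 <- k - 1; df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  Fstat[ss_within == 0 & ss_between == 0] <- 0
  Fstat[ss_within == 0 & ss_between > 0] <- Inf
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  data.frame(F = Fstat, p = p, row.names = rownames(matrix))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up FDR, both via
#' [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values (q-values for `"bh"`).
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  pp <- p[!is.na(p)]
  if (length(pp) && (min(pp) < 0 || max(pp) > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' SAM-style moderated d statistic
#'
#' The significance-analysis-of-microarrays relative difference:
#' `d = (mean(a) - mean(b)) / (s + s0)`, where `s` is the pooled standard
#' error `sqrt((1/nA + 1/nB) * (SSa + SSb) / (nA + nB - 2))` and `s0` the
#' fudge factor that damps genes with tiny variance.
#'
#' @param a,b numeric vectors with at least two values each.
#' @param s0 non-negative fudge factor.
#' @return the d statistic (scalar).
#' @export
sam_d <- function(a, b, s0 = 0) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two values per group")
  if (s0 < 0) stop("s0 must be non-negative")
  nA <- length(a); nB <- length(b)
  ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  s <- sqrt((1 / nA + 1 / nB) * ss / (nA + nB - 2))
  if (s + s0 == 0) stop("zero pooled error and zero s0")
  (mean(a) - mean(b)) / (s + s0)
}

#' Default SAM fudge factor: median pooled standard error
#'
#' Computes `s0` as the median of the per-gene pooled standard errors of a
#' two-group comparison, a simple and stable choice for the damping
#' constant.
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param groupA,groupB column indices of the two groups.
#' @return scalar `s0`.
#' @export
sam_s0_default <- function(matrix, groupA, groupB) {
  a <- matrix[, groupA, drop = FALSE]
  b <- matrix[, groupB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  ss <- rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)
  stats::median(sqrt((1 / nA + 1 / nB) * ss / (nA + nB - 2)))
}
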