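# Independent oracles and small fixture builders shared across test files.

# Exhaustive-enumeration two-sided Mann-Whitney p-value: distribution of U
# over all C(nA+nB, nA) assignments of the pooled ranks to group A.
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); nA <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(n, nA)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# brute-force pairwise AUC with half credit for ties
auc_pairwise <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# tiny expression cohort for fast cascade tests
small_cohort <- function(seed = 1, n_genes = 500, n_decoy = 30,
                         group_sizes = c(N = 20L, T = 20L, M = 10L), ...) {
  gen_expression_cohort(sim_config(seed = seed, n_genes = n_genes,
                                   n_decoy = n_decoy,
                                   group_sizes = group_sizes, ...))
}

# hand-built qpcr_dataset wrapper around a long-format table
as_qpcr <- function(data, clinical = NULL) {
  structure(list(data = data, clinical = clinical, truth = NULL),
            class = "qpcr_dataset")
}

# one qpcr long-table row
qpcr_row <- function(sample, group, gene = "G1", reps = c(100, 110, 120),
                     patient = paste0("P", sample), lobe = NA_character_,
                     spike_added = 1e6, spike_measured = 5e5, rna_ug = 1,
                     ldl = 50) {
  data.frame(sample = sample, patient = patient, lobe = lobe,
             group = group, gene = gene,
             rep1 = reps[1], rep2 = reps[2], rep3 = reps[3],
             spike_added = spike_added, spike_measured = spike_measured,
             rna_ug = rna_ug, ldl = ldl, stringsAsFactors = FALSE)
}

# rasterized disk mask
disk_mask <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
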