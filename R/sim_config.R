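#' Simulation configuration for synthetic study data
#'
#' Builds and validates the configuration object consumed by all synthetic
#' generators ([gen_expression_cohort()], [gen_qpcr_cohort()],
#' [gen_organoid_image()], [gen_wound_series()]). A single integer `seed`
#' feeds a hierarchical stream: each generator derives its own child seed
#' from `seed` and its stream name, so adding a generator never perturbs the
#' draws of another.
#'
#' The defaults encode the study conditions the pipeline is designed around:
#' a three-group expression cohort (N = benign prostate, T = primary
#' tumor, M = metastasis) with a handful of planted marker genes; a
#' four-group qPCR cohort (CP-B, CP-IPCa, RP-B, RP-PCa) in which
#' cancer-adjacent benign tissue (RP-B) shows a multiplicative "field
#' effect" elevation over true normal tissue (CP-B), and overt cancer
#' (RP-PCa) a larger one; and two-channel organoid projections with known
#' protrusion counts and dead-cell fractions.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes in the expression matrix.
#' @param group_sizes named integer vector `c(N=,T=,M=)` of samples per group.
#' @param planted_genes data.frame with columns `gene`, `lfc_tn` (log2
#'   effect T vs N), `lfc_mt` (log2 effect M vs T), `tissue_ratio`
#'   (prostate-to-other-tissue score ratio), `citations` (PubMed-style
#'   co-citation count), `hazard_beta` (log hazard ratio per SD of
#'   expression). `NULL` gives the default eight-marker panel.
#' @param n_decoy number of decoy genes: genes given a real T-vs-N effect
#'   (drawn from `decoy_lfc_range`) but non-specific tissue scores and high
#'   citation counts, so they enter the top list yet fail downstream filters.
#' @param decoy_lfc_range range of decoy log2 T-vs-N effects.
#' @param noise_sd log2-scale residual standard deviation of expression.
#' @param baseline_log2 log2 baseline expression level.
#' @param surv_horizon administrative censoring horizon, months.
#' @param surv_base_rate baseline exponential event rate per month.
#' @param qpcr_group_sizes named integer vector
#'   `c("CP-B"=, "CP-IPCa"=, "RP-B"=, "RP-PCa"=)`.
#' @param qpcr_genes character vector of assayed gene names (defaults to the
#'   planted panel).
#' @param base_copies baseline transcript abundance in CP-B, copies/ug RNA.
#' @param field_effect multiplicative elevation of RP-B over CP-B.
#' @param ipca_effect multiplicative elevation of CP-IPCa over CP-B.
#' @param cancer_effect multiplicative elevation of RP-PCa over CP-B.
#' @param sample_log2_sd between-sample biological SD of log2 copy number.
#' @param rep_cv coefficient of variation of technical qPCR triplicates.
#' @param ldl lowest assay detection limit, copies/reaction.
#' @param spike_added copies of internal-standard spike-in RNA added.
#' @param recovery_range `c(lo, hi)` of the uniform spike-in recovery
#'   fraction, `0 < lo <= hi <= 1` (recoveries above 1 are tolerated on
#'   input data but not generated).
#' @param rna_ug_range range of total RNA input per sample, micrograms.
#' @param canvas image canvas size in pixels (square).
#' @param organoid_radius_range integer range of organoid radii, pixels.
#' @param n_organoids organoids per generated image.
#' @param protrusion_count protrusions per organoid (scalar or vector
#'   recycled over organoids).
#' @param protrusion_length,protrusion_width protrusion geometry, pixels.
#' @param dead_fraction fraction of in-mask pixels carrying dead-cell
#'   (ethidium-homodimer-like) signal.
#' @param live_level,dead_level 16-bit intensity levels of the two channels.
#' @param wound_size `c(height, width)` of wound-assay frames.
#' @param wound_width initial wound width, pixels.
#' @param wound_rate fraction of the initial width closed per frame.
#' @param n_frames number of wound frames (frame 0 .. n_frames-1).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L,
                       group_sizes = c(N = 20L, T = 20L, M = 20L),
                       planted_genes = NULL,
                       n_decoy = 400L,
                       decoy_lfc_range = c(1.2, 1.8),
                       noise_sd = 0.5,
                       baseline_log2 = 6,
                       surv_horizon = 120,
                       surv_base_rate = 0.012,
                       qpcr_group_sizes = c("CP-B" = 7L, "CP-IPCa" = 12L,
                                            "RP-B" = 20L, "RP-PCa" = 20L),
                       qpcr_genes = NULL,
                       base_copies = 1e4,
                       field_effect = 3,
                       ipca_effect = 2,
                       cancer_effect = 10,
                       sample_log2_sd = 1.0,
                       rep_cv = 0.15,
                       ldl = 50,
                       spike_added = 1e6,
                       recovery_range = c(0.3, 0.9),
                       rna_ug_range = c(0.5, 2),
                       canvas = 192L,
                       organoid_radius_range = c(14L, 20L),
                       n_organoids = 3L,
                       protrusion_count = 4L,
                       protrusion_length = 15L,
                       protrusion_width = 3L,
                       dead_fraction = 0.1,
                       live_level = 20000L,
                       dead_level = 30000L,
                       wound_size = c(120L, 160L),
                       wound_width = 60L,
                       wound_rate = 0.1,
                       n_frames = 10L) {
  if (is.null(planted_genes)) planted_genes <- default_planted_panel()
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    group_sizes = group_sizes, planted_genes = planted_genes,
    n_decoy = as.integer(n_decoy), decoy_lfc_range = decoy_lfc_range,
    noise_sd = noise_sd, baseline_log2 = baseline_log2,
    surv_horizon = surv_horizon, surv_base_rate = surv_base_rate,
    qpcr_group_sizes = qpcr_group_sizes,
    qpcr_genes = qpcr_genes %||% planted_genes$gene,
    base_copies = base_copies, field_effect = field_effect,
    ipca_effect = ipca_effect, cancer_effect = cancer_effect,
    sample_log2_sd = sample_log2_sd, rep_cv = rep_cv, ldl = ldl,
    spike_added = spike_added, recovery_range = recovery_range,
    rna_ug_range = rna_ug_range,
    canvas = as.integer(canvas),
    organoid_radius_range = as.integer(organoid_radius_range),
    n_organoids = as.integer(n_organoids),
    protrusion_count = as.integer(protrusion_count),
    protrusion_length = as.integer(protrusion_length),
    protrusion_width = as.integer(protrusion_width),
    dead_fraction = dead_fraction,
    live_level = as.integer(live_level), dead_level = as.integer(dead_level),
    wound_size = as.integer(wound_size),
    wound_width = as.integer(wound_width),
    wound_rate = wound_rate, n_frames = as.integer(n_frames)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default planted eight-marker panel
#'
#' Eight genes planted to survive the whole prioritization cascade: strong
#' T-vs-N overexpression, prostate-specific tissue scores, at most five
#' literature citations, and a positive survival hazard association. Three
#' of the eight additionally separate metastases from primary tumors, so
#' they gain the combined-rank boost.
#'
#' @return data.frame with one row per planted gene.
#' @export
default_planted_panel <- function() {
  data.frame(
    gene = sprintf("PLANT%02d", 1:8),
    lfc_tn = rep(2.0, 8),
    lfc_mt = c(1.5, 1.5, 1.5, 0, 0, 0, 0, 0),
    tissue_ratio = rep(10, 8),
    citations = c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 1L),
    hazard_beta = rep(2.0, 8),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_genes <= 0L) stop("n_genes must be positive")
  if (any(cfg$group_sizes <= 0L)) stop("all group sizes must be positive")
  if (!all(c("N", "T", "M") %in% names(cfg$group_sizes)))
    stop("group_sizes must be named N, T, M")
  pg <- cfg$planted_genes
  need <- c("gene", "lfc_tn", "lfc_mt", "tissue_ratio", "citations",
            "hazard_beta")
  if (!all(need %in% names(pg)))
    stop("planted_genes must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pg$gene)) stop("duplicate planted gene ids")
  if (nrow(pg) + cfg$n_decoy > cfg$n_genes)
    stop("n_genes too small for planted + decoy genes")
  if (any(cfg$qpcr_group_sizes < 0L))
    stop("qpcr group sizes must be non-negative")
  rr <- cfg$recovery_range
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] > 1 || rr[1] > rr[2])
    stop("recovery_range must satisfy 0 < lo <= hi <= 1")
  if (!(cfg$field_effect < cfg$cancer_effect) &&
      !(cfg$field_effect == 1 && cfg$cancer_effect == 1))
    stop("field_effect must be below cancer_effect (CP-B < RP-B < RP-PCa)")
  if (cfg$wound_rate < 0 || cfg$wound_rate > 1)
    stop("wound_rate must lie in [0, 1]")
  max_diam <- 2 * max(cfg$organoid_radius_range) + 2 * cfg$protrusion_length
  if (cfg$canvas <= max_diam)
    stop("canvas must exceed organoid diameter plus protrusion length")
  cfg
}

# Deterministic child seed for a named generator stream. FNV-style string
# hash folded into [0, 2^31 - 2]; keeps every derived seed a valid 32-bit
# integer regardless of the master seed the caller supplies.
child_seed <- function(seed, stream) {
  h <- 2166136261
  for (ch in utf8ToInt(stream)) {
    h <- (h * 16777619 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stream))
  expr
}
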