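#' siRNA knockdown efficiency
#'
#' Percent knockdown from normalized expression of treated vs untreated
#' control cells: `100 * (1 - treated / control)`. Negative values
#' (upregulation after treatment) are reported, not clamped, and flagged.
#'
#' @param treated,control normalized expression values (control > 0).
#' @return list: `percent`, `upregulated` flag.
#' @export
knockdown_efficiency <- function(treated, control) {
  if (control <= 0) stop("control expression must be positive")
  pct <- 100 * (1 - treated / control)
  list(percent = pct, upregulated = pct < 0)
}

#' Select the most effective siRNA for one gene
#'
#' Argmax of knockdown efficiency; ties broken by lexicographically
#' smaller siRNA id.
#'
#' @param efficiencies named numeric vector of percent knockdown per
#'   siRNA.
#' @return name of the selected siRNA.
#' @export
best_sirna <- function(efficiencies) {
  if (length(efficiencies) == 0L) stop("no efficiencies supplied")
  ord <- order(-efficiencies, names(efficiencies))
  names(efficiencies)[ord[1]]
}

#' Percent-of-control condition summary
#'
#' Summarizes replicate readouts per condition as a percentage of the
#' control condition's mean: `100 * mean(condition) / mean(control)`. The
#' control maps to exactly 100. Scale-invariant: multiplying every readout
#' by a positive constant changes nothing.
#'
#' @param data data.frame with columns `condition` and `readout`
#'   (non-negative values), one row per replicate.
#' @param control_condition name of the control condition (must be
#'   present).
#' @return data.frame: `condition, n, mean, sd, percent_of_control`, the
#'   control first, remaining conditions in first-appearance order.
#' @export
percent_of_control <- function(data, control_condition = "untreated") {
  if (!all(c("condition", "readout") %in% names(data)))
    stop("data must have columns 'condition' and 'readout'")
  if (any(data$readout < 0)) stop("readouts must be non-negative")
  if (!control_condition %in% data$condition)
    stop("control condition '", control_condition, "' missing from data")
  conds <- unique(data$condition)
  conds <- c(control_condition, setdiff(conds, control_condition))
  ctrl_mean <- mean(data$readout[data$condition == control_condition])
  if (ctrl_mean <= 0) stop("control mean must be positive")
  out <- do.call(rbind, lapply(conds, function(cc) {
    v <- data$readout[data$condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               percent_of_control = 100 * mean(v) / ctrl_mean,
               stringsAsFactors = FALSE)
  }))
  out$percent_of_control[out$condition == control_condition] <- 100
  rownames(out) <- NULL
  out
}

#' Wound-healing kinetics from a mask series
#'
#' Per-frame migration metrics of a scratch-wound assay:
#' \describe{
#'   \item{wound_width}{mean per-row horizontal gap extent (pixels) of the
#'     cell-free region inside the wound strip}
#'   \item{wound_confluence}{percent of the initial wound region occupied
#'     by cells}
#'   \item{relative_wound_density}{`100 * (w(t) - w(0)) / (c(t) - w(0))`,
#'     where `w` is the cell density inside the wound region and `c` the
#'     density outside it; clamped to `[0, 100]`}
#' }
#'
#' @param series a `wound_series` (see [gen_wound_series()]) or a list
#'   with `frames` (binary matrices, cells = 1) and `wound_region`
#'   (binary matrix).
#' @param pixel_scale optional micrometres per pixel applied to the width.
#' @return data.frame: `frame, wound_width, wound_confluence,
#'   relative_wound_density`.
#' @export
wound_metrics <- function(series, pixel_scale = 1) {
  frames <- series$frames
  wr <- series$wound_region > 0
  if (!sum(wr)) stop("wound region is empty")
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("frames must share dimensions")
  if (!identical(dim(wr), dims))
    stop("wound region must match frame dimensions")

  w0 <- mean(frames[[1]][wr] > 0)
  out <- lapply(seq_along(frames), function(t) {
    f <- frames[[t]] > 0
    w_t <- mean(f[wr])
    c_t <- if (any(!wr)) mean(f[!wr]) else NA_real_
    conf <- 100 * w_t
    denom <- c_t - w0
    rwd <- if (is.na(denom) || denom == 0) {
      if (!is.na(denom)) stop("degenerate series: outside density equals ",
                              "initial wound density")
      NA_real_
    } else {
      min(100, max(0, 100 * (w_t - w0) / denom))
    }
    # mean horizontal gap extent over rows that intersect the wound strip
    rows <- which(apply(wr, 1L, any))
    gaps <- vapply(rows, function(r) {
      cols <- which(wr[r, ])
      sum(!f[r, cols])
    }, numeric(1))
    data.frame(frame = t - 1L,
               wound_width = mean(gaps) * pixel_scale,
               wound_confluence = conf,
               relative_wound_density = rwd)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
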