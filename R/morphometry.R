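#' Maximum-intensity projection of an image stack
#'
#' Collapses a z-stack to a 2-D projection by per-pixel maximum, the
#' projection convention used for confocal organoid stacks.
#'
#' @param stack list of equally sized matrices, or a 3-D array with the
#'   third dimension indexing slices.
#' @return a single matrix.
#' @export
project_stack <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (!length(stack)) stop("need at least one slice")
  dims <- dim(stack[[1]])
  if (!all(vapply(stack, function(s) identical(dim(s), dims), logical(1))))
    stop("slice dimensions differ")
  Reduce(pmax, stack)
}

#' 8-connected component labeling
#'
#' Labels connected foreground components of a binary mask using
#' 8-connectivity. Labels are assigned in deterministic order of each
#' component's top-left pixel (smallest row, then smallest column).
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  # seeds in top-left order: sort by (row, col)
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  seeds <- fg[order(rows, cols)]
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      fi <- (frontier - 1L) %% nr + 1L
      fj <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        ni <- fi + off$di[k]; nj <- fj + off$dj[k]
        ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
        if (!any(ok)) next
        idx <- (nj[ok] - 1L) * nr + ni[ok]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Threshold segmentation of an organoid image
#'
#' Global threshold (Otsu by default, or a fixed value), 8-connected
#' component labeling, removal of components below `min_area`, and
#' deterministic relabeling by top-left pixel. An all-background image
#' yields zero labels, not an error.
#'
#' @param image non-negative intensity matrix (e.g. the live channel).
#' @param threshold `"otsu"` or a numeric cut; pixels strictly above it
#'   are foreground.
#' @param min_area minimum component size in pixels.
#' @return integer label matrix.
#' @export
segment <- function(image, threshold = "otsu", min_area = 20L) {
  if (!length(image)) stop("image is empty")
  rng <- range(image)
  if (identical(threshold, "otsu")) {
    if (rng[1] == rng[2]) return(matrix(0L, nrow(image), ncol(image)))
    threshold <- EBImage::otsu(EBImage::Image(image / rng[2]),
                               range = c(0, 1)) * rng[2]
  }
  mask <- image > threshold
  lab <- label_components(mask)
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)  # preserves top-left order
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Moore-neighbor boundary tracing; returns the chain-code perimeter
# (axial step = 1, diagonal step = sqrt(2)) and the traced boundary pixels
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask > 0
  fg <- which(pad)
  if (!length(fg)) return(list(perimeter = 0, boundary = NULL))
  rows <- (fg - 1L) %% (nr + 2L) + 1L
  cols <- (fg - 1L) %/% (nr + 2L) + 1L
  o <- order(rows, cols)
  start <- c(rows[o[1]], cols[o[1]])
  if (length(fg) == 1L)
    return(list(perimeter = 1,
                boundary = matrix(start - 1L, ncol = 2)))
  nbr <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                ncol = 2, byrow = TRUE)
  cur <- start; b <- 6L  # backtrack direction: came from the west
  per <- 0
  bpix <- list(start)
  repeat {
    moved <- FALSE
    for (k in 0:7) {
      d <- (b + k) %% 8L
      cand <- cur + nbr[d + 1L, ]
      if (pad[cand[1], cand[2]]) {
        per <- per + if (sum(abs(cand - cur)) == 2L) sqrt(2) else 1
        b <- (d + 5L) %% 8L
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel
    if (all(cur == start)) break
    bpix[[length(bpix) + 1L]] <- cur
  }
  list(perimeter = max(per, 1),
       boundary = do.call(rbind, bpix) - 1L)  # unpad
}

#' Shape features of a single organoid mask
#'
#' Area (pixel count), perimeter (Moore boundary-step estimator: axial
#' steps weight 1, diagonal steps sqrt(2)), roundness
#' (`min(1, 4 * pi * area / perimeter^2)`, clamped against discretization
#' overshoot) and roughness (mean absolute radial deviation of the
#' boundary outline from the outline of the morphologically opened mask,
#' normalized by the equivalent radius `sqrt(area / pi)`).
#'
#' @param mask logical or 0/1 matrix containing one connected component.
#' @param smooth_radius structuring-disk radius for the roughness
#'   reference outline; `NULL` = a quarter of the equivalent radius (at
#'   least 2).
#' @return list: `area`, `perimeter`, `roundness`, `roughness`.
#' @export
shape_features <- function(mask, smooth_radius = NULL) {
  mask <- mask > 0
  area <- sum(mask)
  if (area == 0L) stop("empty mask")
  tb <- trace_boundary(mask)
  perimeter <- tb$perimeter
  roundness <- min(1, 4 * pi * area / perimeter^2)
  r_eq <- sqrt(area / pi)
  smooth_radius <- smooth_radius %||% max(2L, round(r_eq / 4))
  smooth <- open_mask(mask, smooth_radius)
  roughness <- if (sum(smooth) == 0L) NA_real_ else {
    ro <- radial_outline(mask)
    rs <- radial_outline(smooth, center = attr(ro, "center"))
    common <- !is.na(ro) & !is.na(rs)
    if (!any(common)) NA_real_
    else mean(abs(ro[common] - rs[common])) / r_eq
  }
  list(area = area, perimeter = perimeter, roundness = roundness,
       roughness = roughness)
}

# morphological opening with a disc structuring element (EBImage)
open_mask <- function(mask, radius) {
  if (radius < 1) return(mask > 0)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  as.matrix(EBImage::opening(EBImage::Image(1 * (mask > 0)), brush)) > 0
}

# max radius of mask pixels per angular bin around the mask centroid
radial_outline <- function(mask, n_bins = 72L, center = NULL) {
  px <- which(mask, arr.ind = TRUE)
  if (is.null(center)) center <- colMeans(px)
  dy <- px[, 1] - center[1]; dx <- px[, 2] - center[2]
  ang <- atan2(dy, dx)
  bin <- pmin(n_bins, 1L + floor((ang + pi) / (2 * pi) * n_bins))
  r <- sqrt(dy^2 + dx^2)
  out <- rep(NA_real_, n_bins)
  agg <- tapply(r, bin, max)
  out[as.integer(names(agg))] <- agg
  attr(out, "center") <- center
  out
}

#' Protrusion count and protrusion-area fraction
#'
#' The organoid body is the morphological opening of the mask with a disk
#' of `opening_radius`; protrusions ("apps") are the 8-connected
#' components of mask minus body with at least `min_spike_area` pixels.
#' Returns their count and the fraction of the mask area they cover. If
#' the opening erases the mask entirely the result is flagged degenerate
#' with a count of 0.
#'
#' @param mask logical or 0/1 matrix, one organoid.
#' @param opening_radius structuring-disk radius, at least 1.
#' @param min_spike_area minimum protrusion size in pixels.
#' @return list: `app_count`, `app_index`, `degenerate`.
#' @export
protrusion_features <- function(mask, opening_radius, min_spike_area = 5L) {
  if (opening_radius < 1) stop("opening_radius must be at least 1")
  mask <- mask > 0
  body <- open_mask(mask, opening_radius)
  if (sum(body) == 0L)
    return(list(app_count = 0L, app_index = 0, degenerate = TRUE))
  spikes <- mask & !body
  lab <- label_components(spikes)
  if (max(lab) == 0L)
    return(list(app_count = 0L, app_index = 0, degenerate = FALSE))
  sizes <- tabulate(lab)
  keep <- sizes >= min_spike_area
  list(app_count = sum(keep),
       app_index = sum(sizes[keep]) / sum(mask),
       degenerate = FALSE)
}

#' Intensity features over an organoid mask
#'
#' Live-channel density and dead/apoptosis channel statistics: density is
#' the mean live intensity over the mask; the dead (ethidium-homodimer-
#' like) and apoptosis channels contribute a mean over the mask and a
#' summed total. When no separate apoptosis reporter channel is supplied,
#' the dead channel is used for both readouts.
#'
#' @param live,dead intensity matrices sharing the mask's shape.
#' @param mask logical or 0/1 matrix.
#' @param apoptosis optional apoptosis reporter channel.
#' @return list: `density`, `ethd_mean`, `ethd_total`, `apoptosis_mean`,
#'   `apoptosis_total`.
#' @export
intensity_features <- function(live, dead, mask, apoptosis = NULL) {
  mask <- mask > 0
  if (!sum(mask)) stop("empty mask")
  if (!identical(dim(live), dim(mask)) || !identical(dim(dead), dim(mask)))
    stop("channel dimensions must match the mask")
  apoptosis <- apoptosis %||% dead
  list(density = mean(live[mask]),
       ethd_mean = mean(dead[mask]), ethd_total = sum(dead[mask]),
       apoptosis_mean = mean(apoptosis[mask]),
       apoptosis_total = sum(apoptosis[mask]))
}

#' Cell number estimate for one organoid
#'
#' With a nuclei image: the count of segmented nuclei blobs inside the
#' mask. Without one: `round(area / typical_cell_area)`.
#'
#' @param mask logical or 0/1 matrix.
#' @param nuclei_image optional intensity matrix of a nuclear stain.
#' @param typical_cell_area fallback cell footprint, pixels.
#' @return integer estimate.
#' @export
cell_number <- function(mask, nuclei_image = NULL,
                        typical_cell_area = NULL) {
  mask <- mask > 0
  if (!is.null(nuclei_image)) {
    blobs <- label_components(nuclei_image > 0 & mask)
    return(max(blobs))
  }
  if (is.null(typical_cell_area) || typical_cell_area <= 0)
    stop("need a nuclei image or a positive typical_cell_area")
  as.integer(round(sum(mask) / typical_cell_area))
}

#' Per-organoid morphometric records for one image
#'
#' Segments the live channel, then computes shape, protrusion and
#' intensity features per organoid. The default opening radius for
#' protrusion detection is adaptive: a quarter of the median equivalent
#' radius of the segmented organoids (at least 1).
#'
#' @param image an `organoid_image` (see [gen_organoid_image()]) or a list
#'   with `live` and `dead` matrices.
#' @param opening_radius protrusion opening radius; `NULL` = adaptive.
#' @param min_spike_area minimum protrusion size, pixels.
#' @param min_area minimum organoid size, pixels.
#' @param threshold segmentation threshold (see [segment()]).
#' @param typical_cell_area cell footprint for the cell-number estimate.
#' @return data.frame, one row per organoid: `organoid, area, perimeter,
#'   roundness, roughness, app_count, app_index, density, cell_number,
#'   ethd_mean, ethd_total, apoptosis_mean, apoptosis_total`.
#' @export
morphometric_record <- function(image, opening_radius = NULL,
                                min_spike_area = 5L, min_area = 20L,
                                threshold = "otsu",
                                typical_cell_area = 100) {
  lab <- segment(image$live, threshold, min_area)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(organoid = integer(0)))
  areas <- tabulate(lab)
  r_eq_med <- stats::median(sqrt(areas / pi))
  opening_radius <- opening_radius %||% max(1L, round(r_eq_med / 4))
  rows <- lapply(seq_len(n), function(k) {
    m <- lab == k
    sf <- shape_features(m)
    pf <- protrusion_features(m, opening_radius, min_spike_area)
    itf <- intensity_features(image$live, image$dead, m)
    data.frame(organoid = k, area = sf$area, perimeter = sf$perimeter,
               roundness = sf$roundness, roughness = sf$roughness,
               app_count = pf$app_count, app_index = pf$app_index,
               density = itf$density,
               cell_number = cell_number(m, typical_cell_area = typical_cell_area),
               ethd_mean = itf$ethd_mean, ethd_total = itf$ethd_total,
               apoptosis_mean = itf$apoptosis_mean,
               apoptosis_total = itf$apoptosis_total)
  })
  out <- do.call(rbind, rows)
  attr(out, "opening_radius") <- opening_radius
  out
}

#' Condition-level percent-of-control morphometry summary
#'
#' Summarizes per-organoid records per condition in the shape of a
#' silencing-impact table: mean apoptosis signal, total apoptosis signal,
#' mean dead-cell (EthD) signal, total dead-cell signal, and summed
#' organoid area — each expressed as a percentage of the control
#' condition. The control row is identically 100%.
#'
#' @param records data.frame of [morphometric_record()] rows with an added
#'   `condition` column.
#' @param control_condition name of the control condition.
#' @return data.frame: `condition, apoptosis_mean, apoptosis_total,
#'   ethd_mean, ethd_total, area_total` (percent of control). Conditions
#'   without records yield `NA` rows with a warning.
#' @export
condition_summary <- function(records, control_condition = "untreated") {
  if (!"condition" %in% names(records))
    stop("records must carry a 'condition' column")
  if (!control_condition %in% records$condition)
    stop("control condition '", control_condition, "' missing")
  conds <- unique(records$condition)
  conds <- c(control_condition, setdiff(conds, control_condition))
  summarize <- function(cc) {
    r <- records[records$condition == cc, , drop = FALSE]
    if (nrow(r) == 0L || all(is.na(r$area))) {
      warning("condition '", cc, "' has no records")
      return(c(apoptosis_mean = NA, apoptosis_total = NA, ethd_mean = NA,
               ethd_total = NA, area_total = NA))
    }
    c(apoptosis_mean = mean(r$apoptosis_mean),
      apoptosis_total = sum(r$apoptosis_total),
      ethd_mean = mean(r$ethd_mean),
      ethd_total = sum(r$ethd_total),
      area_total = sum(r$area))
  }
  ctrl <- summarize(control_condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    v <- 100 * summarize(cc) / ctrl
    data.frame(condition = cc, t(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
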