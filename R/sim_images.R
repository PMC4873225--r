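#' Generate a synthetic two-channel organoid projection image
#'
#' Emulates a maximum-intensity projection of a live/dead stained 3D
#' organoid culture: channel 1 carries the live-cell signal (filled disks
#' with rectangular protrusions radiating outward, mimicking invasive
#' processes), channel 2 the dead-cell signal (speckles at a configured
#' fraction of in-mask pixels, mimicking ethidium-homodimer uptake).
#' Organoids are placed without overlap; placement failure after bounded
#' retries is an error. Coordinates are 0-based (row, column); masks are
#' 8-connected foreground.
#'
#' @param config a [sim_config()] object.
#' @param index integer; distinguishes the random stream of successive
#'   images generated under one config (image `index` is reproducible on
#'   its own).
#' @return object of class `organoid_image`: list with `live` and `dead`
#'   (integer matrices, 16-bit intensity range), and `truth` (data.frame:
#'   organoid, center_row, center_col, radius, area, protrusions,
#'   dead_fraction; 0-based centers).
#' @export
gen_organoid_image <- function(config, index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, paste0("organoid:", index), {
    C <- config$canvas
    live <- matrix(0L, C, C)
    dead <- matrix(0L, C, C)
    n_org <- config$n_organoids
    prot_n <- rep_len(config$protrusion_count, n_org)
    L <- config$protrusion_length
    W <- config$protrusion_width

    centers <- matrix(NA_real_, n_org, 2)
    radii <- integer(n_org)
    margin_gap <- 4  # minimum clearance between organoid envelopes
    for (i in seq_len(n_org)) {
      r <- sample(seq(config$organoid_radius_range[1],
                      config$organoid_radius_range[2]), 1)
      reach <- r + if (prot_n[i] > 0) L else 0
      placed <- FALSE
      for (try in seq_len(200L)) {
        cy <- stats::runif(1, reach + 2, C - reach - 1)
        cx <- stats::runif(1, reach + 2, C - reach - 1)
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            reach_j <- radii[j] + if (prot_n[j] > 0) L else 0
            d <- sqrt((cy - centers[j, 1])^2 + (cx - centers[j, 2])^2)
            if (d < reach + reach_j + margin_gap) { ok <- FALSE; break }
          }
        }
        if (ok) {
          centers[i, ] <- c(cy, cx)
          radii[i] <- r
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place organoid ", i,
             " without overlap after 200 retries; enlarge the canvas")
    }

    truth <- vector("list", n_org)
    for (i in seq_len(n_org)) {
      mask <- raster_disk(C, centers[i, 1], centers[i, 2], radii[i])
      if (prot_n[i] > 0) {
        angles <- (seq_len(prot_n[i]) - 1) * 2 * pi / prot_n[i] +
          stats::runif(1, 0, 2 * pi)
        for (a in angles) {
          mask <- mask | raster_ray_rect(C, centers[i, 1], centers[i, 2],
                                         a, radii[i] - 2, radii[i] + L, W)
        }
      }
      live[mask] <- config$live_level
      n_dead <- floor(config$dead_fraction * sum(mask))
      if (n_dead > 0) {
        px <- sample(which(mask), n_dead)
        dead[px] <- config$dead_level
      }
      truth[[i]] <- data.frame(
        organoid = i,
        center_row = centers[i, 1] - 1, center_col = centers[i, 2] - 1,
        radius = radii[i], area = sum(mask), protrusions = prot_n[i],
        dead_fraction = if (sum(mask) > 0) n_dead / sum(mask) else 0
      )
    }

    structure(list(live = live, dead = dead, truth = do.call(rbind, truth)),
              class = "organoid_image")
  })
}

# filled disk mask on an n x n canvas (1-based center coordinates)
raster_disk <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# rectangle of width w along the ray at angle `ang` from (cy, cx),
# covering radial distances [r0, r1]
raster_ray_rect <- function(n, cy, cx, ang, r0, r1, w) {
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  # coordinates along (u) and across (v) the ray
  u <- yy * sin(ang) + xx * cos(ang)
  v <- -yy * cos(ang) + xx * sin(ang)
  u >= r0 & u <= r1 & abs(v) <= w / 2
}

#' Generate a synthetic closing-wound mask series
#'
#' Emulates a scratch-wound (wound-healing) assay: a confluent binary
#' monolayer with a central vertical cell-free strip of fixed initial
#' width that fills inward from both edges at a constant rate. At frame
#' `t` (0-based) the remaining wound width is
#' `round(wound_width * max(0, 1 - wound_rate * t))`.
#'
#' @param config a [sim_config()] object.
#' @return object of class `wound_series`: list with `frames` (list of
#'   binary matrices, cells = 1), `wound_region` (binary matrix, initial
#'   wound strip), `timestamps` (hours, one per frame) and `truth`
#'   (data.frame: frame, width_px).
#' @export
gen_wound_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  H <- config$wound_size[1]; Wd <- config$wound_size[2]
  w0 <- config$wound_width
  if (w0 >= Wd) stop("wound_width must be below the frame width")
  center <- (Wd + 1) / 2
  strip <- function(w) {
    m <- matrix(FALSE, H, Wd)
    if (w > 0) {
      lo <- ceiling(center - w / 2); hi <- floor(center + (w - 1) / 2)
      lo <- max(1L, lo); hi <- min(Wd, hi)
      m[, lo:hi] <- TRUE
    }
    m
  }
  wound_region <- strip(w0)
  widths <- vapply(seq_len(config$n_frames) - 1L, function(t)
    as.integer(round(w0 * max(0, 1 - config$wound_rate * t))), integer(1))
  frames <- lapply(widths, function(w) {
    f <- matrix(1L, H, Wd)
    f[strip(w)] <- 0L
    f
  })
  structure(
    list(frames = frames, wound_region = wound_region,
         timestamps = seq_len(config$n_frames) - 1L,
         truth = data.frame(frame = seq_len(config$n_frames) - 1L,
                            width_px = widths)),
    class = "wound_series"
  )
}
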