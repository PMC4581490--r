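#' Archetype: named staining windows along the body axis
#'
#' An archetype describes a cylindrically symmetric staining pattern as a set
#' of named expression-domain windows on the arc-length axis `[0, 1]`
#' (0 = animal/oral pole, 1 = vegetal/aboral pole), each with its own
#' staining amplitude. Window edges are smooth logistic ramps of width
#' `edge_width`: real ISH domain boundaries are gradients a few percent of
#' the body axis wide, not pixel-sharp steps.
#'
#' @param stage developmental stage the archetype belongs to.
#' @param windows data frame with columns `name`, `start`, `end` and
#'   optionally `amplitude` (default 0.8); `0 <= start < end <= 1`, names
#'   unique.
#' @param edge_width logistic ramp width on the arc axis (default 0.04).
#' @return Object of class `archetype_spec`.
#' @export
#' @examples
#' a <- archetype_spec("blastula", data.frame(name = "Cd", start = 0, end = 0.3))
#' curve(archetype_intensity(a, x), 0, 1)
archetype_spec <- function(stage, windows, edge_width = 0.04) {
  stage <- canonical_stage(stage)
  windows <- as.data.frame(windows)
  stopifnot(all(c("name", "start", "end") %in% names(windows)))
  if (!"amplitude" %in% names(windows)) windows$amplitude <- 0.8
  if (any(windows$start < 0 | windows$end > 1 | windows$start >= windows$end)) {
    stop("windows must satisfy 0 <= start < end <= 1")
  }
  if (anyDuplicated(windows$name)) stop("window names must be unique per stage")
  if (edge_width <= 0) stop("edge_width must be positive")
  structure(list(stage = stage, windows = windows, edge_width = edge_width),
            class = "archetype_spec")
}

#' Evaluate an archetype's staining intensity along the arc axis
#'
#' Each window contributes `amplitude * (plogis((s - start)/w) -
#' plogis((s - end)/w))` with `w = edge_width / 6` (so the ramp from 5 to 95
#' percent spans about `edge_width`); overlapping windows saturate via the
#' pointwise maximum, and the result is capped at 1.
#'
#' @param archetype an [archetype_spec()].
#' @param s arc-length positions in \[0,1\].
#' @return Numeric vector of intensities in \[0,1\].
#' @export
archetype_intensity <- function(archetype, s) {
  stopifnot(inherits(archetype, "archetype_spec"))
  w <- archetype$edge_width / 6
  out <- rep(0, length(s))
  for (k in seq_len(nrow(archetype$windows))) {
    win <- archetype$windows[k, ]
    # a window touching an axis end extends fully to the pole (no ramp there)
    left <- if (win$start <= 0) rep(1, length(s)) else stats::plogis((s - win$start) / w)
    right <- if (win$end >= 1) rep(0, length(s)) else stats::plogis((s - win$end) / w)
    out <- pmax(out, win$amplitude * (left - right))
  }
  pmin(out, 1)
}

# elliptical radius in direction t (t = 0 points "up" toward the pole,
# direction (sin t, -cos t) in image coordinates with y down)
.ellipse_radius <- function(t, a, b) {
  a * b / sqrt((b * sin(t))^2 + (a * cos(t))^2)
}

# radial boundary functions for a (possibly invaginated) annulus half-scene
.scene_radii <- function(shape) {
  dent <- function(t) 1 - shape$invagination_depth *
    exp(-(t / shape$invagination_width)^2)
  list(
    outer = function(t) .ellipse_radius(t, shape$outer_a, shape$outer_b) * dent(t),
    inner = function(t) (.ellipse_radius(t, shape$outer_a, shape$outer_b) -
                           shape$layer_thickness) * dent(t)
  )
}

#' Shape parameters for a synthetic embryo scene
#'
#' The embryo cell layer is an elliptical annulus half (a half-meridian:
#' the half with x to the right of the center), optionally with an
#' invagination dent at the animal/oral pole to mimic gastrula-like
#' morphologies. All lengths are in pixels.
#'
#' @param width,height image size.
#' @param center x, y of the embryo center (default: left-of-center so the
#'   right half-meridian fits the frame).
#' @param outer_a,outer_b semi-axes of the outer boundary ellipse.
#' @param layer_thickness radial thickness of the cell layer.
#' @param invagination_depth fractional inward dent at the oral pole
#'   (0 = blastula-like; 0.2-0.4 = gastrula-like).
#' @param invagination_width angular width (radians) of the dent.
#' @return A list of validated shape parameters.
#' @export
embryo_shape <- function(width = 240, height = 240,
                         center = c(width * 0.32, height / 2),
                         outer_a = 90, outer_b = 100,
                         layer_thickness = 26,
                         invagination_depth = 0,
                         invagination_width = 0.5) {
  stopifnot(width > 0, height > 0, outer_a > 0, outer_b > 0,
            layer_thickness > 0, invagination_depth >= 0,
            invagination_depth < 1, invagination_width > 0)
  if (layer_thickness >= min(outer_a, outer_b) * (1 - invagination_depth)) {
    stop("inner boundary is not strictly inside the outer boundary")
  }
  list(width = as.integer(width), height = as.integer(height),
       center = as.numeric(center), outer_a = outer_a, outer_b = outer_b,
       layer_thickness = layer_thickness,
       invagination_depth = invagination_depth,
       invagination_width = invagination_width)
}

#' Generate a synthetic embryo ISH image with ground truth
#'
#' Paints a half-meridian embryo scene: pixels inside the cell layer take
#' `background + archetype_intensity(s)` where `s` is the arc-length position
#' of the pixel (via the midline arc-length map); pixels outside take the
#' background level. Optional hard-edged disc artifacts (bright or dark) are
#' injected at given arc positions, and Gaussian noise truncated at zero is
#' added last. The true morphology (101 index-paired boundary points uniform
#' in midline arc length), the true noise-free profile function and the
#' exact arc intervals touched by artifacts are returned as ground truth.
#'
#' @param shape an [embryo_shape()].
#' @param archetype an [archetype_spec()].
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param artifact_spec `NULL`, or a data frame with columns `position`
#'   (arc position in \[0,1\]), `delta` (intensity offset, may be negative)
#'   and `radius` (disc radius in pixels).
#' @param background background intensity level (default 0.1).
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical scene.
#' @param n_boundary_points point pairs in the emitted true morphology.
#' @return Object of class `image_scene` with fields `image` (numeric
#'   matrix), `true_morphology`, `true_profile` (function of arc position),
#'   `artifact_regions` (list of `c(start, end)` intervals), `background`,
#'   and `seed`.
#' @export
generate_embryo_image <- function(shape = embryo_shape(), archetype,
                                  noise_sd = 0, artifact_spec = NULL,
                                  background = 0.1, seed = 1L,
                                  n_boundary_points = 101L) {
  stopifnot(inherits(archetype, "archetype_spec"), noise_sd >= 0,
            background >= 0)
  radii <- .scene_radii(shape)

  # midline arc-length map s(t) on a fine angular grid
  tg <- seq(0, pi, length.out = 2001L)
  rmid <- (radii$inner(tg) + radii$outer(tg)) / 2
  pts <- cbind(shape$center[1] + rmid * sin(tg),
               shape$center[2] - rmid * cos(tg))
  cum <- .cum_arclength(pts)
  total_len <- cum[length(cum)]
  s_of_t <- function(t) stats::approx(tg, cum / total_len, xout = t,
                                      rule = 2, ties = "ordered")$y
  t_of_s <- function(s) stats::approx(cum / total_len, tg, xout = s,
                                      rule = 2, ties = "ordered")$y

  # pixel-wise membership and arc position
  xs <- (seq_len(shape$width)) - 0.5
  ys <- (seq_len(shape$height)) - 0.5
  dx <- outer(rep(1, shape$height), xs - shape$center[1])
  dy <- outer(ys - shape$center[2], rep(1, shape$width))
  r <- sqrt(dx^2 + dy^2)
  tt <- atan2(dx, -dy)                       # angle from the pole direction
  half <- tt >= 0 & tt <= pi
  tt_clamped <- pmin(pmax(tt, 0), pi)
  in_layer <- half & r >= radii$inner(tt_clamped) & r <= radii$outer(tt_clamped)
  s_pix <- matrix(s_of_t(tt_clamped), shape$height, shape$width)

  img <- matrix(background, shape$height, shape$width)
  img[in_layer] <- background + archetype_intensity(archetype, s_pix[in_layer])

  artifact_regions <- list()
  if (!is.null(artifact_spec) && nrow(as.data.frame(artifact_spec)) > 0) {
    artifact_spec <- as.data.frame(artifact_spec)
    stopifnot(all(c("position", "delta", "radius") %in% names(artifact_spec)))
    if (any(artifact_spec$position < 0 | artifact_spec$position > 1)) {
      stop("artifact positions must lie within [0, 1]")
    }
    for (k in seq_len(nrow(artifact_spec))) {
      a <- artifact_spec[k, ]
      t0 <- t_of_s(a$position)
      r0 <- (radii$inner(t0) + radii$outer(t0)) / 2
      cx <- shape$center[1] + r0 * sin(t0)
      cy <- shape$center[2] - r0 * cos(t0)
      hit <- (dx + shape$center[1] - cx)^2 + (dy + shape$center[2] - cy)^2 <=
        a$radius^2
      img[hit] <- pmax(img[hit] + a$delta, 0)
      touched <- hit & in_layer
      if (any(touched)) {
        artifact_regions[[k]] <- c(min(s_pix[touched]), max(s_pix[touched]))
      } else {
        artifact_regions[[k]] <- c(max(0, a$position - a$radius / total_len),
                                   min(1, a$position + a$radius / total_len))
      }
    }
  }

  if (noise_sd > 0) {
    img <- withr::with_seed(as.integer(seed), {
      pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img)), 0)
    })
  }

  # true morphology: boundary points at angles uniform in midline arc length
  t_pts <- t_of_s(seq(0, 1, length.out = n_boundary_points))
  inner <- cbind(shape$center[1] + radii$inner(t_pts) * sin(t_pts),
                 shape$center[2] - radii$inner(t_pts) * cos(t_pts))
  outer_pts <- cbind(shape$center[1] + radii$outer(t_pts) * sin(t_pts),
                     shape$center[2] - radii$outer(t_pts) * cos(t_pts))

  structure(list(
    image = img,
    true_morphology = boundary_morphology(inner, outer_pts, pole = "first"),
    true_profile = function(s) pmin(background + archetype_intensity(archetype, s), 1),
    artifact_regions = artifact_regions,
    background = background,
    stage = archetype$stage,
    seed = as.integer(seed)
  ), class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  cat("image_scene:", nrow(x$image), "x", ncol(x$image), "pixels, stage",
      x$stage, ",", length(x$artifact_regions), "artifact region(s)\n")
  invisible(x)
}
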