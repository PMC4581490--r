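#' Decompose the cell layer into quadrilateral segments
#'
#' Segment `k` is the quadrilateral `(inner_k, inner_{k+1}, outer_{k+1},
#' outer_k)`. Its arc-length position is the normalized cumulative arc length
#' of the midline (the pointwise average of the inner and outer polylines) at
#' the segment midpoint, so positions lie strictly inside (0, 1) and run from
#' the animal/oral pole (0) to the vegetal/aboral pole (1).
#'
#' If the morphology does not already have `n_segments + 1` point pairs it is
#' resampled by arc-length-uniform interpolation of each polyline.
#'
#' @param morphology a [boundary_morphology()].
#' @param n_segments number of segments (default 100).
#' @return A list of class `cell_layer_segments`; each element has `quad`
#'   (4 x 2 vertex matrix), `position` (midline arc-length midpoint in (0,1))
#'   and `area` (shoelace area). Degenerate (zero-area) quads are an error
#'   naming the segment index.
#' @export
segment_cell_layer <- function(morphology, n_segments = 100L) {
  stopifnot(inherits(morphology, "boundary_morphology"), n_segments >= 1)
  m <- .orient_pole_first(morphology)
  if (n_point_pairs(m) != n_segments + 1L) {
    m <- resample_morphology(m, n_segments + 1L)
  }
  midline <- (m$inner + m$outer) / 2
  s <- .cum_arclength(midline)
  total <- s[length(s)]
  if (total <= 0) stop("midline has zero length")
  positions <- (s[-length(s)] + s[-1]) / 2 / total
  segs <- vector("list", n_segments)
  for (k in seq_len(n_segments)) {
    quad <- rbind(m$inner[k, ], m$inner[k + 1L, ],
                  m$outer[k + 1L, ], m$outer[k, ])
    area <- .shoelace_area(quad)
    if (area <= .Machine$double.eps * 100) {
      stop("degenerate (zero-area) quad at segment ", k)
    }
    segs[[k]] <- list(quad = quad, position = positions[k], area = area)
  }
  structure(segs, class = "cell_layer_segments")
}

#' Raw (unstandardized) expression profile
#'
#' @param positions strictly increasing arc-length midpoints in \[0,1\].
#' @param intensities mean pixel intensity per segment.
#' @param pixel_counts pixels averaged per segment (>= 1).
#' @return An object of class `raw_profile`.
#' @export
raw_profile <- function(positions, intensities, pixel_counts = rep(1L, length(positions))) {
  stopifnot(length(positions) == length(intensities),
            length(positions) == length(pixel_counts))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(pixel_counts < 1)) stop("pixel_counts must be >= 1")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 pixel_counts = as.integer(pixel_counts)),
            class = "raw_profile")
}

#' @export
print.raw_profile <- function(x, ...) {
  cat("raw_profile:", length(x$positions), "segments, positions",
      sprintf("%.3f", min(x$positions)), "-", sprintf("%.3f", max(x$positions)),
      "\n")
  invisible(x)
}

#' Mean pixel intensity per cell-layer segment
#'
#' A pixel belongs to a segment when its center falls inside the segment's
#' quadrilateral (even-odd rule). Pixels on a shared edge are claimed by the
#' first segment that contains them, so each pixel is counted at most once.
#' Segments containing no pixel centers are dropped with a warning.
#'
#' Pixel centers are at `(col - 0.5, row - 0.5)` in the morphology's
#' coordinate system (x right, y down, origin at the top-left image corner).
#'
#' @param image numeric matrix of intensities (rows = y, cols = x).
#' @param segments a `cell_layer_segments` from [segment_cell_layer()].
#' @return A [raw_profile()] with per-segment means and pixel counts.
#' @export
segment_mean_intensity <- function(image, segments) {
  stopifnot(is.matrix(image), inherits(segments, "cell_layer_segments"))
  nr <- nrow(image); nc <- ncol(image)
  claimed <- matrix(FALSE, nr, nc)
  pos <- numeric(0); mu <- numeric(0); cnt <- integer(0)
  dropped <- integer(0)
  for (k in seq_along(segments)) {
    quad <- segments[[k]]$quad
    # candidate pixels from the quad's bounding box
    c0 <- max(1L, floor(min(quad[, 1]) + 0.5)); c1 <- min(nc, ceiling(max(quad[, 1]) + 0.5))
    r0 <- max(1L, floor(min(quad[, 2]) + 0.5)); r1 <- min(nr, ceiling(max(quad[, 2]) + 0.5))
    if (c0 > c1 || r0 > r1) { dropped <- c(dropped, k); next }
    cols <- c0:c1; rows <- r0:r1
    grid <- expand.grid(row = rows, col = cols)
    px <- grid$col - 0.5; py <- grid$row - 0.5
    inside <- pracma::inpolygon(px, py, quad[, 1], quad[, 2], boundary = TRUE)
    if (!any(inside)) { dropped <- c(dropped, k); next }
    ij <- cbind(grid$row[inside], grid$col[inside])
    free <- !claimed[ij]
    if (!any(free)) { dropped <- c(dropped, k); next }
    ij <- ij[free, , drop = FALSE]
    claimed[ij] <- TRUE
    pos <- c(pos, segments[[k]]$position)
    mu <- c(mu, mean(image[ij]))
    cnt <- c(cnt, nrow(ij))
  }
  if (length(pos) == 0) stop("no segment contains any pixel center")
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped), " segment(s) with no pixels: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  raw_profile(pos, mu, cnt)
}

#' Edit mask for artifact correction
#'
#' @param intervals two-column matrix (or data frame) of `[start, end]`
#'   arc-length intervals in \[0,1\] to be replaced.
#' @return Object of class `edit_mask` (a normalized, merged interval matrix).
#' @export
edit_mask <- function(intervals) {
  m <- as.matrix(intervals)
  if (length(m) == 0) {
    return(structure(matrix(numeric(0), ncol = 2), class = "edit_mask"))
  }
  stopifnot(ncol(m) == 2)
  if (any(m < 0 | m > 1)) stop("mask intervals must lie within [0, 1]")
  if (any(m[, 1] > m[, 2])) stop("mask intervals must have start <= end")
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge overlaps
  out <- m[1, , drop = FALSE]
  for (k in seq_len(nrow(m))[-1]) {
    if (m[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[k, 2])
    } else {
      out <- rbind(out, m[k, ])
    }
  }
  structure(unname(out), class = "edit_mask")
}

#' Replace masked profile stretches by interpolation
#'
#' Intensities at positions covered by the mask are replaced by linear
#' interpolation between the nearest unmasked neighbors; masked runs touching
#' either end of the profile take the nearest unmasked value. This is the
#' programmatic analogue of manually editing an intensity plot to remove
#' staining artifacts, annotations and segmentation imperfections.
#'
#' @param raw a [raw_profile()].
#' @param mask an [edit_mask()] (or an interval matrix coerced to one).
#' @return A [raw_profile()] with masked intensities replaced.
#' @export
edit_profile <- function(raw, mask) {
  stopifnot(inherits(raw, "raw_profile"))
  if (!inherits(mask, "edit_mask")) mask <- edit_mask(mask)
  if (nrow(mask) == 0) return(raw)
  masked <- rep(FALSE, length(raw$positions))
  for (k in seq_len(nrow(mask))) {
    masked <- masked | (raw$positions >= mask[k, 1] & raw$positions <= mask[k, 2])
  }
  if (all(masked)) stop("mask covers every profile point")
  if (!any(masked)) return(raw)
  fixed <- stats::approx(raw$positions[!masked], raw$intensities[!masked],
                         xout = raw$positions[masked], rule = 2, ties = "ordered")$y
  out <- raw$intensities
  out[masked] <- fixed
  raw_profile(raw$positions, out, raw$pixel_counts)
}

#' Standardized 100-point expression profile
#'
#' @param values numeric vector of exactly 100 nonnegative intensities with
#'   maximum 1 (within 1e-9).
#' @param gene,stage,sample_id labels; `stage` is canonicalized against the
#'   seven-stage vocabulary (or may be `NA`).
#' @return Object of class `standardized_profile`.
#' @export
standardized_profile <- function(values, gene = NA_character_,
                                 stage = NA_character_,
                                 sample_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) != 100L) stop("a standardized profile has exactly 100 values")
  if (any(values < 0)) stop("standardized profile values must be nonnegative")
  if (abs(max(values) - 1) > 1e-9) stop("standardized profile maximum must be 1")
  if (!is.na(stage)) stage <- canonical_stage(stage)
  structure(list(values = values, gene = gene, stage = stage,
                 sample_id = sample_id),
            class = "standardized_profile")
}

#' @export
print.standardized_profile <- function(x, ...) {
  cat("standardized_profile:", x$gene, "/", x$stage, "/", x$sample_id,
      " (100 points, max 1)\n")
  invisible(x)
}

#' Standardize a raw profile to 100 unit-scaled points
#'
#' The raw profile is linearly interpolated at one hundred equidistant
#' arc-length positions spanning `[0, 1]` inclusive (step 1/99; positions
#' outside the raw range take the nearest raw value) and divided by its
#' maximum, so the output has length exactly 100 and maximum exactly 1.
#' All-zero (or non-positive-maximum) profiles are rejected: they carry no
#' usable expression signal.
#'
#' @param raw a [raw_profile()] with at least 2 points.
#' @param gene,stage,sample_id labels attached to the result.
#' @return A [standardized_profile()].
#' @export
standardize_profile <- function(raw, gene = NA_character_,
                                stage = NA_character_,
                                sample_id = NA_character_) {
  stopifnot(inherits(raw, "raw_profile"))
  if (length(raw$positions) < 2) stop("need at least 2 profile points")
  v <- stats::approx(raw$positions, raw$intensities,
                     xout = seq(0, 1, length.out = 100L),
                     rule = 2, ties = "ordered")$y
  mx <- max(v)
  if (mx <= 0) stop("profile rejected: maximum intensity is not positive")
  standardized_profile(v / mx, gene = gene, stage = stage, sample_id = sample_id)
}

#' Extract a standardized profile from an image
#'
#' Convenience wrapper chaining [segment_cell_layer()],
#' [segment_mean_intensity()], [edit_profile()] and [standardize_profile()].
#'
#' @param image numeric intensity matrix (already single-channel; see
#'   [read_image()] for channel and inversion policy).
#' @param morphology a [boundary_morphology()].
#' @param n_segments number of cell-layer segments (default 100).
#' @param mask optional [edit_mask()] of artifact intervals.
#' @param gene,stage,sample_id labels for the result.
#' @return A [standardized_profile()].
#' @export
extract_profile <- function(image, morphology, n_segments = 100L, mask = NULL,
                            gene = NA_character_, stage = NA_character_,
                            sample_id = NA_character_) {
  segs <- segment_cell_layer(morphology, n_segments)
  raw <- segment_mean_intensity(image, segs)
  if (!is.null(mask)) raw <- edit_profile(raw, mask)
  standardize_profile(raw, gene = gene, stage = stage, sample_id = sample_id)
}
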