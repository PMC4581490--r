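#' Boundary morphology of the embryo cell layer
#'
#' A "digital morphology": two ordered, index-paired polylines tracing the
#' inner and outer boundary of the embryo's cell layer along a half-meridian.
#' Point pair `k` of the inner polyline corresponds to point pair `k` of the
#' outer polyline; consecutive pairs bound one quadrilateral segment of the
#' cell layer.
#'
#' @param inner,outer numeric matrices with two columns (x, y) and the same
#'   number (>= 3) of rows.
#' @param pole which end of the polylines is the animal/oral pole
#'   (arc-length position 0): `"first"` (default) or `"last"`.
#' @return An object of class `boundary_morphology`.
#' @export
boundary_morphology <- function(inner, outer, pole = c("first", "last")) {
  pole <- match.arg(pole)
  inner <- as.matrix(inner); outer <- as.matrix(outer)
  storage.mode(inner) <- "double"; storage.mode(outer) <- "double"
  if (ncol(inner) != 2 || ncol(outer) != 2) {
    stop("inner and outer must be two-column (x, y) matrices")
  }
  if (nrow(inner) != nrow(outer)) {
    stop("inner and outer polylines must have the same number of points")
  }
  if (nrow(inner) < 3) stop("a morphology needs at least 3 point pairs")
  structure(list(inner = inner, outer = outer, pole = pole),
            class = "boundary_morphology")
}

#' @export
print.boundary_morphology <- function(x, ...) {
  cat("boundary_morphology:", nrow(x$inner), "point pairs,",
      nrow(x$inner) - 1L, "segments; pole at", x$pole, "end\n")
  invisible(x)
}

#' Number of point pairs in a morphology
#' @param morphology a `boundary_morphology`.
#' @return integer count of index-paired points.
#' @export
n_point_pairs <- function(morphology) nrow(morphology$inner)

# cumulative arc length of an n x 2 polyline; length n, starts at 0
.cum_arclength <- function(points) {
  d <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(d))
}

# resample a polyline at n points uniform in its own cumulative arc length
.resample_polyline <- function(points, n) {
  s <- .cum_arclength(points)
  total <- s[length(s)]
  if (total <= 0) stop("polyline has zero length")
  target <- seq(0, total, length.out = n)
  x <- stats::approx(s, points[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, points[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

#' Resample a morphology to a given number of point pairs
#'
#' Each polyline is resampled independently at points uniform in its own
#' cumulative arc length; the pole orientation is preserved.
#'
#' @param morphology a `boundary_morphology`.
#' @param n_pairs number of point pairs in the result (segments + 1).
#' @return A `boundary_morphology` with `n_pairs` point pairs.
#' @export
resample_morphology <- function(morphology, n_pairs) {
  stopifnot(inherits(morphology, "boundary_morphology"), n_pairs >= 3)
  boundary_morphology(
    .resample_polyline(morphology$inner, n_pairs),
    .resample_polyline(morphology$outer, n_pairs),
    pole = morphology$pole
  )
}

# orient so that the animal/oral pole is the first point pair
.orient_pole_first <- function(morphology) {
  if (morphology$pole == "last") {
    boundary_morphology(morphology$inner[rev(seq_len(nrow(morphology$inner))), ],
                        morphology$outer[rev(seq_len(nrow(morphology$outer))), ],
                        pole = "first")
  } else {
    morphology
  }
}

# signed shoelace area of a polygon given as an n x 2 matrix (open ring)
.shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Write a morphology to CSV
#'
#' Columns: `point_index`, `inner_x`, `inner_y`, `outer_x`, `outer_y`.
#'
#' @param morphology a `boundary_morphology`.
#' @param path output CSV path.
#' @export
write_morphology_csv <- function(morphology, path) {
  df <- data.frame(
    point_index = seq_len(nrow(morphology$inner)),
    inner_x = morphology$inner[, 1], inner_y = morphology$inner[, 2],
    outer_x = morphology$outer[, 1], outer_y = morphology$outer[, 2]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a morphology from CSV
#'
#' @param path CSV path with the [write_morphology_csv()] schema.
#' @param pole which end is the animal/oral pole.
#' @return A `boundary_morphology`.
#' @export
read_morphology_csv <- function(path, pole = "first") {
  df <- utils::read.csv(path)
  need <- c("point_index", "inner_x", "inner_y", "outer_x", "outer_y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("morphology CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- df[order(df$point_index), ]
  boundary_morphology(cbind(df$inner_x, df$inner_y),
                      cbind(df$outer_x, df$outer_y), pole = pole)
}
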