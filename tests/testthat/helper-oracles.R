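# Independent oracles and fixture builders used across the suite.

# --- brute-force UPGMA oracle ------------------------------------------------
# Recomputes every cluster-pair mean distance from the original leaf matrix
# at each step (O(n^3)); clusters indexed by smallest member leaf, ties
# broken by smallest (index_a, index_b). Returns merge leaf-sets and heights.
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  sets <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    key <- vapply(clusters, min, numeric(1))
    ord <- order(key)
    clusters <- clusters[ord]
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || dd < best$d) best <- list(d = dd, i = i, j = j)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    sets[[length(sets) + 1]] <- merged
    heights <- c(heights, best$d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(sets = sets, heights = heights)
}

# leaf sets per merge step of an upgma_dendrogram, sorted
dendrogram_leaf_sets <- function(dend) {
  leaves <- vector("list", nrow(dend$merge))
  for (s in seq_len(nrow(dend$merge))) {
    lv <- function(x) if (x < 0) -x else leaves[[x]]
    leaves[[s]] <- sort(c(lv(dend$merge[s, 1]), lv(dend$merge[s, 2])))
  }
  leaves
}

# --- exhaustive Fisher oracle ------------------------------------------------
# Enumerates all tables with the observed margins; probabilities from
# log-binomial coefficients (independent of dhyper); two-tail sum of
# probabilities <= observed (relative tie slack).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  p <- exp(logp)
  p_obs <- p[match(a, support)]
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# --- geometry oracle ---------------------------------------------------------
# point-in-convex-polygon via cross-product signs (on-edge counts as inside);
# independent of pracma::inpolygon
in_convex_quad <- function(px, py, quad) {
  n <- nrow(quad)
  sgn <- rep(0, length(px))
  ok <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    x1 <- quad[k, 1]; y1 <- quad[k, 2]
    x2 <- quad[k %% n + 1, 1]; y2 <- quad[k %% n + 1, 2]
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    ok <- ok & (sgn == 0 | sign(cr) == 0 | sign(cr) == sgn)
    sgn <- ifelse(sgn == 0 & sign(cr) != 0, sign(cr), sgn)
  }
  ok
}

# brute-force per-segment pixel means replicating the first-claim rule
segment_means_oracle <- function(image, segments) {
  claimed <- matrix(FALSE, nrow(image), ncol(image))
  out <- data.frame(position = numeric(0), mean = numeric(0), count = integer(0))
  for (k in seq_along(segments)) {
    quad <- segments[[k]]$quad
    hits_r <- integer(0); hits_c <- integer(0)
    for (r in seq_len(nrow(image))) {
      for (cc in seq_len(ncol(image))) {
        x <- cc - 0.5; y <- r - 0.5
        if (x < min(quad[, 1]) - 1 || x > max(quad[, 1]) + 1 ||
            y < min(quad[, 2]) - 1 || y > max(quad[, 2]) + 1) next
        if (!claimed[r, cc] && in_convex_quad(x, y, quad)) {
          hits_r <- c(hits_r, r); hits_c <- c(hits_c, cc)
        }
      }
    }
    if (length(hits_r) == 0) next
    claimed[cbind(hits_r, hits_c)] <- TRUE
    out <- rbind(out, data.frame(position = segments[[k]]$position,
                                 mean = mean(image[cbind(hits_r, hits_c)]),
                                 count = length(hits_r)))
  }
  out
}

# --- shared fixtures ---------------------------------------------------------
# concentric half-circle morphology (r_in, r_out around a center), points at
# angles uniform in t so midline arc length is uniform too
half_circle_morphology <- function(r_in = 10, r_out = 20, n_pairs = 5,
                                   center = c(30, 30)) {
  t <- seq(0, pi, length.out = n_pairs)
  boundary_morphology(
    cbind(center[1] + r_in * sin(t), center[2] - r_in * cos(t)),
    cbind(center[1] + r_out * sin(t), center[2] - r_out * cos(t))
  )
}

# well-separated single-window archetypes for planted-cluster tests
planted_archetypes <- function(stage, k) {
  wins <- list(c(0, 0.22), c(0.26, 0.48), c(0.52, 0.74), c(0.78, 1))
  doms <- list("Cd", "Cr", "Er", "VeHe")
  lapply(seq_len(k), function(j) {
    archetype_spec("blastula", data.frame(name = doms[[j]],
                                          start = wins[[j]][1],
                                          end = wins[[j]][2],
                                          amplitude = 0.8))
  })
}

# reference period summaries as printed in the survey's summary tables,
# frozen cell-for-cell (counts and integer percentages)
reference_period_summaries <- function() {
  p <- paste(stage_names()[1:6], stage_names()[2:7], sep = "-")
  m3 <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE,
                dimnames = list(p, c("minor", "major", "vanished")))
    m
  }
  m5 <- function(...) {
    matrix(c(...), ncol = 5, byrow = TRUE,
           dimnames = list(p, c("minor", "major", "appeared", "vanished", "none")))
  }
  list(
    R1 = list(counts = m3(22, 2, 1,  9, 4, 0,  8, 2, 0,  5, 2, 0, 11, 2, 0,  9, 1, 0),
              pct    = m3(88, 8, 4, 69, 31, 0, 80, 20, 0, 71, 29, 0, 85, 15, 0, 90, 10, 0)),
    R2 = list(counts = m3(9, 1, 0,  9, 3, 0, 13, 3, 0,  8, 3, 0,  7, 1, 1,  4, 0, 0),
              pct    = m3(90, 10, 0, 75, 25, 0, 81, 19, 0, 73, 27, 0, 78, 11, 11, 100, 0, 0)),
    R3 = list(counts = m3(0, 0, 0,  4, 2, 0,  5, 1, 0,  6, 1, 0,  5, 1, 0,  2, 1, 0),
              pct    = m3(0, 0, 0, 67, 33, 0, 83, 17, 0, 86, 14, 0, 83, 17, 0, 67, 33, 0)),
    all = list(counts = m5(31, 5, 3, 1, 1, 23, 11, 8, 0, 1, 28, 11, 15, 0, 0,
                           22, 12, 15, 0, 0, 28, 8, 9, 1, 0, 18, 5, 1, 0, 0),
               pct    = m5(76, 12, 7, 2, 2, 53, 26, 19, 0, 2, 52, 20, 28, 0, 0,
                           45, 24, 31, 0, 0, 61, 17, 20, 2, 0, 75, 21, 4, 0, 0))
  )
}
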