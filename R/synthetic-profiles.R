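#' Generate a labeled set of standardized profiles with planted clusters
#'
#' Each archetype's window function is sampled at 100 equidistant arc
#' positions; every replicate is perturbed by per-window amplitude jitter and
#' additive Gaussian noise (truncated at zero), then max-scaled to 1. The
#' generating archetype of every profile is retained as ground truth, so
#' downstream clustering can be scored against the planted labels.
#'
#' @param archetypes list of [archetype_spec()] objects (planted clusters).
#' @param n_per_archetype replicates per archetype (>= 1).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param amplitude_jitter relative jitter of window amplitudes: each window
#'   amplitude is multiplied by `1 + amplitude_jitter * z`, `z ~ N(0, 1)`.
#' @param seed integer seed (same seed and parameters give identical output).
#' @return Object of class `profile_set`: list with `profiles` (list of
#'   [standardized_profile()]) and `truth` (data frame `sample_id`,
#'   `archetype`, `stage`).
#' @export
generate_profile_set <- function(archetypes, n_per_archetype, noise_sd = 0.05,
                                 amplitude_jitter = 0, seed = 1L) {
  stopifnot(is.list(archetypes), length(archetypes) >= 1,
            n_per_archetype >= 1, noise_sd >= 0, amplitude_jitter >= 0)
  for (a in archetypes) stopifnot(inherits(a, "archetype_spec"))
  pos <- seq(0, 1, length.out = 100L)
  withr::with_seed(as.integer(seed), {
    profiles <- list()
    truth <- list()
    idx <- 0L
    for (j in seq_along(archetypes)) {
      arch <- archetypes[[j]]
      arch_name <- paste0("A", j)
      base <- archetype_intensity(arch, pos)
      if (max(base) <= 0 && noise_sd == 0) {
        stop("archetype ", j, " is all-zero with zero noise: cannot scale")
      }
      for (i in seq_len(n_per_archetype)) {
        idx <- idx + 1L
        arch_i <- arch
        if (amplitude_jitter > 0) {
          arch_i$windows$amplitude <- arch_i$windows$amplitude *
            (1 + amplitude_jitter * stats::rnorm(nrow(arch_i$windows)))
        }
        v <- archetype_intensity(arch_i, pos)
        if (noise_sd > 0) v <- pmax(v + stats::rnorm(100L, 0, noise_sd), 0)
        mx <- max(v)
        if (mx <= 0) stop("generated profile is all-zero: cannot scale")
        sid <- sprintf("%s_r%02d", arch_name, i)
        profiles[[idx]] <- standardized_profile(v / mx,
                                                gene = sid,
                                                stage = arch$stage,
                                                sample_id = sid)
        truth[[idx]] <- data.frame(sample_id = sid, archetype = arch_name,
                                   stage = arch$stage)
      }
    }
    structure(list(profiles = profiles, truth = do.call(rbind, truth)),
              class = "profile_set")
  })
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set:", length(x$profiles), "profiles,",
      length(unique(x$truth$archetype)), "archetype(s)\n")
  invisible(x)
}

#' Stack standardized profiles into a samples x 100 matrix
#'
#' @param profiles a `profile_set`, a list of [standardized_profile()], or a
#'   numeric matrix with 100 columns (returned unchanged apart from row
#'   names).
#' @return Numeric matrix, one row per sample, 100 columns, row names from
#'   sample ids.
#' @export
profile_matrix <- function(profiles) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  if (is.matrix(profiles)) {
    if (ncol(profiles) != 100L) stop("profile matrix must have 100 columns")
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- sprintf("s%03d", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  stopifnot(is.list(profiles), length(profiles) >= 1)
  m <- t(vapply(profiles, function(p) {
    stopifnot(inherits(p, "standardized_profile"))
    p$values
  }, numeric(100L)))
  rownames(m) <- vapply(profiles, function(p) p$sample_id, character(1))
  m
}
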