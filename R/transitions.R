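#' Transition categories
#'
#' Region-filtered count tables use three categories
#' (minor:major:vanished); the all-regions table uses five
#' (minor:major:appeared:vanished:none).
#'
#' @param filter `"all"` or one of `"R1"`, `"R2"`, `"R3"`.
#' @return Character vector of category names in tuple order.
#' @export
transition_categories <- function(filter = "all") {
  if (identical(filter, "all")) {
    c("minor", "major", "appeared", "vanished", "none")
  } else {
    c("minor", "major", "vanished")
  }
}

#' Consecutive available stage pairs for one gene
#'
#' Pairs are consecutive in the gene's own availability order: if images
#' exist for the blastula, mid gastrula and planula only, the pairs are
#' (blastula, mid gastrula) and (mid gastrula, planula), even though those
#' stages are not adjacent in the global order.
#'
#' @param stages character vector of the gene's available stages (>= 2).
#' @return Data frame with columns `initial` and `final`.
#' @export
consecutive_available_pairs <- function(stages) {
  stages <- canonical_stage(stages)
  idx <- stage_index(stages)
  if (anyDuplicated(idx)) stop("duplicate stages in availability list")
  stages <- stages[order(idx)]
  if (length(stages) < 2) stop("need at least 2 available stages")
  data.frame(initial = stages[-length(stages)], final = stages[-1])
}

#' Classify an expression transition against the major regions
#'
#' Between two consecutive available stages, a gene's expression has:
#' stayed absent (`none`, both region sets empty), `appeared` (empty to
#' nonempty), `vanished` (nonempty to empty), remained within the same major
#' region(s) (`minor`, equal nonempty sets), or shifted across major regions
#' (`major`, any other change between nonempty sets). Region-set equality is
#' the strictest reading of "remained within the same major region" and is
#' the one consistent with the reference count tables.
#'
#' @param regions_i,regions_f character vectors over `{"R1","R2","R3"}`.
#' @return One of `"none"`, `"appeared"`, `"vanished"`, `"minor"`, `"major"`.
#' @export
#' @examples
#' classify_transition("R1", "R1")            # minor
#' classify_transition("R1", c("R1", "R2"))   # major
classify_transition <- function(regions_i, regions_f) {
  ok <- function(x) all(x %in% c("R1", "R2", "R3"))
  if (!ok(regions_i) || !ok(regions_f)) stop("regions must be among R1, R2, R3")
  ei <- length(regions_i) == 0; ef <- length(regions_f) == 0
  if (ei && ef) return("none")
  if (ei) return("appeared")
  if (ef) return("vanished")
  if (setequal(regions_i, regions_f)) "minor" else "major"
}

#' Pairwise transition count matrix
#'
#' Tallies transition categories for every (initial stage, final stage)
#' combination over all genes' consecutive available stage pairs. With a
#' region filter, only pairs whose initial region set is exactly that one
#' region are counted (three categories); with `filter = "all"` every pair
#' is counted (five categories). A stage whose nonempty domain set maps
#' entirely to unmapped regions has unknown region membership: such pairs
#' are skipped with a warning (an empty domain set, by contrast, means "not
#' expressed").
#'
#' @param table a [domain_table()] (or data frame coercible to one).
#' @param region_map named map domain -> region, see [default_region_map()].
#' @param filter `"all"` (default) or `"R1"`, `"R2"`, `"R3"`.
#' @return Object of class `pairwise_counts`: a 7 x 7 x categories integer
#'   array (initial stage x final stage x category) with the filter stored
#'   as an attribute. Only cells with final index > initial index can be
#'   populated.
#' @export
build_pairwise_matrix <- function(table, region_map = default_region_map(),
                                  filter = c("all", "R1", "R2", "R3")) {
  filter <- match.arg(filter)
  if (!inherits(table, "domain_table")) table <- domain_table(table)
  cats <- transition_categories(filter)
  counts <- array(0L, dim = c(7L, 7L, length(cats)),
                  dimnames = list(stage_names(), stage_names(), cats))
  skipped <- 0L
  for (gene in unique(table$gene)) {
    rows <- table[table$gene == gene, ]
    if (nrow(rows) < 2) next
    doms <- lapply(rows$domains, .split_domains)
    reg <- lapply(doms, map_domains_to_regions, region_map = region_map)
    pairs <- consecutive_available_pairs(rows$stage)
    for (k in seq_len(nrow(pairs))) {
      i <- match(pairs$initial[k], rows$stage)
      f <- match(pairs$final[k], rows$stage)
      unknown_i <- length(reg[[i]]$regions) == 0 && length(reg[[i]]$unmapped) > 0
      unknown_f <- length(reg[[f]]$regions) == 0 && length(reg[[f]]$unmapped) > 0
      if (unknown_i || unknown_f) { skipped <- skipped + 1L; next }
      if (filter != "all" && !identical(reg[[i]]$regions, filter)) next
      cat_k <- classify_transition(reg[[i]]$regions, reg[[f]]$regions)
      if (!cat_k %in% cats) next  # cannot happen for region filters, by construction
      counts[pairs$initial[k], pairs$final[k], cat_k] <-
        counts[pairs$initial[k], pairs$final[k], cat_k] + 1L
    }
  }
  if (skipped > 0) {
    warning(skipped, " stage pair(s) skipped: domains map only to unmapped regions")
  }
  structure(counts, filter = filter, class = "pairwise_counts")
}

#' Construct a pairwise count matrix from pre-tallied counts
#'
#' @param df data frame with columns `initial_stage`, `final_stage` and one
#'   column per category of the filter's tuple.
#' @param filter `"all"` or `"R1"`, `"R2"`, `"R3"`.
#' @return A `pairwise_counts` array.
#' @export
pairwise_counts <- function(df, filter = "all") {
  df <- as.data.frame(df)
  cats <- transition_categories(filter)
  need <- c("initial_stage", "final_stage", cats)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pairwise counts need column(s): ", paste(miss, collapse = ", "))
  }
  counts <- array(0L, dim = c(7L, 7L, length(cats)),
                  dimnames = list(stage_names(), stage_names(), cats))
  ii <- stage_index(df$initial_stage); ff <- stage_index(df$final_stage)
  if (any(ff <= ii)) stop("final stage must come after initial stage")
  for (k in seq_len(nrow(df))) {
    for (ct in cats) {
      v <- df[[ct]][k]
      if (is.na(v) || v < 0 || v != round(v)) {
        stop("counts must be nonnegative integers (row ", k, ", ", ct, ")")
      }
      counts[ii[k], ff[k], ct] <- counts[ii[k], ff[k], ct] + as.integer(v)
    }
  }
  structure(counts, filter = filter, class = "pairwise_counts")
}

#' @export
print.pairwise_counts <- function(x, ...) {
  cats <- dimnames(x)[[3]]
  cat("pairwise_counts (filter ", attr(x, "filter"), "), categories ",
      paste(cats, collapse = ":"), ", total ", sum(x), "\n", sep = "")
  invisible(x)
}

#' Integer percentage tuple
#'
#' Each entry is `round(count / total * 100)` with ties rounded away from
#' zero; a zero total yields all zeros.
#'
#' @param counts nonnegative integer vector.
#' @return Integer vector of the same length summing to about 100.
#' @export
#' @examples
#' percent_tuple(c(9, 4, 0))  # 69 31 0
percent_tuple <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) return(rep(0L, length(counts)))
  x <- counts / total * 100
  as.integer(floor(x + 0.5))  # ties away from zero (all values nonnegative)
}

#' Aggregate pairwise counts into two-stage period sums
#'
#' A transition observed between initial stage `i` and final stage `f`
#' could have happened during any consecutive-stage period `(s, s+1)` with
#' `index(i) <= s < index(f)`, so its counts are credited to every such
#' period. Per-period sums are also expressed as integer percentages
#' ([percent_tuple()]).
#'
#' @param matrix a `pairwise_counts` array.
#' @return Object of class `period_summary`: list with `counts` and
#'   `percentages`, both 6 x categories matrices with period-name rows,
#'   plus the filter attribute.
#' @export
aggregate_periods <- function(matrix) {
  stopifnot(inherits(matrix, "pairwise_counts"))
  cats <- dimnames(matrix)[[3]]
  periods <- paste(stage_names()[1:6], stage_names()[2:7], sep = "-")
  counts <- base::matrix(0L, 6L, length(cats),
                         dimnames = list(periods, cats))
  for (i in 1:6) for (f in (i + 1):7) {
    cell <- matrix[i, f, ]
    if (sum(cell) == 0) next
    for (s in i:(f - 1)) counts[s, ] <- counts[s, ] + cell
  }
  pct <- t(apply(counts, 1, percent_tuple))
  dimnames(pct) <- dimnames(counts)
  structure(list(counts = counts, percentages = pct),
            filter = attr(matrix, "filter"), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat("period_summary (filter ", attr(x, "filter"), ")\n", sep = "")
  show <- data.frame(
    counts = apply(x$counts, 1, paste, collapse = ":"),
    percentages = apply(x$percentages, 1, paste, collapse = ":")
  )
  print(show)
  invisible(x)
}

#' Summed percentages of selected categories per period
#'
#' For each two-stage period, adds the integer percentages of the selected
#' categories, e.g. the possible major change plus first appearance rate.
#'
#' @param summary a [aggregate_periods()] result.
#' @param categories subset of the summary's category names.
#' @return Named integer vector, one value per period.
#' @export
period_change_rate <- function(summary, categories) {
  stopifnot(inherits(summary, "period_summary"))
  if (length(categories) == 0) {
    return(stats::setNames(rep(0L, nrow(summary$percentages)),
                           rownames(summary$percentages)))
  }
  bad <- setdiff(categories, colnames(summary$percentages))
  if (length(bad) > 0) {
    stop("unknown category(ies): ", paste(bad, collapse = ", "))
  }
  out <- as.integer(rowSums(summary$percentages[, categories, drop = FALSE]))
  stats::setNames(out, rownames(summary$percentages))
}

#' Two-tailed Fisher's exact test for a 2 x 2 table
#'
#' The two-tail p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (up to a small relative slack for floating-point
#' ties). Any zero margin leaves a single attainable table and p = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_two_tail(3, 1, 1, 3)  # 34/70
fisher_exact_two_tail <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers")
  }
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- dens[match(a, support)]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
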