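#' Transition kernel for synthetic expression-domain evolution
#'
#' Per-period probabilities of the five transition categories. Because
#' category feasibility depends on the current state, the kernel is applied
#' conditionally: from a nonempty region set the probabilities of
#' minor/major/vanished are renormalized; from an empty set those of
#' appeared/none are. A gene's state at its first available stage is empty
#' with probability `start_empty` (default: the appeared + none mass), else
#' a single uniformly chosen region.
#'
#' @param minor,major,appeared,vanished,none category probabilities; must sum
#'   to 1.
#' @param availability probability that a gene has an image at a stage;
#'   scalar or one value per stage (all in \[0,1\]).
#' @param start_empty probability the first available state is empty.
#' @return Object of class `transition_kernel`.
#' @export
transition_kernel <- function(minor = 0.7, major = 0.3, appeared = 0,
                              vanished = 0, none = 0, availability = 1,
                              start_empty = appeared + none) {
  p <- c(minor = minor, major = major, appeared = appeared,
         vanished = vanished, none = none)
  if (any(p < 0)) stop("kernel probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("kernel probabilities must sum to 1")
  if (any(availability < 0 | availability > 1)) {
    stop("availability must lie in [0, 1]")
  }
  if (start_empty < 0 || start_empty > 1) stop("start_empty must lie in [0, 1]")
  structure(list(p = p, availability = availability, start_empty = start_empty),
            class = "transition_kernel")
}

#' Representative expression domains per major region and stage
#'
#' For each stage, the domain names the synthetic generator may use to
#' realize expression in each major region. All names are legal for their
#' stage ([domain_vocabulary()]) and map to their region under
#' [default_region_map()].
#'
#' @return Nested list: `stage -> region -> character vector of domains`.
#' @export
region_representatives <- function() {
  list(
    "blastula"       = list(R1 = "Cd", R2 = c("Cr", "Er"), R3 = c("VeHe", "Ve")),
    "early gastrula" = list(R1 = "pEn", R2 = "bEc", R3 = c("VeHe", "Ve")),
    "mid gastrula"   = list(R1 = "En", R2 = "OrEc", R3 = c("VeHe", "Ve")),
    "late gastrula"  = list(R1 = "En", R2 = c("OrEc", "PhEc"), R3 = c("AbEc", "Ve")),
    "early planula"  = list(R1 = c("En", "PhEn"), R2 = c("OrEc", "PhEc"), R3 = "AbEc"),
    "planula"        = list(R1 = c("En", "PhEn"), R2 = c("OrEc", "M"), R3 = c("AbEc", "At")),
    "late planula"   = list(R1 = c("En", "PhEn"), R2 = c("OrEc", "M"), R3 = c("AbEc", "At"))
  )
}

#' Expression-domain table
#'
#' Validates and classes a long-format expression-domain table: one row per
#' gene and available stage, with the domain names observed at that stage
#' (semicolon-separated in the `domains` column; empty string = image shows
#' no staining) and a flag for noncylindrical patterns (carried through the
#' table but excluded from 1D profile quantification).
#'
#' @param df data frame with columns `gene`, `stage`, `domains`,
#'   and optionally `noncylindrical` (0/1; default 0).
#' @param check_vocabulary validate domain names against
#'   [domain_vocabulary()] (default `TRUE`).
#' @return The data frame, stages canonicalized and rows ordered by gene and
#'   stage index, with class `domain_table`.
#' @export
domain_table <- function(df, check_vocabulary = TRUE) {
  df <- as.data.frame(df)
  need <- c("gene", "stage", "domains")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("domain table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"noncylindrical" %in% names(df)) df$noncylindrical <- rep(0L, nrow(df))
  df$stage <- canonical_stage(df$stage)
  df$domains[is.na(df$domains)] <- ""
  df <- df[order(df$gene, stage_index(df$stage)), ]
  dup <- duplicated(df[, c("gene", "stage")])
  if (any(dup)) {
    stop("duplicate (gene, stage) rows: ",
         paste(utils::head(paste(df$gene[dup], df$stage[dup]), 5), collapse = "; "))
  }
  if (check_vocabulary) {
    vocab <- domain_vocabulary()
    for (i in seq_len(nrow(df))) {
      doms <- .split_domains(df$domains[i])
      bad <- setdiff(doms, vocab[[df$stage[i]]])
      if (length(bad) > 0) {
        stop("domain(s) not legal for stage '", df$stage[i], "' (gene ",
             df$gene[i], "): ", paste(bad, collapse = ", "))
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("domain_table", "data.frame")
  df
}

.split_domains <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

.join_domains <- function(x) paste(x, collapse = ";")

#' Generate a synthetic expression-domain table with known transitions
#'
#' Every gene receives a random subset of available stages (per the kernel's
#' availability; redrawn until at least two stages are available, since only
#' such genes enter the transition analysis) and a region-set trajectory
#' evolving under the kernel over its consecutive available stages. Region
#' sets are realized as stage-legal domain names via `region_vocab`. The
#' true category of every consecutive transition is recorded.
#'
#' @param n_genes number of genes (>= 1).
#' @param stages ordered stages to simulate over (default all seven).
#' @param kernel a [transition_kernel()].
#' @param region_vocab `stage -> region -> domains` lookup
#'   (default [region_representatives()]).
#' @param seed integer seed.
#' @return List of class `domain_table_sim` with `table` (a
#'   [domain_table()]) and `truth` (data frame `gene`, `initial_stage`,
#'   `final_stage`, `category`).
#' @export
generate_domain_table <- function(n_genes, stages = stage_names(),
                                  kernel = transition_kernel(),
                                  region_vocab = region_representatives(),
                                  seed = 1L) {
  stopifnot(n_genes >= 1, inherits(kernel, "transition_kernel"))
  stages <- canonical_stage(stages)
  stopifnot(length(stages) >= 2, !is.unsorted(stage_index(stages)))
  avail_p <- if (length(kernel$availability) == 1) {
    rep(kernel$availability, length(stages))
  } else {
    stopifnot(length(kernel$availability) == length(stages))
    kernel$availability
  }
  regions <- c("R1", "R2", "R3")
  nonempty_sets <- lapply(seq_len(7), function(m) {
    regions[as.logical(intToBits(m)[1:3])]
  })
  p <- kernel$p

  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_genes * length(stages))
    truth <- vector("list", n_genes * length(stages))
    ri <- 0L; ti <- 0L
    for (g in seq_len(n_genes)) {
      gene <- sprintf("g%04d", g)
      repeat {
        avail <- stats::runif(length(stages)) < avail_p
        if (sum(avail) >= 2) break
      }
      st <- stages[avail]
      # initial state
      state <- if (stats::runif(1) < kernel$start_empty) {
        character(0)
      } else {
        sample(regions, 1)
      }
      prev_state <- NULL
      for (j in seq_along(st)) {
        if (j > 1) {
          prev_state <- state
          if (length(state) > 0) {
            q <- p[c("minor", "major", "vanished")]
            cat_j <- if (sum(q) <= 0) "minor" else {
              sample(names(q), 1, prob = q / sum(q))
            }
            state <- switch(cat_j,
              minor = state,
              vanished = character(0),
              major = {
                others <- Filter(function(s) !setequal(s, state), nonempty_sets)
                others[[sample(length(others), 1)]]
              })
          } else {
            q <- p[c("appeared", "none")]
            cat_j <- if (sum(q) <= 0) "none" else {
              sample(names(q), 1, prob = q / sum(q))
            }
            state <- switch(cat_j, none = character(0),
                            appeared = sample(regions, 1))
          }
          ti <- ti + 1L
          truth[[ti]] <- data.frame(gene = gene, initial_stage = st[j - 1],
                                    final_stage = st[j], category = cat_j)
        }
        # realize the region set as stage-legal domain names
        doms <- unlist(lapply(sort(state), function(rg) {
          cand <- region_vocab[[st[j]]][[rg]]
          cand[sample(length(cand), 1)]
        }), use.names = FALSE)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(gene = gene, stage = st[j],
                                 domains = .join_domains(doms),
                                 noncylindrical = 0L)
      }
    }
    tab <- domain_table(do.call(rbind, rows[seq_len(ri)]))
    structure(list(table = tab,
                   truth = do.call(rbind, truth[seq_len(ti)]),
                   kernel = kernel),
              class = "domain_table_sim")
  })
}

#' @export
print.domain_table_sim <- function(x, ...) {
  cat("domain_table_sim:", length(unique(x$table$gene)), "genes,",
      nrow(x$truth), "recorded transitions\n")
  invisible(x)
}
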