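#' Developmental stage vocabulary
#'
#' The seven ordered developmental stages used throughout the package, from
#' blastula to late planula. All stage arguments in the package are matched
#' against this vocabulary (case-insensitively, with a small synonym list,
#' see [canonical_stage()]).
#'
#' @return Character vector of the seven stage names in developmental order.
#' @export
#' @examples
#' stage_names()
stage_names <- function() {
  c("blastula", "early gastrula", "mid gastrula", "late gastrula",
    "early planula", "planula", "late planula")
}

#' Stage index in developmental order
#'
#' @param stage character vector of stage names (canonicalized first).
#' @return integer vector, 1 for blastula through 7 for late planula.
#' @export
stage_index <- function(stage) {
  idx <- match(canonical_stage(stage), stage_names())
  idx
}

# synonym list for stage-name canonicalization; keys are lowercase with
# punctuation collapsed to single spaces
.stage_synonyms <- c(
  "gastrula (early)" = "early gastrula",
  "gastrula (mid)"   = "mid gastrula",
  "gastrula (late)"  = "late gastrula",
  "planula (early)"  = "early planula",
  "planula (late)"   = "late planula",
  "midgastrula"      = "mid gastrula",
  "early_gastrula"   = "early gastrula",
  "mid_gastrula"     = "mid gastrula",
  "late_gastrula"    = "late gastrula",
  "early_planula"    = "early planula",
  "late_planula"     = "late planula"
)

#' Canonicalize stage names
#'
#' Stage names are matched case-insensitively and a fixed synonym list is
#' applied (e.g. `"gastrula (mid)"` to `"mid gastrula"`). Unknown names are
#' an error listing the legal names; they are never guessed.
#'
#' @param stage character vector.
#' @return character vector of canonical stage names.
#' @export
#' @examples
#' canonical_stage(c("Blastula", "gastrula (mid)"))
canonical_stage <- function(stage) {
  if (!is.character(stage)) stage <- as.character(stage)
  low <- tolower(trimws(stage))
  syn <- .stage_synonyms[low]
  low[!is.na(syn)] <- syn[!is.na(syn)]
  bad <- !(low %in% stage_names())
  if (any(bad)) {
    stop("unknown stage name(s): ", paste(unique(stage[bad]), collapse = ", "),
         "; legal names are: ", paste(stage_names(), collapse = ", "))
  }
  low
}

#' Per-stage expression-domain vocabulary
#'
#' Legal named expression domains for each developmental stage, following the
#' schematic-morphology nomenclature for *Nematostella vectensis* (Cd =
#' central domain, Cr = central ring, Er = external ring, AnHe/VeHe = animal/
#' vegetal hemisphere, pEn = presumptive endoderm, bEc = blastoporal ectoderm,
#' En/Ec = endoderm/ectoderm, OrEc/AbEc = oral/aboral ectoderm, PhEc/PhEn =
#' pharyngeal ectoderm/endoderm, At = apical tuft, M = mouth, BwEc/BwEn =
#' body wall ectoderm/endoderm, MeEc/MeEn = mesentery ectoderm/endoderm,
#' TeEc/TeEn = tentacle ectoderm/endoderm, Si = siphonoglyph).
#'
#' @return Named list, one character vector of legal domain names per stage.
#' @export
domain_vocabulary <- function() {
  list(
    "blastula"       = c("AnHe", "VeHe", "An", "Ve", "Cd", "Cr", "Er"),
    "early gastrula" = c("pEn", "bEc", "Ec", "VeHe", "Ve", "An"),
    "mid gastrula"   = c("En", "bEc", "OrEc", "Ec", "VeHe", "Ve"),
    "late gastrula"  = c("En", "OrEc", "AbEc", "PhEc", "PhEn", "Ec", "Ve", "At"),
    "early planula"  = c("En", "OrEc", "AbEc", "PhEc", "PhEn", "Ec", "At",
                         "BwEc", "BwEn", "M"),
    "planula"        = c("En", "OrEc", "AbEc", "PhEc", "PhEn", "Ec", "At",
                         "AtEc", "AtEn", "BwEc", "BwEn", "MeEc", "MeEn", "M"),
    "late planula"   = c("En", "OrEc", "AbEc", "PhEc", "PhEn", "Ec", "At",
                         "AtEc", "AtEn", "BwEc", "BwEn", "MeEc", "MeEn", "M",
                         "TeB", "TeEc", "TeEn", "TeTi", "TeBa", "Si")
  )
}

#' Default map from expression domains to major regions
#'
#' The three major expression regions are: `R1` central domain/endoderm, `R2`
#' central ring/external ring/oral ectoderm, `R3` vegetal hemisphere/aboral
#' ectoderm. Domains without a clear single-region identity (pan-regional
#' names such as `Ec`, `AnHe`, or the body-wall ectoderm whose regional
#' assignment is uncertain) map to `"unmapped"`; they are reported, never
#' silently dropped. The map is an inference from the coarse region
#' groupings, and is deliberately user-overridable: pass a modified copy of
#' this named vector wherever a `region_map` is accepted.
#'
#' @return Named character vector: domain name -> one of `"R1"`, `"R2"`,
#'   `"R3"`, `"unmapped"`.
#' @export
#' @examples
#' default_region_map()[c("Cd", "Cr", "VeHe")]
default_region_map <- function() {
  c(
    # central domain / endoderm lineage
    Cd = "R1", An = "R1", pEn = "R1", En = "R1", PhEn = "R1", BwEn = "R1",
    MeEn = "R1", TeEn = "R1", AtEn = "R1",
    # central ring / external ring / oral ectoderm lineage
    Cr = "R2", Er = "R2", bEc = "R2", OrEc = "R2", PhEc = "R2", M = "R2",
    # vegetal hemisphere / aboral ectoderm lineage
    VeHe = "R3", Ve = "R3", AbEc = "R3", At = "R3", AtEc = "R3",
    # pan-regional or uncertain
    AnHe = "unmapped", Ec = "unmapped", BwEc = "unmapped", TeEc = "unmapped",
    MeEc = "unmapped", TeB = "unmapped", TeTi = "unmapped", TeBa = "unmapped",
    Si = "unmapped"
  )
}

#' Map a set of expression domains to major regions
#'
#' @param domains character vector of domain names (possibly empty).
#' @param region_map named character vector, see [default_region_map()].
#' @return List with `regions` (sorted character vector, subset of
#'   R1/R2/R3) and `unmapped` (domain names that carried no region).
#'   Unknown domain names are an error.
#' @export
#' @examples
#' map_domains_to_regions(c("Cd"))$regions      # "R1"
#' map_domains_to_regions(c("Cr", "Er"))$regions # "R2"
map_domains_to_regions <- function(domains, region_map = default_region_map()) {
  if (length(domains) == 0) {
    return(list(regions = character(0), unmapped = character(0)))
  }
  domains <- as.character(domains)
  unknown <- setdiff(domains, names(region_map))
  if (length(unknown) > 0) {
    stop("unknown expression domain name(s): ", paste(unknown, collapse = ", "))
  }
  reg <- region_map[domains]
  list(
    regions  = sort(unique(unname(reg[reg != "unmapped"]))),
    unmapped = unname(domains[reg == "unmapped"])
  )
}

#' Annotate a standardized profile with expression domains
#'
#' Rule-based bridge from a 100-point standardized profile to a set of named
#' expression domains: a domain is called present when the mean profile value
#' inside its arc-length window is at least `theta`. The windows must tile
#' `[0, 1]` without overlap. This mirrors how a curator would read a profile
#' against the schematic morphology, and lets synthetic profiles feed the
#' transition analysis end to end.
#'
#' @param profile a `standardized_profile` (see [standardize_profile()]) or a
#'   numeric vector of length 100.
#' @param windows data frame with columns `name`, `start`, `end` covering
#'   `[0,1]` without overlap.
#' @param theta presence threshold on the window-mean, in (0, 1); default 0.5.
#' @return Character vector of present domain names.
#' @export
annotate_profile <- function(profile, windows, theta = 0.5) {
  values <- if (inherits(profile, "standardized_profile")) profile$values else profile
  stopifnot(is.numeric(values), length(values) == 100L)
  if (!(theta > 0 && theta < 1)) stop("theta must be in (0, 1)")
  windows <- as.data.frame(windows)
  stopifnot(all(c("name", "start", "end") %in% names(windows)))
  o <- order(windows$start)
  windows <- windows[o, ]
  if (windows$start[1] > 0 || windows$end[nrow(windows)] < 1 ||
      (nrow(windows) > 1 && any(abs(windows$start[-1] - windows$end[-nrow(windows)]) > 1e-9))) {
    stop("windows must cover [0, 1] without overlap")
  }
  pos <- seq(0, 1, length.out = 100L)
  present <- vapply(seq_len(nrow(windows)), function(k) {
    inside <- if (k == nrow(windows)) {
      pos >= windows$start[k] & pos <= windows$end[k]
    } else {
      pos >= windows$start[k] & pos < windows$end[k]
    }
    mean(values[inside]) >= theta
  }, logical(1))
  as.character(windows$name[present])
}
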