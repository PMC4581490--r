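#' Read an image as a single-channel intensity matrix
#'
#' PNG and TIFF are supported. RGB(A) images are reduced to one channel by
#' the chosen policy (Rec. 601 luminance by default, or a single stain
#' channel), and inverted by default: ISH signal is a dark stain on a light
#' background, so `1 - luminance` makes stronger staining brighter. Pass
#' `invert = FALSE` for signal-positive images (e.g. the synthetic
#' generator's output).
#'
#' @param path PNG or TIFF file path.
#' @param invert subtract the intensity from 1 (default `TRUE`).
#' @param channel `"luminance"` (default), `"red"`, `"green"` or `"blue"`.
#' @return Numeric matrix in \[0,1\], rows = image rows (y down).
#' @export
read_image <- function(path, invert = TRUE,
                       channel = c("luminance", "red", "green", "blue")) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  img <- if (length(dim(arr)) == 2) {
    arr
  } else {
    switch(channel,
      luminance = 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3],
      red = arr[, , 1], green = arr[, , 2], blue = arr[, , 3])
  }
  if (invert) img <- 1 - img
  img
}

#' Write an intensity matrix as a PNG or TIFF image
#'
#' Values are clamped to \[0,1\].
#'
#' @param image numeric matrix.
#' @param path output path; format chosen from the extension.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  invisible(path)
}

#' Write standardized profiles to CSV
#'
#' One row per sample: `gene`, `stage`, `sample_id`, `p001` ... `p100`.
#'
#' @param profiles a `profile_set` or list of [standardized_profile()].
#' @param path output CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  meta <- data.frame(
    gene = vapply(profiles, function(p) p$gene, character(1)),
    stage = vapply(profiles, function(p) p$stage, character(1)),
    sample_id = vapply(profiles, function(p) p$sample_id, character(1))
  )
  vals <- t(vapply(profiles, function(p) p$values, numeric(100)))
  colnames(vals) <- sprintf("p%03d", 1:100)
  utils::write.csv(cbind(meta, as.data.frame(vals)), path, row.names = FALSE)
  invisible(path)
}

#' Read standardized profiles from CSV
#'
#' @param path CSV with the [write_profiles_csv()] schema.
#' @return List of [standardized_profile()] objects (validated: length 100,
#'   nonnegative, maximum 1).
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pcols <- sprintf("p%03d", 1:100)
  miss <- setdiff(c("gene", "stage", "sample_id", pcols), names(df))
  if (length(miss) > 0) {
    stop("profile CSV ", path, " is missing column(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  }
  lapply(seq_len(nrow(df)), function(i) {
    standardized_profile(as.numeric(df[i, pcols]),
                         gene = df$gene[i], stage = df$stage[i],
                         sample_id = df$sample_id[i])
  })
}

#' Write an expression-domain table to CSV
#'
#' Columns: `gene`, `stage`, `domains` (semicolon-separated names, empty =
#' no staining), `noncylindrical` (0/1).
#'
#' @param table a [domain_table()].
#' @param path output CSV path.
#' @export
write_domain_table_csv <- function(table, path) {
  if (!inherits(table, "domain_table")) table <- domain_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read an expression-domain table from CSV
#'
#' @param path CSV with the [write_domain_table_csv()] schema.
#' @param check_vocabulary validate domains against [domain_vocabulary()].
#' @return A [domain_table()].
#' @export
read_domain_table_csv <- function(path, check_vocabulary = TRUE) {
  df <- utils::read.csv(path, colClasses = c(domains = "character"))
  domain_table(df, check_vocabulary = check_vocabulary)
}

#' Write pairwise transition counts to CSV
#'
#' Long format mirroring a pairwise-counts spreadsheet: `filter`,
#' `initial_stage`, `final_stage`, `minor`, `major`, `appeared`,
#' `vanished`, `none` (the latter two columns empty for region-filtered
#' tuples).
#'
#' @param matrices named list of `pairwise_counts` (names ignored; the
#'   filter attribute is written), or a single `pairwise_counts`.
#' @param path output CSV path.
#' @export
write_pairwise_counts_csv <- function(matrices, path) {
  if (inherits(matrices, "pairwise_counts")) matrices <- list(matrices)
  rows <- list()
  for (m in matrices) {
    cats <- dimnames(m)[[3]]
    for (i in 1:6) for (f in (i + 1):7) {
      cell <- m[i, f, ]
      if (sum(cell) == 0) next
      row <- data.frame(filter = attr(m, "filter"),
                        initial_stage = stage_names()[i],
                        final_stage = stage_names()[f],
                        minor = NA_integer_, major = NA_integer_,
                        appeared = NA_integer_, vanished = NA_integer_,
                        none = NA_integer_)
      for (ct in cats) row[[ct]] <- cell[[ct]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read pairwise transition counts from CSV
#'
#' @param path CSV with the [write_pairwise_counts_csv()] schema.
#' @return Named list of `pairwise_counts`, one per filter present.
#' @export
read_pairwise_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("filter", "initial_stage", "final_stage", "minor", "major")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pairwise counts CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- list()
  for (flt in unique(df$filter)) {
    sub <- df[df$filter == flt, ]
    cats <- transition_categories(flt)
    sub[cats][is.na(sub[cats])] <- 0L
    out[[flt]] <- pairwise_counts(sub[, c("initial_stage", "final_stage", cats)],
                                  filter = flt)
  }
  out
}

#' Write a period summary to CSV
#'
#' Columns: `period`, one count column and one percentage column per
#' category.
#'
#' @param summary a [aggregate_periods()] result.
#' @param path output CSV path.
#' @export
write_period_summary_csv <- function(summary, path) {
  stopifnot(inherits(summary, "period_summary"))
  cats <- colnames(summary$counts)
  df <- data.frame(period = rownames(summary$counts))
  for (ct in cats) df[[paste0("count_", ct)]] <- summary$counts[, ct]
  for (ct in cats) df[[paste0("pct_", ct)]] <- summary$percentages[, ct]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Reference pairwise transition counts for *Nematostella vectensis*
#'
#' The expression-domain transition counts for the 73 *N. vectensis* genes
#' with Kahi Kai ISH images in at least two stages, as tallied in the
#' published survey this package reimplements: three region-filtered tables
#' (initial expression exactly in the central domain/endoderm `R1`, the
#' central/external ring and oral ectoderm `R2`, or the vegetal
#' hemisphere/aboral ectoderm `R3`) and one all-regions table.
#'
#' @return Named list of `pairwise_counts` with elements `R1`, `R2`, `R3`
#'   and `all`.
#' @export
#' @examples
#' summ <- aggregate_periods(nv_reference_counts()$R1)
#' summ$percentages[1, ]  # 88:8:4
nv_reference_counts <- function() {
  path <- system.file("extdata", "nv_pairwise_counts.csv",
                      package = "ishquant", mustWork = TRUE)
  read_pairwise_counts_csv(path)
}

#' Write a provenance record for a pipeline run
#'
#' @param path output JSON path.
#' @param config list of parameters used.
#' @param seed integer seed(s) used.
#' @export
write_provenance <- function(path, config = list(), seed = NA_integer_) {
  rec <- list(
    package = "ishquant",
    version = as.character(utils::packageVersion("ishquant")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
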