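# Minimal MAT-file (level 5) container support: uncompressed double
# matrices only, little-endian. Enough to exchange stage-grouped profile
# arrays with MATLAB-format tooling; no installed R package reads MAT files.

.mi_INT8 <- 1L; .mi_INT32 <- 5L; .mi_UINT32 <- 6L; .mi_DOUBLE <- 9L
.mi_MATRIX <- 14L
.mx_DOUBLE_CLASS <- 6L

.pad8 <- function(n) (8L - n %% 8L) %% 8L

#' Write numeric matrices to a MAT v5 file
#'
#' @param vars named list of numeric matrices (or vectors, stored 1 x n).
#' @param path output path.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- "MATLAB 5.0 MAT-file, created by ishquant"
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(rep(as.raw(0), 8), con)                 # subsystem offset
  writeBin(as.integer(c(0x0100)), con, size = 2)   # version
  writeBin(charToRaw("IM"), con)                   # little-endian marker
  for (nm in names(vars)) {
    m <- vars[[nm]]
    if (!is.matrix(m)) m <- matrix(as.numeric(m), nrow = 1)
    storage.mode(m) <- "double"
    name_raw <- charToRaw(nm)
    npad <- .pad8(length(name_raw))
    nbytes <- 16L + 16L + (8L + length(name_raw) + npad) + (8L + 8L * length(m))
    writeBin(c(.mi_MATRIX, nbytes), con, size = 4)
    writeBin(c(.mi_UINT32, 8L), con, size = 4)     # array flags
    writeBin(c(.mx_DOUBLE_CLASS, 0L), con, size = 4)
    writeBin(c(.mi_INT32, 8L), con, size = 4)      # dimensions
    writeBin(c(nrow(m), ncol(m)), con, size = 4)
    writeBin(c(.mi_INT8, length(name_raw)), con, size = 4)  # name
    writeBin(name_raw, con)
    if (npad > 0) writeBin(rep(as.raw(0), npad), con)
    writeBin(c(.mi_DOUBLE, 8L * length(m)), con, size = 4)  # real data
    writeBin(as.numeric(m), con, size = 8)
  }
  invisible(path)
}

# read one element tag; returns list(type, nbytes, small_data or NULL)
.read_tag <- function(con) {
  raw4 <- readBin(con, "raw", 4)
  if (length(raw4) < 4) return(NULL)
  type_full <- readBin(raw4, "integer", 1, size = 4, endian = "little")
  small_n <- bitwAnd(bitwShiftR(type_full, 16), 0xFFFF)
  if (small_n != 0) {                 # small data element format
    type <- bitwAnd(type_full, 0xFFFF)
    data <- readBin(con, "raw", 4)
    list(type = type, nbytes = small_n, small = data[seq_len(small_n)])
  } else {
    nbytes <- readBin(con, "integer", 1, size = 4, endian = "little")
    list(type = type_full, nbytes = nbytes, small = NULL)
  }
}

.read_subelement <- function(con) {
  tag <- .read_tag(con)
  if (is.null(tag)) return(NULL)
  if (!is.null(tag$small)) {
    return(list(type = tag$type, data = tag$small))
  }
  data <- readBin(con, "raw", tag$nbytes)
  pad <- .pad8(tag$nbytes)
  if (pad > 0) readBin(con, "raw", pad)
  list(type = tag$type, data = data)
}

#' Read numeric matrices from a MAT v5 file
#'
#' Supports uncompressed little-endian files with double-precision
#' matrices (as written by [write_mat()] and by MATLAB/scipy with
#' compression disabled).
#'
#' @param path MAT file path.
#' @return Named list of numeric matrices.
#' @export
read_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 124)
  if (length(hdr) < 124) stop(path, " is not a MAT v5 file (truncated header)")
  version <- readBin(con, "integer", 1, size = 2, endian = "little")
  endmark <- rawToChar(readBin(con, "raw", 2))
  if (endmark == "MI") stop("big-endian MAT files are not supported")
  if (endmark != "IM") stop(path, " is not a MAT v5 file (bad endian marker)")
  out <- list()
  repeat {
    tag <- .read_tag(con)
    if (is.null(tag)) break
    if (tag$type == 15L) stop("compressed MAT elements are not supported")
    if (tag$type != .mi_MATRIX) {
      readBin(con, "raw", tag$nbytes + .pad8(tag$nbytes))
      next
    }
    flags <- .read_subelement(con)
    cls <- bitwAnd(readBin(flags$data, "integer", 1, size = 4,
                           endian = "little"), 0xFF)
    dims_el <- .read_subelement(con)
    dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4,
                    size = 4, endian = "little")
    name_el <- .read_subelement(con)
    nm <- rawToChar(name_el$data)
    data_el <- .read_subelement(con)
    if (cls != .mx_DOUBLE_CLASS || data_el$type != .mi_DOUBLE) {
      stop("variable '", nm, "' is not a double matrix")
    }
    vals <- readBin(data_el$data, "double", length(data_el$data) / 8,
                    size = 8, endian = "little")
    if (length(dims) != 2 || prod(dims) != length(vals)) {
      stop("variable '", nm, "' has an unsupported array shape")
    }
    out[[nm]] <- matrix(vals, dims[1], dims[2])
  }
  out
}

#' Read stage-grouped standardized profiles from a MAT file
#'
#' Each variable in the file is expected to hold one stage's profiles. The
#' stage is discovered from the variable name (canonicalized, with
#' underscores allowed, e.g. `early_gastrula`); the orientation is
#' discovered from the shape (the dimension of length 100 is the profile
#' axis, with samples x 100 preferred when ambiguous). What was found is
#' reported via `message()`. Profiles failing validation (length 100,
#' values nonnegative, maximum 1 within 1e-6) are an error naming the
#' variable.
#'
#' @param path MAT file path.
#' @return Named list, stage -> list of [standardized_profile()].
#' @export
read_profiles_mat <- function(path) {
  vars <- read_mat(path)
  if (length(vars) == 0) stop("no variables found in ", path)
  out <- list()
  for (nm in names(vars)) {
    stage <- tryCatch(canonical_stage(gsub("_", " ", nm)),
                      error = function(e) {
                        stop("cannot infer a stage from variable '", nm, "': ",
                             conditionMessage(e))
                      })
    m <- vars[[nm]]
    if (ncol(m) == 100L) {
      # samples x 100, keep
    } else if (nrow(m) == 100L) {
      m <- t(m)
    } else {
      stop("variable '", nm, "' has shape ", nrow(m), " x ", ncol(m),
           "; neither dimension is 100")
    }
    profs <- lapply(seq_len(nrow(m)), function(i) {
      v <- m[i, ]
      if (any(v < 0) || abs(max(v) - 1) > 1e-6) {
        stop("variable '", nm, "' row ", i,
             " is not a standardized profile (nonnegative, max 1)")
      }
      v <- v / max(v)
      standardized_profile(v, gene = sprintf("%s_%03d", nm, i),
                           stage = stage,
                           sample_id = sprintf("%s_%03d", nm, i))
    })
    message("read ", length(profs), " profile(s) for stage '", stage,
            "' from variable '", nm, "'")
    out[[stage]] <- c(out[[stage]], profs)
  }
  out
}

#' Write stage-grouped standardized profiles to a MAT file
#'
#' One samples x 100 double matrix per stage, variable names with
#' underscores (`early_gastrula`, ...).
#'
#' @param profiles a `profile_set` or list of [standardized_profile()].
#' @param path output path.
#' @export
write_profiles_mat <- function(profiles, path) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  stages <- vapply(profiles, function(p) p$stage, character(1))
  vars <- list()
  for (st in unique(stages)) {
    m <- t(vapply(profiles[stages == st], function(p) p$values, numeric(100)))
    vars[[gsub(" ", "_", st)]] <- m
  }
  write_mat(vars, path)
}
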