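#' Read an experimental observation (.dat) file
#'
#' Whitespace-delimited plain text; lines starting with `#` are comments.
#' The dialect is auto-detected: a single number on a single line is a
#' scalar; one column over several lines is a list; two columns are a
#' curve (x then y, x strictly increasing).
#'
#' @param path path to a `.dat` file.
#' @return scalar, numeric vector, or [curve_data()].
#' @export
read_dat <- function(path) {
  if (!file.exists(path)) stop(sprintf("observation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop(sprintf("%s: no data lines", path))
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      bad <- toks[which(is.na(vals))[1]]
      stop(sprintf("%s: non-numeric token '%s' on line %d", path, bad, i))
    }
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    stop(sprintf("%s: inconsistent column counts", path))
  }
  if (ncols == 1L) {
    vals <- vapply(rows, `[`, numeric(1), 1L)
    if (length(vals) == 1L) return(vals)
    return(vals)
  }
  if (ncols == 2L) {
    x <- vapply(rows, `[`, numeric(1), 1L)
    y <- vapply(rows, `[`, numeric(1), 2L)
    if (any(diff(x) <= 0)) {
      stop(sprintf("%s: curve x-values must be strictly increasing", path))
    }
    return(curve_data(x, y))
  }
  stop(sprintf("%s: expected 1 or 2 columns, found %d", path, ncols))
}

#' Write an observation (.dat) file
#'
#' Inverse of [read_dat()]: scalars and lists as one column, curves as
#' two columns. Full double precision so generated fixtures round-trip
#' exactly.
#'
#' @param payload scalar, numeric vector, or `calib_curve`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(payload, path) {
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  lines <- if (is_curve(payload)) {
    paste(fmt(payload$x), fmt(payload$y))
  } else {
    fmt(as.numeric(payload))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load paired model/observation files from two directories
#'
#' Each forward-model definition file (`.yaml`) in `model_dir` must have
#' a same-basename `.dat` partner in `data_dir`. Orphans on either side
#' are reported together before anything is run. Pairs are returned in
#' filename-sorted order.
#'
#' @param model_dir directory of model definition files.
#' @param data_dir directory of `.dat` observation files (defaults to
#'   `model_dir`).
#' @return list of `list(model = , obs = )` pairs.
#' @export
load_pairs <- function(model_dir, data_dir = model_dir) {
  model_files <- sort(list.files(model_dir, pattern = "\\.ya?ml$", full.names = TRUE))
  model_files <- model_files[!basename(model_files) %in% c("manifest.yaml", "manifest.yml", "config.yaml", "config.yml")]
  dat_files <- sort(list.files(data_dir, pattern = "\\.dat$", full.names = TRUE))
  if (!length(model_files)) stop(sprintf("no model files found in %s", model_dir))
  mb <- sub("\\.(ya?ml)$", "", basename(model_files))
  db <- sub("\\.dat$", "", basename(dat_files))
  orphans <- c(sprintf("model without data: %s", setdiff(mb, db)),
               sprintf("data without model: %s", setdiff(db, mb)))
  if (length(orphans)) {
    stop(paste(c("unpaired model/data files:", orphans), collapse = "\n  "))
  }
  lapply(seq_along(model_files), function(i) {
    model <- read_model_file(model_files[i])
    payload <- read_dat(file.path(data_dir, paste0(mb[i], ".dat")))
    obs <- observation(mb[i], payload)
    if (obs$kind != model_output_kind(model)) {
      stop(sprintf("specimen '%s': observation kind '%s' does not match model output kind '%s'",
                   mb[i], obs$kind, model_output_kind(model)))
    }
    list(model = model, obs = obs)
  })
}
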