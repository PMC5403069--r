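#' Read an en-face angiogram from PNG or TIFF
#'
#' Loads an 8-bit grayscale image; colour or higher-depth inputs are
#' converted to 8-bit luminance (BT.709 weights) with a message, since the
#' nonperfusion threshold is only meaningful on the 0-255 scale.
#'
#' @param path PNG or TIFF file.
#' @param plexus slab label to attach (`"superficial"` or `"deep"`).
#' @param field_mm physical field width used for calibration (default 3).
#' @param eye_id identifier; defaults to the file stem.
#' @return an [enface_angiogram()].
#' @export
read_angiogram <- function(path, plexus = c("superficial", "deep"),
                           field_mm = 3.0,
                           eye_id = sub("\\.[^.]*$", "", basename(path))) {
  plexus <- match.arg(plexus)
  if (!file.exists(path)) stop_io("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_io("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    } else {
      stop_io("unsupported image format: ", path)
    }
  }, error = function(e) {
    stop_io("could not read image ", path, ": ", conditionMessage(e))
  })
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      message("colour image ", basename(path), ": converted to luminance")
      arr <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  px <- matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
  enface_angiogram(px, calibrate(ncol(px), field_mm), plexus = plexus,
                   eye_id = eye_id)
}

#' Write an en-face angiogram as 8-bit grayscale PNG
#'
#' @param image an [enface_angiogram()].
#' @param path output path (`.png`).
#' @return the path, invisibly.
#' @export
write_angiogram <- function(image, path) {
  px <- angiogram_pixels(image)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read a traced FAZ contour
#'
#' Accepts either a JSON vertex list (an array of \[x, y\] pairs, or an
#' object with a `vertices` field) or two-column whitespace-separated XY
#' text as exported by manual tracing tools; a non-numeric header line in
#' XY text is skipped with a notice, and a duplicated closing vertex is
#' removed with a warning.
#'
#' @param path contour file (`.json` or text).
#' @return a [faz_contour()] with source `"manual_trace"`.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop_io("contour file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) {
                      stop_io("could not parse JSON contour ", path, ": ",
                              conditionMessage(e))
                    })
    v <- if (is.list(obj) && !is.null(obj$vertices)) obj$vertices else obj
    v <- as.matrix(v)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    toks <- strsplit(trimws(first), "\\s+")[[1L]]
    skip <- if (length(toks) >= 2L && anyNA(suppressWarnings(as.numeric(toks)))) {
      message("skipping header line in ", basename(path))
      1L
    } else 0L
    v <- as.matrix(utils::read.table(path, skip = skip,
                                     col.names = c("x", "y")))
  }
  faz_contour(v, source = "manual_trace")
}

#' Write a contour as a JSON vertex list
#' @param contour a [faz_contour()].
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_contour <- function(contour, path) {
  v <- if (inherits(contour, "faz_contour")) contour else faz_contour(contour)
  jsonlite::write_json(
    list(source = attr(v, "source"),
         vertices = unclass(matrix(as.numeric(v), nrow(v)))),
    path, auto_unbox = TRUE, digits = 6
  )
  invisible(path)
}

#' Pipeline run configuration
#'
#' Holds the constants of the measurement protocol: field width, the NPI
#' brightness threshold and its inequality, the questionable-contour band
#' of the FAZ grade, the entry/stay p-values of the covariate model, and
#' the RNG seed. Round-trips losslessly through JSON.
#'
#' @param field_mm imaged field width (mm).
#' @param npi_threshold 8-bit nonperfusion brightness threshold.
#' @param inclusive_threshold count pixels equal to the threshold.
#' @param questionable_epsilon grade-1 band of [grade_faz()].
#' @param entry_p,stay_p covariate entry / retention p-values.
#' @param seed RNG seed recorded with every report.
#' @return a `run_config` list.
#' @export
run_config <- function(field_mm = 3.0, npi_threshold = 45L,
                       inclusive_threshold = FALSE,
                       questionable_epsilon = 0.05,
                       entry_p = 0.20, stay_p = 0.05, seed = 1L) {
  check_positive(field_mm, "field_mm")
  if (npi_threshold < 0 || npi_threshold > 255) {
    stop_param("`npi_threshold` must lie in [0, 255]")
  }
  check_fraction(questionable_epsilon, "questionable_epsilon")
  check_fraction(entry_p, "entry_p")
  check_fraction(stay_p, "stay_p")
  structure(list(field_mm = field_mm,
                 npi_threshold = as.integer(npi_threshold),
                 inclusive_threshold = isTRUE(inclusive_threshold),
                 questionable_epsilon = questionable_epsilon,
                 entry_p = entry_p, stay_p = stay_p,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Canonical JSON with sorted keys and 6-significant-digit floats, so that
# identical inputs give byte-identical (hashable) reports.
canonical_json <- function(x) {
  sort_keys <- function(o) {
    if (is.list(o) && !is.null(names(o)) && length(o)) {
      o <- o[order(names(o))]
      lapply(o, sort_keys)
    } else if (is.list(o)) {
      lapply(o, sort_keys)
    } else o
  }
  jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = I(6),
                   dataframe = "rows", na = "null", pretty = TRUE)
}

#' Write an analysis report atomically
#'
#' Serializes the report as canonical JSON (sorted keys, fixed float
#' precision) plus one CSV per tabular section, writing to temporary files
#' first and renaming into place. The JSON carries the config, its MD5
#' hash, the seed, and the package version, so identical inputs yield an
#' identical report hash.
#'
#' @param report a report list, e.g. from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  writeLines(canonical_json(report), tmp)
  file.rename(tmp, json_path)
  written <- json_path
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      csv <- file.path(dir, paste0(nm, ".csv"))
      tmpc <- tempfile(tmpdir = dir, fileext = ".csv")
      utils::write.csv(report[[nm]], tmpc, row.names = FALSE)
      file.rename(tmpc, csv)
      written <- c(written, csv)
    }
  }
  invisible(written)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical_json(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
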