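#' @include AllClasses.R methods-accessors.R
NULL

# Header synonyms accepted in vendor exports, matched case/space-insensitively.
HEADER_SYNONYMS <- list(
  mz            = c("mz", "m/z", "mass", "masstocharge", "masstochargeratio"),
  time          = c("time", "tof", "acquisitiontime"),
  intensity     = c("intensity", "intens"),
  snr           = c("snr", "s/n", "sn", "signaltonoise", "signaltonoiseratio"),
  resolution    = c("resolution", "res"),
  area          = c("area", "peakarea"),
  rel_intensity = c("relintensity", "relativeintensity", "reli", "rel"),
  fwhm          = c("fwhm", "fullwidthathalfmaximum", "fullwidthhalfmaximum"))

normalizeHeader <- function(x) gsub("[^a-z/]", "", tolower(x))

# Map raw export column names onto the eight canonical peak columns.
# Returns the named index vector or stops naming the first missing column.
matchPeakColumns <- function(nms) {
  norm <- normalizeHeader(nms)
  idx <- vapply(names(HEADER_SYNONYMS), function(canon) {
    hit <- which(norm %in% HEADER_SYNONYMS[[canon]])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(idx))
    stop(sprintf("peak table is missing required column(s): %s",
                 paste(names(idx)[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  idx
}

# Coerce a raw data.frame from any dialect into the canonical peak frame:
# canonical column order, numeric columns with unparseable cells as NA, and
# rel_intensity normalised from percent to [0, 1] when needed.
canonicalizePeakFrame <- function(raw) {
  idx <- matchPeakColumns(colnames(raw))
  pk <- raw[, idx, drop = FALSE]
  colnames(pk) <- PEAK_COLUMNS
  pk[] <- lapply(pk, function(col) {
    if (is.numeric(col)) as.numeric(col)
    else suppressWarnings(as.numeric(as.character(col)))
  })
  pctDialect <- FALSE
  ri <- pk$rel_intensity
  if (any(!is.na(ri)) && max(ri, na.rm = TRUE) > 1.5) {
    pk$rel_intensity <- ri / 100   # percent dialect -> [0, 1]
    pctDialect <- TRUE
  }
  rownames(pk) <- NULL
  attr(pk, "relIntensityPercent") <- pctDialect
  pk
}

# Parse "<farm>_<sample>_run<k>" metadata from a file name.
parseRunFilename <- function(path) {
  base <- sub("\\.[A-Za-z]+$", "", basename(path))
  m <- regmatches(base, regexec("^(.+)_([^_]+)_run([0-9]+)$", base))[[1]]
  if (length(m) == 4)
    return(list(farmId = m[2], sampleId = paste(m[2], m[3], sep = "_"),
                runIndex = as.integer(m[4])))
  list(farmId = base, sampleId = base, runIndex = 1L)
}

#' Read one exported peak table
#'
#' Reads a per-run peak table as exported by the acquisition software (one
#' spectrum per file) into a [SpectrumRun-class]. Columns are matched by
#' header name, case- and space-insensitively and order-tolerantly, against
#' the eight expected peak features; unparseable cells become `NA`. Relative
#' intensity given in percent is normalised to \[0, 1\]. Farm, sample and run
#' metadata are parsed from the file name convention
#' `<farm>_<sample>_run<k>.<ext>`; the species label is taken from the parent
#' folder name when it is one of the three milk classes.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @param dialect `"auto"` (from the file extension), `"csv"` or `"xlsx"`.
#'   Reading xlsx requires the readxl package.
#' @param species optional explicit species label overriding folder-based
#'   detection.
#' @return a [SpectrumRun-class]; empty files yield an empty run with a
#'   warning, a missing required column is an error naming the column.
#' @seealso [writePeakTable()], [loadDatasetTree()]
#' @export
readPeakTable <- function(path, dialect = c("auto", "csv", "xlsx"),
                          species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx"
               else "csv"
  raw <- if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = 1, col_types = "text"))
  } else {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  meta <- parseRunFilename(path)
  if (is.null(species)) {
    parent <- basename(dirname(normalizePath(path, mustWork = FALSE)))
    species <- if (parent %in% MILK_SPECIES) parent else "Unknown"
  }
  if (nrow(raw) == 0) {
    warning("empty peak table: ", path)
    pk <- emptyPeakFrame()
    if (ncol(raw) >= length(PEAK_COLUMNS)) matchPeakColumns(colnames(raw))
  } else {
    pk <- canonicalizePeakFrame(raw)
  }
  SpectrumRun(pk, farmId = meta$farmId, sampleId = meta$sampleId,
              runIndex = meta$runIndex, species = species)
}

#' Write a peak table
#'
#' Writes a [SpectrumRun-class] peak table as CSV with the eight canonical
#' columns in fixed order (`mz`, `time`, `intensity`, `snr`, `resolution`,
#' `area`, `rel_intensity`, `fwhm`), readable back by [readPeakTable()].
#' CSV is the pipeline's native on-disk format; xlsx files are supported as
#' read-only vendor-export inputs.
#'
#' @param run a [SpectrumRun-class].
#' @param path destination file path.
#' @param dialect only `"csv"` is writable.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(run, path, dialect = c("csv", "xlsx")) {
  dialect <- match.arg(dialect)
  stopifnot(is(run, "SpectrumRun"))
  if (dialect == "xlsx")
    stop("xlsx output is not supported; xlsx is a read-only input format, ",
         "use dialect = 'csv'")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    write.csv(run@peaks[, PEAK_COLUMNS, drop = FALSE], path,
              row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write peak table to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Load a labelled folder tree of peak tables
#'
#' Walks a dataset root whose immediate subfolders are named by species label
#' (`Bovine_Milk`, `Goat_Milk`, `Sheep_Milk`), reads every `.csv`/`.xlsx`
#' peak-table file inside them, groups files into samples via the
#' `<farm>_<sample>_run<k>` naming convention, and attaches every run to
#' exactly one species-labelled sample. Files outside a recognised species
#' folder are skipped with a warning and counted in the provenance. The
#' result is independent of file-enumeration order: runs are sorted by
#' sample id and run index.
#'
#' @param root dataset root directory.
#' @param manifest optional path to a YAML manifest mapping `file` to
#'   `sample` and `species`, overriding the folder/name conventions.
#' @param verbose emit a message with file/run/row counts.
#' @return a [MilkDataset-class] with provenance counts
#'   (`nFiles`, `nRuns`, `nRows`, `nSkipped`).
#' @export
loadDatasetTree <- function(root, manifest = NULL, verbose = FALSE) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  manifestMap <- NULL
  if (!is.null(manifest)) {
    entries <- yaml::read_yaml(manifest)$files
    manifestMap <- do.call(rbind, lapply(entries, function(e)
      data.frame(file = e$file, sample = e$sample, species = e$species)))
  }
  files <- list.files(root, pattern = "\\.(csv|xlsx)$", recursive = TRUE,
                      full.names = TRUE)
  runs <- list(); nSkipped <- 0L
  for (f in files) {
    rel <- sub(paste0("^", normalizePath(root), .Platform$file.sep), "",
               normalizePath(f))
    species <- NULL; sampleOverride <- NULL
    if (!is.null(manifestMap)) {
      hit <- match(rel, manifestMap$file)
      if (!is.na(hit)) {
        species <- manifestMap$species[hit]
        sampleOverride <- manifestMap$sample[hit]
      }
    }
    if (is.null(species)) {
      top <- strsplit(rel, .Platform$file.sep, fixed = TRUE)[[1]][1]
      if (top %in% MILK_SPECIES) species <- top
    }
    if (is.null(species)) {
      warning("file under no recognised species label, skipped: ", rel)
      nSkipped <- nSkipped + 1L
      next
    }
    run <- readPeakTable(f, species = species)
    if (!is.null(sampleOverride)) run@sampleId <- sampleOverride
    runs[[length(runs) + 1L]] <- run
  }
  ord <- order(vapply(runs, slot, character(1), "sampleId"),
               vapply(runs, slot, integer(1), "runIndex"))
  runs <- runs[ord]
  nRows <- sum(vapply(runs, function(r) nrow(r@peaks), integer(1)))
  if (verbose)
    message(sprintf("loaded %d files: %d runs, %d peak rows (%d skipped)",
                    length(files), length(runs), nRows, nSkipped))
  MilkDataset(runs, provenance = list(
    source = root, nFiles = length(files), nRuns = length(runs),
    nRows = nRows, nSkipped = nSkipped))
}

#' Write a dataset as a species-labelled folder tree
#'
#' Inverse of [loadDatasetTree()]: one CSV per run under
#' `<outDir>/<species>/<sample>_run<k>.csv`, plus a YAML manifest listing
#' every file with its sample, species and MD5 digest.
#'
#' @param dataset a [MilkDataset-class].
#' @param outDir destination directory (created if needed).
#' @return path to the written manifest, invisibly.
#' @export
writeDatasetTree <- function(dataset, outDir) {
  stopifnot(is(dataset, "MilkDataset"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset@runs, function(run) {
    fn <- sprintf("%s_run%d.csv", run@sampleId, run@runIndex)
    dest <- file.path(outDir, run@species, fn)
    writePeakTable(run, dest)
    list(file = file.path(run@species, fn), sample = run@sampleId,
         species = run@species, md5 = unname(tools::md5sum(dest)))
  })
  manifestPath <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(list(provenance = dataset@provenance, files = entries),
                   manifestPath)
  invisible(manifestPath)
}
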