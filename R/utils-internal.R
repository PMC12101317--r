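# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rlnorm runif median quantile IQR sd
#' @importFrom utils read.csv write.csv head
NULL

MILK_SPECIES <- c("Bovine_Milk", "Goat_Milk", "Sheep_Milk")
MZ_WINDOW <- c(3000, 10000)
PEAK_COLUMNS <- c("mz", "time", "intensity", "snr", "resolution",
                  "area", "rel_intensity", "fwhm")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library functions never disturb user state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic digest of any jsonlite-serializable object, via tools::md5sum.
configDigest <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

speciesToIndex <- function(species) {
  idx <- match(species, MILK_SPECIES) - 1L
  if (anyNA(idx))
    stop("unknown species label(s): ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  idx
}

indexToSpecies <- function(idx) {
  stopifnot(all(idx %in% 0:2))
  MILK_SPECIES[idx + 1L]
}

# Derive a stream of child seeds from one parent seed, staying inside the
# 32-bit integer range the base RNG accepts.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}
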