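#' Readers, writers, configuration and run manifests
#'
#' Plain-text interchange for every artifact the pipeline produces:
#' gray images as ASCII PGM (and PNG when the `png` package is present),
#' spike-count datasets as tidy CSV plus a JSON sidecar, run
#' configurations as YAML with exact round-tripping, and JSON manifests
#' stamping each output directory with the configuration hash and seed
#' that produced it.
#'
#' @name io
NULL

#' Read and write ASCII (P2) PGM gray images
#'
#' Pixels are rescaled to `[0, 1]` on read and quantized to `maxval`
#' levels on write.
#'
#' @param path file path.
#' @param image a matrix in `[0, 1]` (for writing).
#' @param maxval maximum gray level written.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!startsWith(trimws(txt), "#")]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: pixel count mismatch")
  matrix(vals, h, w, byrow = TRUE) / maxval
}

#' @rdname read_pgm
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gray image from PNG or PGM
#'
#' PNG support requires the `png` package; color PNGs are converted to
#' luminance.
#'
#' @param path file ending in `.png` or `.pgm`.
#' @return Matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG requires the `png` package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L)
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  img
}

#' Write a recording dataset as tidy CSV plus JSON sidecar
#'
#' `counts.csv` holds one row per (neuron, image, size, trial) count,
#' `rf.csv` the RF centers in degrees, and `meta.json` everything else
#' (diameters, baseline statistics, platform, generating configuration).
#'
#' @param dataset a `recording_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "recording_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$counts)
  long <- data.frame(
    neuron = rep(seq_len(d[1]), times = d[2] * 2L * d[4]),
    image = rep(rep(seq_len(d[2]), each = d[1]), times = 2L * d[4]),
    size = rep(rep(c("small", "large"), each = d[1] * d[2]), times = d[4]),
    trial = rep(seq_len(d[4]), each = d[1] * d[2] * 2L),
    count = as.vector(dataset$counts))
  utils::write.csv(long, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(dataset$rf, file.path(dir, "rf.csv"), row.names = FALSE)
  meta <- list(stim_center = dataset$stim_center,
               diameters = as.list(dataset$diameters),
               baseline = dataset$baseline,
               platform = dataset$platform,
               dims = d)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording dataset written by [write_dataset()]
#'
#' @param dir directory holding `counts.csv`, `rf.csv`, `meta.json`.
#' @return A `recording_dataset`.
#' @export
read_dataset <- function(dir) {
  long <- utils::read.csv(file.path(dir, "counts.csv"))
  rf <- utils::read.csv(file.path(dir, "rf.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  counts <- array(0L, d, dimnames = list(NULL, NULL, c("small", "large"), NULL))
  sz <- match(long$size, c("small", "large"))
  counts[cbind(long$neuron, long$image, sz, long$trial)] <- long$count
  out <- list(counts = counts, rf = rf,
              stim_center = as.numeric(meta$stim_center),
              diameters = unlist(meta$diameters),
              baseline = as.data.frame(meta$baseline),
              platform = meta$platform, config = NULL)
  class(out) <- "recording_dataset"
  out
}

#' Save and load run configurations as YAML
#'
#' Round-trips nested lists of scalars and vectors exactly
#' (`load_run_config(save_run_config(x, p))` equals `x`).
#'
#' @param config a named list of stage parameters.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration files require the `yaml` package")
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration files require the `yaml` package")
  yaml::read_yaml(path)
}

#' Hash an R object for provenance stamps
#'
#' MD5 of the canonical JSON serialization.
#'
#' @param obj any jsonlite-serializable object.
#' @export
config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Every analysis stage stamps its output directory with the
#' configuration, its hash, the seed, and package/R versions, so any
#' artifact can be traced to what produced it.
#'
#' @param dir output directory.
#' @param config the effective stage configuration (a list).
#' @param seed the seed used.
#' @export
write_manifest <- function(dir, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = config,
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("pairgsm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
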