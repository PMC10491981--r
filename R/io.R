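# Cube, stack, dictionary and configuration I/O.
#
# Cubes are exchanged as ENVI header + raw pairs (float32, band-sequential)
# or as multi-page TIFF with a JSON wavelength sidecar. Compressed stacks
# are stored as multi-page float TIFF plus a JSON sidecar carrying the
# state times and the sensing-matrix hash. All writers embed provenance
# metadata (tool version, seed where applicable).

pkg_version <- function() as.character(utils::packageVersion("muxspec"))

strip_ext <- function(path) sub("\\.(hdr|raw|tif|tiff|json|csv)$", "", path)

#' Write a hyperspectral cube
#'
#' `format = "envi"` writes `<base>.hdr` (text header with the wavelength
#' grid) plus `<base>.raw` (float32, band-sequential interleave, little
#' endian); labels, when present, go to `<base>.labels.csv`.
#' `format = "tiff"` writes a multi-page float TIFF `<base>.tif` plus a
#' JSON sidecar `<base>.json` with the axis. Data are stored as float32 in
#' both formats, so a write/read round trip is exact for float32-valued
#' cubes.
#'
#' @param cube a [HyperspectralCube-class].
#' @param path output path; extensions are stripped and re-added.
#' @param format `"envi"` (default) or `"tiff"`.
#' @return base path, invisibly.
#' @export
writeCube <- function(cube, path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  base <- strip_ext(path)
  d <- dim(cube@data)
  lam <- wavelengths(cube@axis)
  if (format == "envi") {
    hdr <- c("ENVI",
             "description = {muxspec hyperspectral cube}",
             sprintf("samples = %d", d[2]),
             sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             "interleave = bsq",
             "byte order = 0",
             "wavelength units = nm",
             sprintf("wavelength = {%s}",
                     paste(sprintf("%.17g", lam),
                           collapse = ", ")),
             sprintf("; axis = %.17g %.17g %d", cube@axis@start_nm,
                     cube@axis@stop_nm, cube@axis@n_bands),
             sprintf("; muxspec version = %s", pkg_version()))
    writeLines(hdr, paste0(base, ".hdr"))
    con <- file(paste0(base, ".raw"), "wb")
    on.exit(close(con), add = TRUE)
    for (b in seq_len(d[3]))
      writeBin(as.numeric(t(cube@data[, , b])), con, size = 4,
               endian = "little")
  } else {
    pages <- lapply(seq_len(d[3]), function(b) cube@data[, , b])
    tiff::writeTIFF(pages, paste0(base, ".tif"), bits.per.sample = 32,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(
      list(start_nm = cube@axis@start_nm, stop_nm = cube@axis@stop_nm,
           n_bands = cube@axis@n_bands, rows = d[1], cols = d[2],
           muxspec_version = pkg_version()),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cube@labels))
    utils::write.csv(cube@labels, paste0(base, ".labels.csv"),
                     row.names = FALSE)
  invisible(base)
}

parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s *= *[^\n{]+", key), txt))
    if (!length(m)) stop(sprintf("missing ENVI header field '%s'", key))
    trimws(sub(".*=", "", m))
  }
  getblock <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s *= *\\{[^}]*\\}", key), txt))
    if (!length(m)) return(NULL)
    as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  }
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       data_type = as.integer(get1("data type")),
       interleave = tolower(get1("interleave")),
       wavelength = getblock("wavelength"))
}

#' Read a hyperspectral cube
#'
#' Accepts the two dialects written by [writeCube()]. For ENVI input the
#' path may point at the `.hdr` or the base name; a missing wavelength
#' block or sidecar is an explicit error naming the missing field.
#'
#' @param path base path, `.hdr` or `.tif` path.
#' @param format `"envi"` or `"tiff"`; inferred from the files present
#'   when omitted.
#' @return a [HyperspectralCube-class] (with labels when a labels CSV is
#'   found next to the cube).
#' @export
readCube <- function(path, format = NULL) {
  base <- strip_ext(path)
  if (is.null(format))
    format <- if (file.exists(paste0(base, ".hdr"))) "envi" else "tiff"
  if (format == "envi") {
    hdr_path <- paste0(base, ".hdr")
    if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
    h <- parse_envi_header(readLines(hdr_path))
    if (is.null(h$wavelength))
      stop("ENVI header is missing the 'wavelength' block")
    if (h$data_type != 4) stop("only float32 (data type 4) cubes are supported")
    if (h$interleave != "bsq") stop("only bsq interleave is supported")
    n <- h$samples * h$lines * h$bands
    raw <- readBin(paste0(base, ".raw"), what = numeric(), n = n, size = 4,
                   endian = "little")
    if (length(raw) != n) stop("raw file size does not match the header")
    data <- array(0, dim = c(h$lines, h$samples, h$bands))
    per <- h$samples * h$lines
    for (b in seq_len(h$bands))
      data[, , b] <- t(matrix(raw[((b - 1) * per + 1):(b * per)],
                              nrow = h$samples))
    lam <- h$wavelength
    spacing <- if (length(lam) > 1) lam[2] - lam[1] else 1
    axis <- SpectralAxis(lam[1] - spacing / 2,
                         lam[length(lam)] + spacing / 2, h$bands)
  } else {
    side <- paste0(base, ".json")
    if (!file.exists(side))
      stop("wavelength sidecar not found: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (field in c("start_nm", "stop_nm", "n_bands"))
      if (is.null(meta[[field]]))
        stop(sprintf("sidecar is missing the '%s' field", field))
    pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
    if (length(pages) != meta$n_bands)
      stop("sidecar n_bands does not match the TIFF page count")
    data <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (b in seq_along(pages)) data[, , b] <- pages[[b]]
    axis <- SpectralAxis(meta$start_nm, meta$stop_nm, meta$n_bands)
  }
  labels <- NULL
  lab_path <- paste0(base, ".labels.csv")
  if (file.exists(lab_path)) {
    labels <- as.matrix(utils::read.csv(lab_path, check.names = FALSE,
                                        colClasses = "character"))
    dimnames(labels) <- NULL
  }
  new("HyperspectralCube", data = data, axis = axis, labels = labels)
}

#' Write a compressed measurement stack
#'
#' Multi-page float TIFF (frames scaled into `[0, 1]`) plus a JSON sidecar
#' with the scale factor, state times, sensing-matrix hash and noise
#' metadata.
#'
#' @param stack a [CompressedStack-class].
#' @param path output base path.
#' @return base path, invisibly.
#' @export
writeStack <- function(stack, path) {
  base <- strip_ext(path)
  d <- dim(stack@frames)
  scale <- max(stack@frames, 1e-300)
  lo <- min(stack@frames, 0)
  pages <- lapply(seq_len(d[3]), function(b)
    (stack@frames[, , b] - lo) / (scale - lo))
  tiff::writeTIFF(pages, paste0(base, ".tif"), bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, offset = lo, state_times = stack@state_times,
         matrix_id = stack@matrix_id, noise = stack@noise_meta,
         muxspec_version = pkg_version()),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read a compressed measurement stack
#'
#' @param path base path written by [writeStack()].
#' @return a [CompressedStack-class].
#' @export
readStack <- function(path) {
  base <- strip_ext(path)
  side <- paste0(base, ".json")
  if (!file.exists(side)) stop("stack sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$state_times)) stop("sidecar is missing 'state_times'")
  pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
  if (length(pages) != length(meta$state_times))
    stop("state_times length does not match the TIFF page count")
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (b in seq_along(pages))
    frames[, , b] <- pages[[b]] * (meta$scale - meta$offset) + meta$offset
  noise <- if (is.null(meta$noise)) list(model = "unknown") else as.list(meta$noise)
  new("CompressedStack", frames = frames,
      state_times = as.numeric(meta$state_times),
      matrix_id = as.character(meta$matrix_id %||% ""), noise_meta = noise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a dictionary
#'
#' Atoms as a CSV matrix (one column per atom, 17 significant digits for a
#' bit-exact round trip) plus a JSON metadata sidecar with the axis and
#' training provenance.
#'
#' @param dict a [DictionaryModel-class].
#' @param path output base path.
#' @return base path, invisibly.
#' @export
writeDictionary <- function(dict, path) {
  base <- strip_ext(path)
  fmt <- function(x) sprintf("%.17g", x)
  rows <- apply(dict@atoms, 1, function(r) paste(fmt(r), collapse = ","))
  writeLines(rows, paste0(base, ".csv"))
  jsonlite::write_json(
    list(start_nm = dict@axis@start_nm, stop_nm = dict@axis@stop_nm,
         n_bands = dict@axis@n_bands,
         training_meta = dict@training_meta,
         muxspec_version = pkg_version()),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Load a persisted dictionary
#'
#' @param path base path written by [writeDictionary()].
#' @return a [DictionaryModel-class].
#' @export
readDictionary <- function(path) {
  base <- strip_ext(path)
  side <- paste0(base, ".json")
  if (!file.exists(side)) stop("dictionary metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  atoms <- as.matrix(utils::read.csv(paste0(base, ".csv"), header = FALSE))
  dimnames(atoms) <- NULL
  axis <- SpectralAxis(meta$start_nm, meta$stop_nm, meta$n_bands)
  tm <- if (is.null(meta$training_meta)) list() else as.list(meta$training_meta)
  new("DictionaryModel", atoms = atoms, axis = axis, training_meta = tm)
}

## ---- run configuration ------------------------------------------------

#' Default pipeline configuration
#'
#' All knobs of the end-to-end simulation in one list: modulator geometry
#' and dynamics, spectral axis, number of states, noise, solver settings,
#' dictionary training parameters and seeds. Values mirror the default
#' instrument (50 + 25 um E7 cells, polarizer factor 0.5, 47 states over a
#' 1 s window, 250 bands over 450--700 nm).
#'
#' @return a named list accepted by [runPipeline()].
#' @export
defaultRunConfig <- function() {
  list(
    axis = list(start_nm = 450, stop_nm = 700, n_bands = 250),
    modulator = list(thickness_um = c(50, 25), polarizer_factor = 0.5,
                     cauchy = as.list(e7CauchyCoefficients())),
    relaxation = list(tau_s = 0.45, scale_on = 0.25, window_s = 1),
    m_states = 47,
    noise_sigma = 0,
    dictionary = list(n_training = 2000, p_atoms = NULL, sparsity = 1,
                      iterations = 30),
    solver = list(name = "twist", reg_lambda = 0.01, sparsity_k = 3,
                  max_iterations = 2000),
    filters = list(list(center_nm = 632.8, fwhm_nm = 1),
                   list(center_nm = 550, fwhm_nm = 10),
                   list(center_nm = 600, fwhm_nm = 10)),
    tissue = list(n_pixels_per_class = 20, noise_sigma = 0.002),
    seed = 1,
    out_dir = "muxspec-output"
  )
}

# Merge user config over defaults, recursively for nested lists.
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(user[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Fields omitted from the file keep their [defaultRunConfig()] values.
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- merge_config(defaultRunConfig(), yaml::read_yaml(path))
  stopifnot(cfg$m_states >= 1, cfg$axis$n_bands >= 2,
            cfg$axis$stop_nm > cfg$axis$start_nm,
            is.numeric(cfg$seed))
  cfg
}

config_axis <- function(cfg)
  SpectralAxis(cfg$axis$start_nm, cfg$axis$stop_nm, cfg$axis$n_bands)

config_modulator <- function(cfg) {
  cc <- unlist(cfg$modulator$cauchy)
  ModulatorStack(lapply(cfg$modulator$thickness_um,
                        function(d) LiquidCrystalCell(d, cc)),
                 polarizer_factor = cfg$modulator$polarizer_factor)
}

config_matrix <- function(cfg) {
  axis <- config_axis(cfg)
  if (cfg$m_states >= cfg$axis$n_bands)
    warning("non-compressive configuration (M >= N); continuing")
  suppressWarnings(buildSensingMatrix(
    config_modulator(cfg),
    generateStates(cfg$m_states, cfg$relaxation$window_s,
                   RelaxationModel(cfg$relaxation$tau_s,
                                   cfg$relaxation$scale_on)),
    axis))
}
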