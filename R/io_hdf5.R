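#' Cube file I/O (HDF5)
#'
#' Cubes are stored in a documented HDF5 layout: dataset `/counts` (the
#' 5-D integer array), group `/config` carrying the instrument
#' configuration as attributes, optional dataset `/irf` (per-epoch IRF
#' histograms), plus root attributes `pixel_size_nm`, `metadata` (JSON)
#' and `config_hash`. The round trip is lossless for counts, configuration
#' and metadata.
#'
#' @param cube an `sflim_cube`.
#' @param path file path.
#' @return `read_cube` returns an `sflim_cube`; `write_cube` returns the
#'   path invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "sflim_cube"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "counts", dims = dim(cube$counts),
                         storage.mode = "integer",
                         chunk = chunk_dims(dim(cube$counts)), level = 1L)
  counts <- cube$counts
  storage.mode(counts) <- "integer"
  rhdf5::h5write(counts, path, "counts")
  if (!is.null(cube$irf)) rhdf5::h5write(cube$irf$h, path, "irf")
  rhdf5::h5createGroup(path, "config")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  gid <- rhdf5::H5Gopen(fid, "config")
  on.exit(rhdf5::H5Gclose(gid), add = TRUE)
  cfg <- unclass(cube$config)
  for (nm in names(cfg))
    if (!is.null(cfg[[nm]]))
      rhdf5::h5writeAttribute(cfg[[nm]], gid, nm)
  rhdf5::h5writeAttribute(as.numeric(cube$pixel_size_nm), fid, "pixel_size_nm")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(cube$metadata, auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    fid, "metadata")
  rhdf5::h5writeAttribute(config_hash(cube$config), fid, "config_hash")
  invisible(path)
}

chunk_dims <- function(d) {
  c(min(d[1], 64L), min(d[2], 64L), d[3], d[4], d[5])
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path))
    stop_sflim(sprintf("no such file: %s", path), "sflim_io_error")
  ls <- rhdf5::h5ls(path)
  have <- paste0(sub("/$", "", ls$group), "/", ls$name)
  for (need in c("/counts", "/config"))
    if (!need %in% have)
      stop_sflim(sprintf("malformed cube file %s: missing %s", path, need),
                 "sflim_format_error")
  counts <- rhdf5::h5read(path, "counts")
  att <- rhdf5::h5readAttributes(path, "config")
  config <- sflim_config(
    rep_rate = as.numeric(att$rep_rate),
    excitation_wavelengths = as.numeric(att$excitation_wavelengths),
    epoch_offsets_ns = as.numeric(att$epoch_offsets_ns),
    spectral_min = as.numeric(att$spectral_min),
    spectral_max = as.numeric(att$spectral_max),
    n_spectral = as.integer(att$n_spectral),
    n_tcspc = as.integer(att$n_tcspc),
    irf_fwhm_ps = as.numeric(att$irf_fwhm_ps),
    notch = if (!is.null(att$notch)) as.numeric(att$notch) else NULL)
  root <- rhdf5::h5readAttributes(path, "/")
  irf <- if ("/irf" %in% have) new_irf(rhdf5::h5read(path, "irf"), config)
  meta <- if (!is.null(root$metadata))
    jsonlite::fromJSON(as.character(root$metadata)) else list()
  sflim_cube(counts, config,
             pixel_size_nm = as.numeric(root$pixel_size_nm %||% NA_real_),
             metadata = as.list(meta), irf = irf)
}

#' Reference pattern file I/O (HDF5)
#'
#' Patterns are stored as dataset `/p` (the 3-D probability array over
#' epoch x channel x bin) with attributes `label`, `config_hash` and a
#' JSON `meta` record.
#'
#' @param pattern an `sflim_pattern`.
#' @param path file path.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "sflim_pattern"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(pattern$p, path, "p")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(pattern$label, fid, "label")
  rhdf5::h5writeAttribute(pattern$config_hash, fid, "config_hash")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(pattern$meta, auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    fid, "meta")
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  if (!file.exists(path))
    stop_sflim(sprintf("no such file: %s", path), "sflim_io_error")
  ls <- rhdf5::h5ls(path)
  have <- paste0(sub("/$", "", ls$group), "/", ls$name)
  if (!"/p" %in% have)
    stop_sflim(sprintf("malformed pattern file %s: missing /p", path),
               "sflim_format_error")
  p <- rhdf5::h5read(path, "p")
  att <- rhdf5::h5readAttributes(path, "/")
  meta <- if (!is.null(att$meta)) as.list(jsonlite::fromJSON(att$meta))
          else list()
  structure(list(p = p, label = as.character(att$label %||% "pattern"),
                 config_hash = as.character(att$config_hash %||% NA),
                 meta = meta),
            class = "sflim_pattern")
}

#' FCS intensity trace file I/O (HDF5)
#'
#' Binned photon-count traces are stored as `/trace` (counts per bin) and
#' `/dt` (bin width in seconds), with simulation parameters as a JSON
#' `meta` attribute.
#'
#' @param trace an `fcs_trace` (see [simulate_fcs_photons()]).
#' @param path file path.
#' @export
write_fcs_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fcs_trace"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(as.integer(trace$counts), path, "trace")
  rhdf5::h5write(trace$dt_s, path, "dt")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(trace$params, auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    fid, "meta")
  invisible(path)
}

#' @rdname write_fcs_trace
#' @export
read_fcs_trace <- function(path) {
  if (!file.exists(path))
    stop_sflim(sprintf("no such file: %s", path), "sflim_io_error")
  ls <- rhdf5::h5ls(path)
  have <- paste0(sub("/$", "", ls$group), "/", ls$name)
  for (need in c("/trace", "/dt"))
    if (!need %in% have)
      stop_sflim(sprintf("malformed trace file %s: missing %s", path, need),
                 "sflim_format_error")
  att <- rhdf5::h5readAttributes(path, "/")
  params <- if (!is.null(att$meta)) as.list(jsonlite::fromJSON(att$meta))
            else list()
  structure(list(counts = as.integer(rhdf5::h5read(path, "trace")),
                 dt_s = as.numeric(rhdf5::h5read(path, "dt")),
                 params = params),
            class = "fcs_trace")
}
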