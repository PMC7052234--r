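#' sFLIM photon histogram cube
#'
#' The central measurement object: per-pixel photon counts over
#' (excitation epoch x spectral channel x TCSPC bin), stored as a 5-D
#' integer array `counts[row, col, epoch, channel, bin]` where `bin` is the
#' within-epoch TCSPC bin (bin 1 starts at the epoch's pulse offset, bins
#' are half-open). Pixel indexing is 1-based row-major.
#'
#' @param counts 5-D nonnegative integer array, dimensions
#'   `(rows, cols, n_epochs, n_spectral, bins_per_epoch)`.
#' @param config the generating `sflim_config`.
#' @param pixel_size_nm pixel pitch in nm.
#' @param metadata free-form provenance list.
#' @param irf optional `sflim_irf` carried with the cube.
#' @return an `sflim_cube`.
#' @export
sflim_cube <- function(counts, config, pixel_size_nm = NA_real_,
                       metadata = list(), irf = NULL) {
  stopifnot(inherits(config, "sflim_config"), is.array(counts),
            length(dim(counts)) == 5L)
  d <- dim(counts)
  want <- c(n_epochs(config), config$n_spectral, bins_per_epoch(config))
  if (!identical(as.integer(d[3:5]), as.integer(want)))
    stop_sflim(sprintf(
      "cube dimensions (%s) do not match config (epochs %d, channels %d, bins %d)",
      paste(d, collapse = "x"), want[1], want[2], want[3]),
      "sflim_dimension_error")
  if (min(counts) < 0)
    stop_sflim("counts must be nonnegative", "sflim_domain_error")
  structure(list(counts = counts, config = config,
                 pixel_size_nm = pixel_size_nm, metadata = metadata,
                 irf = irf),
            class = "sflim_cube")
}

#' @export
print.sflim_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "sFLIM cube: %d x %d pixels, %d epoch(s) x %d channels x %d bins, %s photons\n",
    d[1], d[2], d[3], d[4], d[5], format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname sflim_cube
#' @param cube an `sflim_cube`.
#' @export
cube_image_shape <- function(cube) dim(cube$counts)[1:2]

#' Total intensity image of a cube
#'
#' @param cube an `sflim_cube`.
#' @param epoch optional epoch restriction.
#' @return matrix of per-pixel total counts.
#' @export
cube_intensity <- function(cube, epoch = NULL) {
  x <- cube$counts
  if (!is.null(epoch)) x <- x[, , epoch, , , drop = FALSE]
  apply(x, c(1, 2), sum)
}

#' In-memory photon record stream
#'
#' A lightweight stand-in for time-tagged time-resolved photon records:
#' one row per detected photon with its pixel coordinates, micro time
#' within the sync period (ns) and spectral channel (1-based).
#'
#' @param pixel_row,pixel_col 1-based pixel indices.
#' @param micro_time_ns arrival time within the sync period, in
#'   `[0, period)`.
#' @param spectral_channel channel index in `1:n_spectral`.
#' @param config the `sflim_config` the stream refers to.
#' @return a `photon_stream` data frame.
#' @export
photon_stream <- function(pixel_row, pixel_col, micro_time_ns,
                          spectral_channel, config) {
  period <- sync_period_ns(config)
  stopifnot(all(micro_time_ns >= 0), all(micro_time_ns < period),
            all(spectral_channel >= 1L),
            all(spectral_channel <= config$n_spectral))
  structure(data.frame(pixel_row = as.integer(pixel_row),
                       pixel_col = as.integer(pixel_col),
                       micro_time_ns = as.numeric(micro_time_ns),
                       spectral_channel = as.integer(spectral_channel)),
            class = c("photon_stream", "data.frame"))
}

#' Histogram a photon stream into a cube
#'
#' Each photon is assigned to the excitation epoch whose
#' `[offset, next offset)` interval contains its micro time, to its
#' within-epoch TCSPC bin, and to its spectral channel. Photons outside
#' the image bounds are dropped (and counted); total counts in the cube
#' plus dropped records always equals the stream length.
#'
#' @param stream a `photon_stream`.
#' @param config an `sflim_config`.
#' @param image_shape integer `c(rows, cols)`.
#' @return an `sflim_cube` with `metadata$dropped_records` set.
#' @export
bin_photons <- function(stream, config, image_shape) {
  stopifnot(length(image_shape) == 2L)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  ne <- n_epochs(config); ns <- config$n_spectral; nb <- bins_per_epoch(config)
  counts <- array(0L, dim = c(nr, nc, ne, ns, nb))
  dropped <- 0L
  if (nrow(stream) > 0) {
    ok <- stream$pixel_row >= 1L & stream$pixel_row <= nr &
      stream$pixel_col >= 1L & stream$pixel_col <= nc
    dropped <- sum(!ok)
    s <- stream[ok, , drop = FALSE]
    if (nrow(s) > 0) {
      epoch <- epoch_of_micro_time(s$micro_time_ns, config)
      dt <- tcspc_bin_width_ns(config)
      rel <- s$micro_time_ns - config$epoch_offsets_ns[epoch]
      bin <- pmin(floor(rel / dt), nb - 1L) + 1L
      idx <- s$pixel_row +
        nr * (s$pixel_col - 1L) +
        nr * nc * (epoch - 1L) +
        nr * nc * ne * (s$spectral_channel - 1L) +
        nr * nc * ne * ns * (bin - 1L)
      tab <- tabulate(idx, nbins = length(counts))
      counts <- array(as.integer(tab), dim = dim(counts))
    }
  }
  sflim_cube(counts, config,
             metadata = list(dropped_records = dropped))
}

#' Emulated bandpass channel-mode images
#'
#' Reproduces conventional filter-based channel-mode imaging on an sFLIM
#' cube: for each (bandpass filter, excitation epoch) combination, spectral
#' channels are weighted by the fractional overlap of their interval with
#' the filter passband, counts are summed over the assigned epoch and over
#' all TCSPC bins. A filter is given as center/full-width in nm (e.g.
#' `c(520, 35)` for a 520/35 filter).
#'
#' @param cube an `sflim_cube`.
#' @param filters list of `c(center_nm, full_width_nm)` passbands.
#' @param epochs integer vector: excitation epoch assigned to each filter.
#' @return list of intensity matrices, one per filter, named
#'   `"<center>/<width>@<laser>nm"`.
#' @export
#' @examples
#' # the three analysis channels of a two-laser triple-antigen experiment
#' # Ch1: 485 nm excitation, 520/35 detection; Ch2: 485 nm, 593/20;
#' # Ch3: 561 nm, 593/20
#' \dontrun{
#' imgs <- bandpass_channel_images(cube,
#'   filters = list(c(520, 35), c(593, 20), c(593, 20)),
#'   epochs = c(1, 1, 2))
#' }
bandpass_channel_images <- function(cube, filters, epochs) {
  stopifnot(inherits(cube, "sflim_cube"), length(filters) == length(epochs))
  config <- cube$config
  edges <- spectral_channel_edges(config)
  out <- vector("list", length(filters))
  nm <- character(length(filters))
  for (i in seq_along(filters)) {
    f <- filters[[i]]
    stopifnot(length(f) == 2L, f[2] > 0)
    lo <- f[1] - f[2] / 2
    hi <- f[1] + f[2] / 2
    ## fractional overlap of each channel interval with the passband
    ov <- pmax(0, pmin(edges[-1], hi) - pmax(edges[-length(edges)], lo)) /
      diff(edges)
    if (all(ov == 0))
      warning(sprintf("filter %g/%g nm has no overlap with the detection range",
                      f[1], f[2]))
    e <- epochs[i]
    slab <- cube$counts[, , e, , , drop = FALSE]
    chan <- apply(slab, c(1, 2, 4), sum)  # rows x cols x channels
    d <- dim(chan)
    img <- matrix(matrix(chan, d[1] * d[2], d[3]) %*% ov, d[1], d[2])
    out[[i]] <- img
    nm[i] <- sprintf("%g/%g@%gnm", f[1], f[2],
                     config$excitation_wavelengths[e])
  }
  names(out) <- nm
  out
}

#' Flatten a cube to a pixel-by-bin count matrix
#'
#' Rows are pixels in column-major order (row index fastest, matching
#' R's array layout); columns are the flattened (epoch, channel, bin)
#' histogram, optionally TCSPC-rebinned by an integer factor (adjacent
#' bins summed). Reference patterns flatten identically, so the two can be
#' used together in the unmixing solver.
#'
#' @param cube an `sflim_cube`.
#' @param rebin integer TCSPC rebin factor (must divide
#'   `bins_per_epoch`).
#' @return numeric matrix `n_pixels x (n_epochs * n_spectral * bins/rebin)`.
#' @export
cube_pixel_matrix <- function(cube, rebin = 1L) {
  d <- dim(cube$counts)
  m <- matrix(as.numeric(cube$counts), d[1] * d[2], d[3] * d[4] * d[5])
  if (rebin != 1L) {
    ## flattened column order is (epoch, channel, bin) with epoch fastest:
    ## rebinning groups of the *last* (slowest) axis needs a reshape
    nb <- d[5]
    a <- array(m, dim = c(nrow(m) * d[3] * d[4], nb))
    a <- rebin_columns(a, rebin)
    m <- matrix(a, nrow(m), d[3] * d[4] * (nb %/% rebin))
  }
  m
}

## Flatten a pattern array (epoch, channel, bin) the same way.
pattern_vector <- function(pattern, rebin = 1L) {
  p <- pattern$p
  d <- dim(p)
  v <- as.numeric(p)
  if (rebin != 1L) {
    a <- matrix(v, d[1] * d[2], d[3])
    v <- as.numeric(rebin_columns(a, rebin))
  }
  v
}

#' Export intensity or contribution images as multi-page TIFF
#'
#' Writes a list of numeric matrices as one 32-bit float TIFF page each.
#' TIFF float samples are stored in \eqn{[0, 1]}, so all pages are divided
#' by a common scale (the global maximum); the scale is returned so
#' callers can record it alongside the file.
#'
#' @param images matrix or list of matrices.
#' @param path output file.
#' @return the intensity scale (counts per unit TIFF value), invisibly.
#' @export
write_images_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  scale <- max(1e-300, vapply(images, max, numeric(1)))
  if (scale <= 1) scale <- 1
  pages <- lapply(images, function(m) {
    m <- pmax(m, 0) / scale
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}
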