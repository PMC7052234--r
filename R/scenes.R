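#' Synthetic organelle-like structure maps
#'
#' Generates nonnegative label-density images emulating the morphologies
#' seen in immunofluorescence: `puncta` (mitochondria-like spots),
#' `filaments` (cytokeratin-like curvilinear networks) and `blobs`
#' (Golgi-like extended patches). Maps are deterministic given the seed
#' and scaled to `[0, 1]`.
#'
#' @param kind one of `"puncta"`, `"filaments"`, `"blobs"`.
#' @param shape integer `c(rows, cols)`.
#' @param params kind-specific parameters: puncta — `count`, `radius`
#'   (px); filaments — `count`, `thickness` (px), `curvature` (radians
#'   per step of direction noise), `length` (px); blobs — `count`, `ax`,
#'   `ay` (Gaussian semi-axes, px).
#' @param seed integer seed.
#' @return matrix in `[0, 1]`.
#' @export
structure_map <- function(kind, shape, params = list(), seed = 1L) {
  stopifnot(length(shape) == 2L)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  img <- matrix(0, nr, nc)
  count <- as.integer(params$count %||% 10L)
  if (count == 0L) return(img)
  img <- with_seed(seed, switch(
    kind,
    puncta = {
      r <- params$radius %||% 2
      for (i in seq_len(count)) {
        img <- stamp_gaussian(img, stats::runif(1, 1, nr),
                              stats::runif(1, 1, nc), r, r, 1)
      }
      img
    },
    blobs = {
      ax <- params$ax %||% 4
      ay <- params$ay %||% 6
      for (i in seq_len(count)) {
        img <- stamp_gaussian(img, stats::runif(1, 1, nr),
                              stats::runif(1, 1, nc),
                              stats::runif(1, 0.7, 1.3) * ax,
                              stats::runif(1, 0.7, 1.3) * ay, 1)
      }
      img
    },
    filaments = {
      thick <- params$thickness %||% 2
      curv <- params$curvature %||% 0.15
      len <- params$length %||% (1.5 * max(nr, nc))
      step <- 0.5
      for (i in seq_len(count)) {
        y <- stats::runif(1, 1, nr); x <- stats::runif(1, 1, nc)
        th <- stats::runif(1, 0, 2 * pi)
        nstep <- ceiling(len / step)
        for (s in seq_len(nstep)) {
          th <- th + stats::rnorm(1, 0, curv)
          y <- y + step * sin(th); x <- x + step * cos(th)
          if (y < 1 || y > nr || x < 1 || x > nc) break
          img <- stamp_disk(img, y, x, thick / 2)
        }
      }
      img
    },
    stop_sflim(sprintf("unknown structure kind '%s'", kind),
               "sflim_domain_error")
  ))
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

## Add a Gaussian bump at (y0, x0); truncated at 3 sigma for speed.
stamp_gaussian <- function(img, y0, x0, sy, sx, amp) {
  nr <- nrow(img); nc <- ncol(img)
  ys <- max(1L, floor(y0 - 3 * sy)):min(nr, ceiling(y0 + 3 * sy))
  xs <- max(1L, floor(x0 - 3 * sx)):min(nc, ceiling(x0 + 3 * sx))
  if (length(ys) == 0L || length(xs) == 0L) return(img)
  g <- amp * outer(exp(-(ys - y0)^2 / (2 * sy^2)),
                   exp(-(xs - x0)^2 / (2 * sx^2)))
  img[ys, xs] <- pmax(img[ys, xs], g)
  img
}

## Mark a hard disk of radius r at (y0, x0) with value 1.
stamp_disk <- function(img, y0, x0, r) {
  nr <- nrow(img); nc <- ncol(img)
  ys <- max(1L, floor(y0 - r)):min(nr, ceiling(y0 + r))
  xs <- max(1L, floor(x0 - r)):min(nc, ceiling(x0 + r))
  d2 <- outer((ys - y0)^2, (xs - x0)^2, `+`)
  img[ys, xs][d2 <= max(r, 0.75)^2] <- 1
  img
}

#' Scene specification
#'
#' Describes a synthetic field of view: image shape, pixel pitch, a list
#' of labelled structures (each a structure kind with parameters plus a
#' `fluorophore` or `fret_pair` label), a uniform background rate and the
#' master seed that fully determines the scene.
#'
#' @param shape integer `c(rows, cols)`.
#' @param structures list of `list(kind =, params =, label =)` entries;
#'   label names must be unique.
#' @param pixel_size_nm pixel pitch in nm.
#' @param background expected background counts per pixel per unit
#'   exposure (spread uniformly over all histogram bins).
#' @param seed master seed.
#' @return an `sflim_scene`.
#' @export
scene_spec <- function(shape, structures, pixel_size_nm = 78,
                       background = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, is.list(structures),
            length(structures) >= 1L, background >= 0)
  labs <- vapply(structures, function(s) s$label$name, character(1))
  if (anyDuplicated(labs))
    stop_sflim("structure label names must be unique", "sflim_domain_error")
  structure(list(shape = as.integer(shape), structures = structures,
                 pixel_size_nm = pixel_size_nm, background = background,
                 seed = as.integer(seed)),
            class = "sflim_scene")
}

#' @export
print.sflim_scene <- function(x, ...) {
  cat(sprintf("sFLIM scene: %d x %d px, %d structure(s), background %g, seed %d\n",
              x$shape[1], x$shape[2], length(x$structures), x$background,
              x$seed))
  for (s in x$structures)
    cat(sprintf("  - %s labelled '%s'\n", s$kind, s$label$name))
  invisible(x)
}

#' Per-label density maps of a scene
#'
#' @param scene an `sflim_scene`.
#' @return named list of `[0, 1]` density matrices, one per structure.
#' @export
scene_densities <- function(scene) {
  seeds <- derive_seeds(scene$seed, length(scene$structures))
  out <- lapply(seq_along(scene$structures), function(i) {
    s <- scene$structures[[i]]
    structure_map(s$kind, scene$shape, s$params, seed = seeds[i])
  })
  names(out) <- vapply(scene$structures, function(s) s$label$name,
                       character(1))
  out
}

#' Simulate an sFLIM measurement of a scene
#'
#' The forward model: per pixel and label, expected photons
#' \eqn{\lambda = \mathrm{density} \times \mathrm{brightness} \times
#' \mathrm{exposure}} are distributed over the (epoch x channel x bin)
#' histogram according to the label's exact reference pattern; observed
#' counts are Poisson with a uniform background added over all bins. The
#' result is deterministic given the seed.
#'
#' @param scene an `sflim_scene`.
#' @param config an `sflim_config`.
#' @param irf an `sflim_irf`.
#' @param exposure exposure scale (photons per unit brightness per unit
#'   density); must be >= 0.
#' @param seed integer seed (defaults to the scene seed).
#' @return list with elements `cube` (an `sflim_cube`) and `truth` (an
#'   `sflim_ground_truth`: per-label `density` maps, `expected`
#'   photon-contribution maps, exact `patterns`, and the `exposure`).
#' @export
simulate_cube <- function(scene, config, irf = gaussian_irf(config),
                          exposure = 1, seed = scene$seed) {
  stopifnot(inherits(scene, "sflim_scene"), inherits(config, "sflim_config"))
  if (exposure < 0)
    stop_sflim("exposure must be nonnegative", "sflim_domain_error")
  nr <- scene$shape[1]; nc <- scene$shape[2]
  npix <- nr * nc
  ne <- n_epochs(config); ns <- config$n_spectral; nb <- bins_per_epoch(config)
  K <- ne * ns * nb
  dens <- scene_densities(scene)
  labels <- lapply(scene$structures, `[[`, "label")
  names(labels) <- names(dens)
  patterns <- lapply(labels, ground_truth_pattern, config = config, irf = irf)
  bright <- vapply(labels, label_brightness, numeric(1), config = config)
  expected <- mapply(function(d, b) d * b * exposure, dens, bright,
                     SIMPLIFY = FALSE)
  counts_flat <- integer(npix * K)
  sim_seeds <- derive_seeds(seed, length(labels) + 1L)
  for (i in seq_along(labels)) {
    lambda <- as.numeric(expected[[i]])
    p <- pattern_vector(patterns[[i]])
    counts_flat <- counts_flat + with_seed(sim_seeds[i], {
      n_i <- rpois(npix, lambda)
      tot <- sum(n_i)
      if (tot == 0) integer(npix * K) else {
        px <- rep.int(which(n_i > 0L), n_i[n_i > 0L])
        bins <- sample.int(K, tot, replace = TRUE, prob = p)
        tabulate(px + npix * (bins - 1), nbins = npix * K)
      }
    })
  }
  if (scene$background > 0 && exposure > 0) {
    counts_flat <- counts_flat + with_seed(sim_seeds[length(sim_seeds)], {
      tot <- rpois(1, npix * scene$background * exposure)
      if (tot == 0) integer(npix * K)
      else tabulate(sample.int(npix * K, tot, replace = TRUE),
                    nbins = npix * K)
    })
  }
  cube <- sflim_cube(array(counts_flat, dim = c(nr, nc, ne, ns, nb)),
                     config, pixel_size_nm = scene$pixel_size_nm,
                     metadata = list(scene_seed = scene$seed,
                                     sim_seed = seed, exposure = exposure),
                     irf = irf)
  truth <- structure(list(density = dens, expected = expected,
                          patterns = patterns, brightness = bright,
                          exposure = exposure),
                     class = "sflim_ground_truth")
  list(cube = cube, truth = truth)
}

#' Pure-structure pixel masks from ground truth
#'
#' Pixels where one label's density exceeds `min_density` and every other
#' label's density is below `max_other` — the regions used for reference
#' pattern extraction and for the residual-crosstalk (bleed-through)
#' evaluation.
#'
#' @param truth an `sflim_ground_truth`.
#' @param min_density minimum density of the target label.
#' @param max_other maximum tolerated density of any other label.
#' @return named list of logical matrices.
#' @export
pure_masks <- function(truth, min_density = 0.5, max_other = 0) {
  dens <- truth$density
  lapply(seq_along(dens), function(i) {
    m <- dens[[i]] >= min_density
    for (j in seq_along(dens)[-i]) m <- m & (dens[[j]] <= max_other)
    m
  }) |> stats::setNames(names(dens))
}
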