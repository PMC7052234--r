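#' Demonstration scenes: dual- and triple-antigen cross-labelling
#'
#' Ready-made scene specifications mirroring the package's two flagship
#' scenarios. `scene_dual_antigen()` holds a punctate mitochondria-like
#' structure carrying a single Alexa488-like label plus a filamentous
#' cytokeratin-like structure carrying a FRET antibody pair
#' (Alexa488-like donor cross-labelled with an Alexa555-like acceptor).
#' `scene_triple_antigen()` adds a Golgi-like structure with a single
#' Alexa546-like label, so three antigens are encoded by two fluorophores:
#' two single labels plus one FRET cross-label. The default FRET
#' efficiency 0.171875 quenches a 3.84 ns donor to 3.18 ns.
#'
#' @param shape image shape in pixels.
#' @param seed master scene seed.
#' @param efficiency FRET efficiency on the cross-labelled structure.
#' @param sensitized_fraction detected share of transferred excitations.
#' @param background expected background counts per pixel per unit
#'   exposure.
#' @return an `sflim_scene`.
#' @export
scene_dual_antigen <- function(shape = c(128L, 128L), seed = 1L,
                               efficiency = 0.171875,
                               sensitized_fraction = 0.5,
                               background = 0.005) {
  donor <- fluorophore_preset("alexa488")
  acceptor <- fluorophore_preset("alexa555")
  scene_spec(
    shape = shape,
    structures = list(
      list(kind = "puncta",
           params = list(count = 90L, radius = 1.8),
           label = fluorophore("tom20_a488", 519, 14, decay = 3.84,
                               excitation = c(1.0, 0.02))),
      list(kind = "filaments",
           params = list(count = 7L, thickness = 2, curvature = 0.12),
           label = fret_pair(donor, acceptor, efficiency,
                             sensitized_fraction,
                             name = "cytokeratin_fret"))),
    background = background, seed = seed)
}

#' @rdname scene_dual_antigen
#' @export
scene_triple_antigen <- function(shape = c(128L, 128L), seed = 1L,
                                 efficiency = 0.171875,
                                 sensitized_fraction = 0.5,
                                 background = 0.005) {
  donor <- fluorophore_preset("alexa488")
  acceptor <- fluorophore_preset("alexa546")
  scene_spec(
    shape = shape,
    structures = list(
      list(kind = "puncta",
           params = list(count = 90L, radius = 1.8),
           label = fluorophore("tom20_a488", 519, 14, decay = 3.84,
                               excitation = c(1.0, 0.02))),
      list(kind = "filaments",
           params = list(count = 7L, thickness = 2, curvature = 0.12),
           label = fret_pair(donor, acceptor, efficiency,
                             sensitized_fraction,
                             name = "cytokeratin_fret")),
      list(kind = "blobs",
           params = list(count = 14L, ax = 3, ay = 6),
           label = fluorophore("golgin_a546", 573, 16, decay = 4.0,
                               excitation = c(0.10, 0.90)))),
    background = background, seed = seed)
}

#' Single-label control scene
#'
#' A control sample carrying only one labelled structure, as used to
#' extract reference patterns for singly labelled antigens and to evaluate
#' their bleed-through rows.
#'
#' @param label a `fluorophore` or `fret_pair`.
#' @param kind structure kind.
#' @param params structure parameters.
#' @param shape image shape.
#' @param seed scene seed.
#' @param background background rate.
#' @return an `sflim_scene`.
#' @export
scene_single_label <- function(label, kind = "blobs",
                               params = list(count = 25L, ax = 4, ay = 6),
                               shape = c(64L, 64L), seed = 1L,
                               background = 0.005) {
  scene_spec(shape = shape,
             structures = list(list(kind = kind, params = params,
                                    label = label)),
             background = background, seed = seed)
}

#' Read a scene specification from YAML
#'
#' Scene files carry `shape`, optional `pixel_size_nm`, `background` and
#' `seed`, and a `structures` list whose entries have `kind`, `params` and
#' a `label` block. A label block is either
#' `{type: fluorophore, preset: alexa488}` (optionally with `name` and
#' `brightness`), a full fluorophore spec
#' (`name`, `emission_center_nm`, `emission_sigma_nm`, `decay`
#' (`tau_ns`, optional `fraction`), `excitation`, `brightness`), or
#' `{type: fret_pair, donor: <block>, acceptor: <block>, efficiency: E,
#' sensitized_fraction: s}`. Two examples ship in
#' `system.file("extdata", package = "sflimfret")`.
#'
#' @param path YAML file.
#' @return an `sflim_scene`.
#' @export
scene_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("shape", "structures"))
    if (is.null(y[[field]]))
      stop_sflim(sprintf("scene spec %s: missing required field '%s'",
                         path, field), "sflim_schema_error")
  structures <- lapply(y$structures, function(s) {
    for (field in c("kind", "label"))
      if (is.null(s[[field]]))
        stop_sflim(sprintf("scene spec %s: structure missing field '%s'",
                           path, field), "sflim_schema_error")
    list(kind = s$kind, params = s$params %||% list(),
         label = label_from_spec(s$label))
  })
  scene_spec(shape = as.integer(y$shape), structures = structures,
             pixel_size_nm = y$pixel_size_nm %||% 78,
             background = y$background %||% 0,
             seed = y$seed %||% 1L)
}

label_from_spec <- function(l) {
  type <- l$type %||% "fluorophore"
  if (type == "fret_pair") {
    if (is.null(l$donor) || is.null(l$acceptor) || is.null(l$efficiency))
      stop_sflim("fret_pair label requires 'donor', 'acceptor', 'efficiency'",
                 "sflim_schema_error")
    return(fret_pair(label_from_spec(l$donor), label_from_spec(l$acceptor),
                     efficiency = l$efficiency,
                     sensitized_fraction = l$sensitized_fraction %||% 0.5,
                     name = l$name))
  }
  if (!is.null(l$preset)) {
    fl <- fluorophore_preset(l$preset, brightness = l$brightness %||% 1)
    if (!is.null(l$name)) fl$name <- l$name
    return(fl)
  }
  for (field in c("name", "emission_center_nm", "emission_sigma_nm",
                  "decay", "excitation"))
    if (is.null(l[[field]]))
      stop_sflim(sprintf("fluorophore label missing field '%s'", field),
                 "sflim_schema_error")
  decay <- if (is.list(l$decay) && !is.null(l$decay$tau_ns))
    data.frame(fraction = l$decay$fraction %||%
                 rep(1 / length(l$decay$tau_ns), length(l$decay$tau_ns)),
               tau_ns = l$decay$tau_ns)
  else unlist(l$decay)
  fluorophore(l$name, l$emission_center_nm, l$emission_sigma_nm,
              decay = decay, excitation = unlist(l$excitation),
              brightness = l$brightness %||% 1)
}
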