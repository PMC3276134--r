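#' Simulate the three-archetype benchmark screen
#'
#' A self-contained parameter-recovery experiment: a solid-design screen of
#' `3 * genotypes_per_class` genotypes, one third per archetype preset
#' (normal / no_recovery / fast_recovery, see [preset_classes()]), with the
#' archetype genotypes themselves named `his3`, `rad52` and `rif1` so the
#' default [archetype_config()] applies. Query genotypes get `replicates`
#' cultures each; the `his3` control keeps the solid design's
#' `control_replicates` (default 144), which also stabilises the normal
#' archetype's MDP.
#'
#' @param seed integer seed.
#' @param genotypes_per_class genotypes per archetype class (default 40).
#' @param replicates replicate cultures per query genotype (default 8).
#' @param control_replicates replicates of the `his3` control (default 144).
#' @param noise a [noise_model()].
#' @return As [simulate_screen()]: list with `dataset` (raw scale) and
#'   `truth`.
#' @export
simulate_benchmark_screen <- function(seed, genotypes_per_class = 40L,
                                      replicates = 8L,
                                      control_replicates = 144L,
                                      noise = noise_model()) {
  k <- as.integer(genotypes_per_class)
  stopifnot(k >= 1L)
  presets <- preset_classes()
  gen <- c("his3", if (k > 1L) sprintf("norm%02d", 2:k),
           "rad52", if (k > 1L) sprintf("norec%02d", 2:k),
           "rif1", if (k > 1L) sprintf("fast%02d", 2:k))
  class_map <- c(rep(list(presets$normal), k),
                 rep(list(presets$no_recovery), k),
                 rep(list(presets$fast_recovery), k))
  names(class_map) <- gen
  config <- sim_config(seed, class_map, design = "solid")
  layouts <- build_solid_layout(gen, control_label = "his3",
                                default_replicates = replicates,
                                control_replicates = control_replicates)
  simulate_screen(layouts, config, noise)
}

#' Simulate the 23-variant clustering benchmark
#'
#' A solid-design screen planting the 23 well-separated trajectory variants
#' of [qt_demo_classes()], `genotypes_per_variant` genotypes per variant and
#' `replicates` cultures per genotype (24 by default, the focused replicate
#' count the solid design uses for genotypes of special interest). With the
#' RMS profile distance and a diameter threshold of 450 transformed units —
#' midway between the within-variant noise scatter and the designed
#' between-variant spacing — QT clustering recovers the 23 planted classes.
#'
#' @param seed integer seed.
#' @param genotypes_per_variant genotypes per variant (default 3).
#' @param replicates replicate cultures per genotype (default 24).
#' @param noise a [noise_model()].
#' @return As [simulate_screen()]: list with `dataset` (raw scale) and
#'   `truth`.
#' @export
simulate_qt_benchmark <- function(seed, genotypes_per_variant = 3L,
                                  replicates = 24L, noise = noise_model()) {
  v <- qt_demo_classes()
  m <- as.integer(genotypes_per_variant)
  gen <- unlist(lapply(names(v), function(n) paste0(n, ".g", seq_len(m))))
  class_map <- rep(v, each = m)
  names(class_map) <- gen
  config <- sim_config(seed, class_map, design = "solid")
  layouts <- build_solid_layout(gen, control_label = gen[1L],
                                default_replicates = replicates,
                                control_replicates = replicates)
  simulate_screen(layouts, config, noise)
}
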