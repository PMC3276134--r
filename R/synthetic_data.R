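#' Genotype-class parameters for the senescence simulator
#'
#' One `class_params` object describes the stochastic senescence behaviour
#' of all replicate cultures of a genotype class: entry into senescence
#' (onset and per-passage decline), the fitness nadir, stochastic emergence
#' of survivors, and permanent sterility of non-recovering cultures.
#' Culture sizes are on the raw integrated-intensity scale; the default
#' healthy fitness of 1e6 raw units corresponds to roughly 4000 units after
#' the power-0.6 variance-stabilising transform (see [transform_sizes()]).
#'
#' @param label class label, reported as simulation ground truth.
#' @param initial_fitness healthy culture size in raw units (> 0).
#' @param onset_passage passage at which fitness decline begins (may be
#'   fractional).
#' @param decline_rate fractional fitness loss per passage after onset, at
#'   the reference liquid dilution of 1:70; in `[0, 1)`.
#' @param nadir_fraction fitness floor as a fraction of `initial_fitness`,
#'   in `[0, 1)`.
#' @param recovery_prob per-culture probability that survivors ever emerge.
#' @param recovery_onset_mean mean number of passages after the nadir until
#'   regrowth begins (>= 1).
#' @param regrowth_rate fractional fitness gain per passage during
#'   recovery, at the reference dilution (> 0).
#' @param extinction_prob per-passage probability that a deeply senescent,
#'   non-recovering culture becomes permanently sterile.
#' @return An object of class `class_params`.
#' @export
class_params <- function(label, initial_fitness = 1e6, onset_passage = 2,
                         decline_rate = 0.6, nadir_fraction = 0.02,
                         recovery_prob = 0.5, recovery_onset_mean = 3,
                         regrowth_rate = 3, extinction_prob = 0.1) {
  stopifnot(
    initial_fitness > 0,
    onset_passage > 0,
    decline_rate >= 0, decline_rate < 1,
    nadir_fraction >= 0, nadir_fraction < 1,
    recovery_prob >= 0, recovery_prob <= 1,
    recovery_onset_mean >= 1,
    regrowth_rate > 0,
    extinction_prob >= 0, extinction_prob <= 1
  )
  structure(list(
    label = label, initial_fitness = initial_fitness,
    onset_passage = onset_passage, decline_rate = decline_rate,
    nadir_fraction = nadir_fraction, recovery_prob = recovery_prob,
    recovery_onset_mean = recovery_onset_mean, regrowth_rate = regrowth_rate,
    extinction_prob = extinction_prob
  ), class = "class_params")
}

#' Measurement-noise model
#'
#' Multiplicative lognormal noise (mean-preserving, coefficient of
#' variation `cv`) applied to every non-sterile size; measurements below
#' `detection_floor` (raw units) are recorded as 0.
#'
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param detection_floor raw size below which a culture reads as 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.25, detection_floor = 1000) {
  stopifnot(cv >= 0, detection_floor >= 0)
  structure(list(cv = cv, detection_floor = detection_floor),
            class = "noise_model")
}

#' Simulation configuration
#'
#' @param seed integer seed; every source of randomness in a simulated
#'   screen derives from it.
#' @param design `"liquid"` or `"solid"`; sets the defaults
#'   `passage_count` = 16 (liquid) / 22 (solid) and `dilution_factor` = 70
#'   (liquid) / 16 (solid). The lower effective dilution of the solid
#'   design gives cultures fewer doublings per passage and hence slower
#'   senescence.
#' @param passage_count number of passages P.
#' @param dilution_factor fold dilution at each passage (> 1).
#' @param class_map named list mapping genotype label to [class_params()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, class_map, design = c("liquid", "solid"),
                       passage_count = NULL, dilution_factor = NULL) {
  design <- match.arg(design)
  passage_count <- as.integer(passage_count %||%
                                switch(design, liquid = 16L, solid = 22L))
  dilution_factor <- dilution_factor %||% switch(design, liquid = 70, solid = 16)
  stopifnot(passage_count >= 1L, dilution_factor > 1,
            is.list(class_map), !is.null(names(class_map)))
  structure(list(seed = as.integer(seed), design = design,
                 passage_count = passage_count,
                 dilution_factor = dilution_factor, class_map = class_map),
            class = "sim_config")
}

#' Preset genotype classes
#'
#' Four ready-made parameter sets spanning the trajectory archetypes seen
#' in telomerase-null senescence screens:
#' \describe{
#'   \item{normal}{his3-like wild-type control behaviour: healthy start,
#'     decline to a fitness nadir near passage 6 under the liquid design,
#'     survivors emerging in 50\% of cultures.}
#'   \item{no_recovery}{rad52-like: reduced initial fitness, earlier entry
#'     into senescence, survivors in only 29\% of cultures (recombination-
#'     dependent survivor formation is crippled).}
#'   \item{fast_recovery}{rif1-like: accelerated entry into senescence and
#'     accelerated, more frequent (81\%) emergence of survivors.}
#'   \item{neutral_nonsenescing}{flat profile, emulating a
#'     telomerase-proficient control that never senesces.}
#' }
#'
#' @return Named list of [class_params()].
#' @export
preset_classes <- function() {
  list(
    normal = class_params(
      "normal", initial_fitness = 1e6, onset_passage = 2,
      decline_rate = 0.62, nadir_fraction = 0.02, recovery_prob = 0.50,
      recovery_onset_mean = 3, regrowth_rate = 3, extinction_prob = 0.10),
    no_recovery = class_params(
      "no_recovery", initial_fitness = 5e5, onset_passage = 1,
      decline_rate = 0.65, nadir_fraction = 0.02, recovery_prob = 0.29,
      recovery_onset_mean = 3, regrowth_rate = 3, extinction_prob = 0.15),
    fast_recovery = class_params(
      "fast_recovery", initial_fitness = 1e6, onset_passage = 1,
      decline_rate = 0.70, nadir_fraction = 0.02, recovery_prob = 0.81,
      recovery_onset_mean = 1, regrowth_rate = 4, extinction_prob = 0.10),
    neutral_nonsenescing = class_params(
      "neutral_nonsenescing", initial_fitness = 1e6, onset_passage = 2,
      decline_rate = 0, nadir_fraction = 0.02, recovery_prob = 1,
      recovery_onset_mean = 1, regrowth_rate = 3, extinction_prob = 0)
  )
}

#' Twenty-three well-separated trajectory variants
#'
#' A designed scenario for exercising unsupervised profile clustering:
#' 23 parameter sets whose noise-free expected profiles (solid design,
#' 22 passages, transformed scale) are mutually at least ~600 RMS units
#' apart. The variants were selected by a maximin (greedy farthest-point)
#' design over a grid of onset passages, decline rates, initial-fitness
#' tiers, nadir floors and flat profiles, so that quality-threshold
#' clustering with the RMS distance can be validated against known
#' ground truth. Correlation distance is deliberately not used here: it is
#' affine-invariant and thus blind to the fitness tiers that several
#' variants differ by.
#'
#' @return Named list of 23 [class_params()] objects.
#' @export
qt_demo_classes <- function() {
  spec <- list(
    # label,               init,  onset, decline, floor
    c("crash_low",        1.2e5,  1,     0.90,    0.02),
    c("crash_hi",         1e6,    1,     0.90,    0.02),
    c("on03_crash",       1e6,    3,     0.90,    0.02),
    c("on05_crash",       1e6,    5,     0.90,    0.02),
    c("on07_crash",       1e6,    7,     0.90,    0.02),
    c("on07_crash_mid",   2.5e5,  7,     0.90,    0.02),
    c("on09_steep",       1e6,    9,     0.70,    0.02),
    c("on09_crash_half",  5e5,    9,     0.90,    0.02),
    c("on11_steep",       1e6,   11,     0.70,    0.02),
    c("on11_crash_half",  5e5,   11,     0.90,    0.02),
    c("on13_crash",       1e6,   13,     0.90,    0.02),
    c("on13_crash_mid",   2.5e5, 13,     0.90,    0.02),
    c("on13_crash_half",  5e5,   13,     0.90,    0.02),
    c("on15_steep",       1e6,   15,     0.70,    0.02),
    c("on15_steep_half",  5e5,   15,     0.70,    0.02),
    c("floor10_on01",     1e6,    1,     0.62,    0.10),
    c("floor10_on07",     1e6,    7,     0.62,    0.10),
    c("floor35_on07",     1e6,    7,     0.62,    0.35),
    c("flat_hi",          1e6,    2,     0,       0.02),
    c("flat_600k",        6e5,    2,     0,       0.02),
    c("flat_350k",        3.5e5,  2,     0,       0.02),
    c("flat_100k",        1e5,    2,     0,       0.02),
    c("shallow",          1e6,    1,     0.20,    0.10)
  )
  out <- lapply(spec, function(s) {
    class_params(s[[1L]], initial_fitness = as.numeric(s[[2L]]),
                 onset_passage = as.numeric(s[[3L]]),
                 decline_rate = as.numeric(s[[4L]]),
                 nadir_fraction = as.numeric(s[[5L]]),
                 recovery_prob = 0, extinction_prob = 0)
  })
  stats::setNames(out, vapply(spec, `[[`, "", 1L))
}

# Dilution scaling: a culture diluted 1:D can perform ~log2(D) doublings per
# passage. Per-passage senescent decline (and regrowth) is scaled by the
# division budget relative to the 1:70 liquid reference, so identical
# parameters senesce more slowly under the 16-fold solid dilution.
dilution_exponent <- function(dilution_factor) {
  log2(dilution_factor) / log2(70)
}

#' Noise-free expected trajectory of a genotype class
#'
#' The deterministic backbone of [simulate_culture()]: constant at
#' `initial_fitness` before onset, geometric decline after onset at a rate
#' scaled by the design's division budget, floored at
#' `nadir_fraction * initial_fitness`.
#'
#' @param params a [class_params()].
#' @param config a [sim_config()].
#' @return List with `sizes` (numeric, length P, raw units) and
#'   `nadir_passage` (first passage at the floor; `Inf` if never reached).
#' @export
expected_trajectory <- function(params, config) {
  P <- config$passage_count
  q <- dilution_exponent(config$dilution_factor)
  retain <- (1 - params$decline_rate)^q
  floor_raw <- params$nadir_fraction * params$initial_fitness
  p <- seq_len(P)
  f <- ifelse(p <= params$onset_passage, params$initial_fitness,
              pmax(floor_raw,
                   params$initial_fitness * retain^(p - params$onset_passage)))
  at_floor <- which(f <= floor_raw * (1 + 1e-9))
  nadir <- if (params$decline_rate > 0 && length(at_floor)) {
    at_floor[1L]
  } else {
    Inf
  }
  list(sizes = f, nadir_passage = nadir)
}

#' Simulate one culture's size trajectory
#'
#' Deterministic given `(params, noise, config, stream)`. The trajectory
#' follows [expected_trajectory()]; at the nadir each culture either
#' recovers (with probability `recovery_prob`, after a geometric delay of
#' mean `recovery_onset_mean` passages) and regrows toward its initial
#' fitness, or risks permanent sterility (per-passage probability
#' `extinction_prob`), after which its sizes are exactly 0. Multiplicative
#' lognormal noise is applied last, with sub-floor readings recorded as 0.
#'
#' @param params a [class_params()].
#' @param noise a [noise_model()].
#' @param config a [sim_config()].
#' @param stream integer seed of this culture's private RNG substream.
#' @return Numeric vector of P raw culture sizes.
#' @export
simulate_culture <- function(params, noise, config, stream) {
  P <- config$passage_count
  with_local_seed(stream, {
    u_recover <- stats::runif(1)
    delay <- if (params$recovery_onset_mean <= 1) 0 else
      stats::rgeom(1, prob = 1 / params$recovery_onset_mean)
    u_ext <- stats::runif(P)
    z <- stats::rnorm(P)

    et <- expected_trajectory(params, config)
    sizes <- et$sizes
    nadir <- et$nadir_passage
    sterile_from <- Inf

    if (is.finite(nadir)) {
      recovers <- u_recover < params$recovery_prob
      if (recovers) {
        start <- nadir + 1 + delay
        if (start <= P) {
          q <- dilution_exponent(config$dilution_factor)
          grow <- (1 + params$regrowth_rate)^q
          for (p in seq(start, P)) {
            sizes[p] <- min(params$initial_fitness, sizes[p - 1] * grow)
          }
        }
      } else if (params$extinction_prob > 0) {
        hit <- which(u_ext < params$extinction_prob)
        hit <- hit[hit >= nadir]
        if (length(hit)) sterile_from <- hit[1L]
      }
    }

    if (noise$cv > 0) {
      sdlog <- sqrt(log(1 + noise$cv^2))
      sizes <- sizes * exp(z * sdlog - sdlog^2 / 2)
    }
    sizes[sizes < noise$detection_floor] <- 0
    if (is.finite(sterile_from)) sizes[seq(sterile_from, P)] <- 0
    sizes
  })
}

#' Simulate a whole screen from plate layouts
#'
#' Generates one culture series per assigned plate position. Each culture
#' uses an independent RNG substream derived deterministically from
#' `(seed, plate_id, row, col)`, so identical configurations are
#' bit-reproducible and adding plates never perturbs existing cultures.
#'
#' @param layouts list of [plate_layout()] objects.
#' @param config a [sim_config()]; every genotype in the layouts must
#'   appear in `config$class_map`.
#' @param noise a [noise_model()].
#' @return List with `dataset` (a raw-scale [screen_dataset()]) and `truth`
#'   (named character vector mapping genotype to its class label).
#' @examples
#' cfg <- sim_config(1, list(g1 = preset_classes()$normal))
#' lay <- plate_layout("P1", rep(1, 4), 1:4, rep("g1", 4), 96, "liquid")
#' sim <- simulate_screen(list(lay), cfg, noise_model())
#' sim$truth
#' @export
simulate_screen <- function(layouts, config, noise = noise_model()) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  wells <- do.call(rbind, lapply(layouts, as.data.frame))
  missing <- setdiff(unique(wells$genotype), names(config$class_map))
  if (length(missing)) {
    stop("genotype(s) missing from class_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  P <- config$passage_count
  n <- nrow(wells)
  sizes <- numeric(n * P)
  for (i in seq_len(n)) {
    stream <- culture_seed(config$seed, wells$plate_id[i], wells$row[i],
                           wells$col[i])
    par_i <- config$class_map[[wells$genotype[i]]]
    sizes[((i - 1L) * P + 1L):(i * P)] <-
      simulate_culture(par_i, noise, config, stream)
  }
  tab <- data.frame(
    plate_id = rep(wells$plate_id, each = P),
    row = rep(wells$row, each = P),
    col = rep(wells$col, each = P),
    genotype = rep(wells$genotype, each = P),
    passage = rep(seq_len(P), n),
    size = sizes,
    stringsAsFactors = FALSE
  )
  truth <- vapply(config$class_map, function(p) p$label, character(1L))
  list(
    dataset = screen_dataset(tab, scale = "raw", design = config$design,
                             passage_count = P),
    truth = truth[unique(wells$genotype)]
  )
}

#' Read a simulation scenario file
#'
#' Scenario files are YAML with a mandatory `seed`, optional `design`,
#' `passage_count`, `dilution_factor`, `noise` (`cv`, `detection_floor`)
#' and a `genotypes` map assigning each genotype either a preset name (see
#' [preset_classes()]) or an explicit parameter map understood by
#' [class_params()].
#'
#' @param path YAML file path.
#' @return List with `config` (a [sim_config()]) and `noise`
#'   (a [noise_model()]).
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$seed)) stop("scenario file must set a seed", call. = FALSE)
  presets <- preset_classes()
  class_map <- lapply(names(sc$genotypes), function(g) {
    spec <- sc$genotypes[[g]]
    if (is.character(spec) && length(spec) == 1L) {
      if (!spec %in% names(presets)) {
        stop("unknown preset '", spec, "' for genotype ", g, call. = FALSE)
      }
      presets[[spec]]
    } else {
      num <- lapply(spec[setdiff(names(spec), "label")], function(v) {
        # yaml leaves "2.0e5"-style scalars as text; coerce where numeric
        if (is.character(v) && !is.na(suppressWarnings(as.numeric(v)))) {
          as.numeric(v)
        } else {
          v
        }
      })
      do.call(class_params, c(list(label = spec$label %||% g), num))
    }
  })
  names(class_map) <- names(sc$genotypes)
  noise_args <- sc$noise %||% list()
  list(
    config = sim_config(sc$seed, class_map,
                        design = sc$design %||% "liquid",
                        passage_count = sc$passage_count,
                        dilution_factor = sc$dilution_factor),
    noise = do.call(noise_model, noise_args)
  )
}
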