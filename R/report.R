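#' Gene sets
#'
#' A named set of genotype labels, used for overlap summaries between the
#' classes found in a screen and externally defined gene lists (for
#' example, genes reported to shorten or lengthen telomeres).
#'
#' @param name set label.
#' @param members character vector of genotype labels (duplicates removed;
#'   must be non-empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (!length(members)) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, members = members), class = "gene_set")
}

#' Venn-region counts for two or three gene sets
#'
#' Exact member counts for every region of a 2- or 3-set Venn diagram.
#' Counts conserve cardinalities: the regions containing a set sum to its
#' size.
#'
#' @param sets list of 2 or 3 [gene_set()] objects.
#' @return Data frame with one row per non-empty region pattern: logical
#'   membership columns (one per set, named by set name), `region` (a
#'   label like `"A&B"`), and `count`. All `2^k - 1` regions are listed,
#'   including zero counts.
#' @export
venn_overlap <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2L, 3L)) {
    stop("venn_overlap needs 2 or 3 gene sets", call. = FALSE)
  }
  nm <- vapply(sets, function(s) s$name, character(1L))
  if (anyDuplicated(nm)) stop("gene set names must be unique", call. = FALSE)
  universe <- unique(unlist(lapply(sets, function(s) s$members)))
  member <- vapply(sets, function(s) universe %in% s$members,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  colnames(member) <- nm
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  colnames(patterns) <- nm
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(row) all(row == p)))
  })
  region <- apply(patterns, 1L, function(p) paste(nm[as.logical(p)],
                                                  collapse = "&"))
  out <- cbind(patterns, data.frame(region = region, count = as.integer(counts),
                                    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Quadrant summary of a highlighted gene set on an interaction plot
#'
#' Given per-genotype genetic-interaction scores on two axes (for example,
#' interaction strength with two different telomere-capping mutants), this
#' summarises where a highlighted gene set falls relative to the full
#' tested background: the fraction of highlighted versus all genes left and
#' right of `x_threshold`, above and below `y_threshold`, the four quadrant
#' fractions, and a bias ratio per axis (left/right and bottom/top of the
#' highlighted fractions). A pronounced left/right but absent top/bottom
#' bias, say, indicates the set interacts with the first background but not
#' the second.
#'
#' @param scores data frame with columns `genotype`, `x_score`, `y_score`.
#' @param highlight a [gene_set()]; members missing from `scores` are
#'   dropped with a warning.
#' @param x_threshold,y_threshold region boundaries (default 0).
#' @return An object of class `quadrant_summary`: list with `axis` (data
#'   frame of left/right/bottom/top fractions for highlight and
#'   background), `quadrants` (2 x 2 highlighted-fraction table), `bias`
#'   (named vector `x_left_over_right`, `y_bottom_over_top`),
#'   `n_highlight`, `n_total`.
#' @export
quadrant_summary <- function(scores, highlight, x_threshold = 0,
                             y_threshold = 0) {
  stopifnot(all(c("genotype", "x_score", "y_score") %in% names(scores)))
  keep <- highlight$members %in% scores$genotype
  if (!all(keep)) {
    warning(sum(!keep), " highlighted gene(s) absent from the score table ",
            "were dropped", call. = FALSE)
  }
  members <- highlight$members[keep]
  if (!length(members)) {
    stop("no highlighted genes remain after filtering against the score table",
         call. = FALSE)
  }
  hi <- scores$genotype %in% members
  frac <- function(idx) {
    c(left = mean(scores$x_score[idx] < x_threshold),
      right = mean(scores$x_score[idx] >= x_threshold),
      bottom = mean(scores$y_score[idx] < y_threshold),
      top = mean(scores$y_score[idx] >= y_threshold))
  }
  f_hi <- frac(hi)
  f_all <- frac(rep(TRUE, nrow(scores)))
  quad <- with(scores[hi, ], table(
    x = factor(ifelse(x_score < x_threshold, "left", "right"),
               c("left", "right")),
    y = factor(ifelse(y_score < y_threshold, "bottom", "top"),
               c("bottom", "top"))
  )) / sum(hi)
  structure(list(
    axis = data.frame(region = names(f_hi), highlight = unname(f_hi),
                      background = unname(f_all), stringsAsFactors = FALSE),
    quadrants = quad,
    bias = c(x_left_over_right = unname(f_hi["left"] / f_hi["right"]),
             y_bottom_over_top = unname(f_hi["bottom"] / f_hi["top"])),
    n_highlight = sum(hi), n_total = nrow(scores)
  ), class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("quadrant summary: %d highlighted of %d scored genes\n",
              x$n_highlight, x$n_total))
  print(x$axis, row.names = FALSE)
  invisible(x)
}

#' Run the full screen-analysis pipeline
#'
#' Executes transform -> MDPs -> archetype classification -> recovered
#' fractions -> (optionally) QT clustering on either a culture table read
#' from disk or a simulated screen, and writes all tabular outputs plus a
#' machine-readable JSON manifest recording the seed, every threshold used
#' and input digests. Identical configuration and inputs produce
#' byte-identical outputs.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `culture_table` (path) *or* `scenario` (path to a [read_scenario()]
#'   file) or `simulation` (list with `config` and `noise` as returned by
#'   [read_scenario()]); optional `transform` (list: `lambda_power`,
#'   `variant`), `classify` (arguments to [archetype_config()]), `cluster`
#'   (arguments to [qt_config()], or `NULL` to skip clustering).
#' @param out_dir output directory (created if needed).
#' @return Invisible list with the in-memory results: `dataset`
#'   (transformed), `mdps`, `assignments`, `recovery_by_class`,
#'   `clustering` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$culture_table)) {
      dataset <- read_culture_table(config$culture_table)
      seed <- NA_integer_
    } else if (!is.null(config$scenario) || !is.null(config$simulation)) {
      sim_in <- config$simulation %||% read_scenario(config$scenario)
      layouts <- sim_in$layouts %||% default_scenario_layouts(sim_in$config)
      sim <- simulate_screen(layouts, sim_in$config, sim_in$noise)
      dataset <- sim$dataset
      seed <- sim_in$config$seed
    } else {
      stop("config must name either a culture_table or a simulation scenario",
           call. = FALSE)
    }

    stage <- "transform"
    tr <- config$transform %||% list()
    lambda <- tr$lambda_power %||% 0.6
    variant <- tr$variant %||% "plain_power"
    if (attr(dataset, "scale") == "raw") {
      dataset <- transform_sizes(dataset, lambda, variant)
    }

    stage <- "profile"
    mdps <- compute_mdps(dataset)

    stage <- "archetype_classify"
    cfg <- do.call(archetype_config, config$classify %||% list())
    assignments <- assign_classes(mdps, dataset, cfg)
    recovery <- class_recovery_summary(assignments)

    stage <- "clustering"
    clustering <- NULL
    if (!is.null(config$cluster)) {
      qcfg <- do.call(qt_config, config$cluster)
      clustering <- qt_cluster(mdps, qcfg)
    }

    stage <- "report"
    write_culture_table(dataset, file.path(out_dir, "cultures.tsv"))
    mdp_table(mdps, file.path(out_dir, "mdp.tsv"))
    write_class_report(assignments, file.path(out_dir, "classification.tsv"))
    for (a in c(cfg$normal_archetype, cfg$no_recovery_archetype,
                cfg$fast_recovery_archetype)) {
      write_ranked_list(rank_by_archetype(mdps, a),
                        file.path(out_dir, paste0("ranked_", a, ".tsv")))
    }
    if (!is.null(clustering)) {
      write_cluster_assignments(clustering, mdps,
                                file.path(out_dir, "clusters.tsv"))
    }

    filt <- attr(assignments, "p2_filter")
    manifest <- list(
      seed = seed,
      design = attr(dataset, "design"),
      passage_count = attr(dataset, "passage_count"),
      n_cultures = n_cultures(dataset),
      n_genotypes = length(mdps),
      transform = list(lambda_power = lambda, variant = variant),
      thresholds = list(
        r_normal = cfg$r_normal, r_no_recovery = cfg$r_no_recovery,
        fast_recovery_top_k = cfg$fast_recovery_top_k,
        recovery_size_threshold = cfg$recovery_size_threshold,
        recovery_passage = cfg$recovery_passage,
        recovery_mode = cfg$recovery_mode,
        filter_passage = cfg$filter_passage
      ),
      passage2_filter = list(c_ave = filt$c_ave, c_sd = filt$c_sd,
                             c_s = filt$c_s),
      clustering = if (is.null(clustering)) NULL else list(
        diameter_threshold = clustering$config$diameter_threshold,
        min_cluster_size = clustering$config$min_cluster_size,
        distance = clustering$config$distance,
        n_clusters = length(clustering$clusters)
      ),
      input_digest = dataset_digest(dataset)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    list(dataset = dataset, mdps = mdps, assignments = assignments,
         recovery_by_class = recovery, clustering = clustering,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Default layouts for a scenario that does not provide any: every genotype
# in the class map gets 8 replicate cultures on solid plates, or one 96-well
# liquid plate layout when the genotype count allows it.
default_scenario_layouts <- function(config) {
  g <- names(config$class_map)
  build_solid_layout(g, control_label = g[[1L]],
                     default_replicates = 8L, control_replicates = 8L)
}

# Order-independent content digest of a dataset (sum-based, not
# cryptographic; used to record inputs in the run manifest).
dataset_digest <- function(dataset) {
  key <- paste(dataset$plate_id, dataset$row, dataset$col, dataset$passage,
               dataset$genotype, formatC(dataset$size, digits = 17,
                                         format = "g"))
  h <- vapply(key, string_hash, numeric(1L), USE.NAMES = FALSE)
  sprintf("%.0f", sum(h) %% 2^52)
}
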