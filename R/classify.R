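#' Classification configuration
#'
#' Bundles the archetype labels and thresholds of the three-archetype
#' classification of senescence profiles:
#' \itemize{
#'   \item normal senescence: correlation to the normal archetype
#'     `r > r_normal` (default 0.85);
#'   \item no recovery: correlation to the no-recovery archetype
#'     `r > r_no_recovery` (default 0.5) *and* mean culture size at the
#'     filter passage below the screen-wide cutoff `c_s` (see
#'     [compute_passage2_filter()]);
#'   \item fast recovery: the `fast_recovery_top_k` (default 20) genotypes
#'     most correlated to the fast-recovery archetype — a top-k class,
#'     because a strict r cutoff retains almost no members while the most
#'     correlated profiles still share a distinctive shape. An optional
#'     strict threshold `r_fast_recovery_strict` may be set instead
#'     (`NULL` disables it).
#' }
#' Memberships are non-exclusive. A culture counts as recovered when it
#' reaches `recovery_size_threshold` (default 1000 transformed units) by
#' passage `recovery_passage` (default 19); `recovery_mode` `"at_passage"`
#' (the default) tests the size at the deadline passage itself, while
#' `"by_passage"` tests the running maximum up to the deadline. The default
#' is `at_passage` because cultures start the screen *above* the recovery
#' threshold: a running maximum taken from passage 1 would count every
#' healthy starting culture as recovered, whereas senescent cultures are
#' monotypically small at the deadline unless survivors emerged.
#'
#' @param normal_archetype,no_recovery_archetype,fast_recovery_archetype
#'   genotype labels of the three archetypes (defaults `"his3"`, `"rad52"`,
#'   `"rif1"`).
#' @param r_normal,r_no_recovery correlation thresholds in (-1, 1).
#' @param fast_recovery_top_k size of the fast-recovery top-k class.
#' @param r_fast_recovery_strict optional strict r cutoff replacing top-k.
#' @param recovery_size_threshold recovery size threshold (transformed
#'   units).
#' @param recovery_passage deadline passage for recovery.
#' @param recovery_mode `"by_passage"` or `"at_passage"`.
#' @param filter_passage passage of the size filter (default 2).
#' @return An object of class `archetype_config`.
#' @export
archetype_config <- function(normal_archetype = "his3",
                             no_recovery_archetype = "rad52",
                             fast_recovery_archetype = "rif1",
                             r_normal = 0.85, r_no_recovery = 0.5,
                             fast_recovery_top_k = 20L,
                             r_fast_recovery_strict = NULL,
                             recovery_size_threshold = 1000,
                             recovery_passage = 19L,
                             recovery_mode = c("at_passage", "by_passage"),
                             filter_passage = 2L) {
  stopifnot(r_normal > -1, r_normal < 1, r_no_recovery > -1, r_no_recovery < 1,
            fast_recovery_top_k >= 1L, recovery_size_threshold > 0,
            recovery_passage >= 1L, filter_passage >= 1L)
  structure(list(
    normal_archetype = normal_archetype,
    no_recovery_archetype = no_recovery_archetype,
    fast_recovery_archetype = fast_recovery_archetype,
    r_normal = r_normal, r_no_recovery = r_no_recovery,
    fast_recovery_top_k = as.integer(fast_recovery_top_k),
    r_fast_recovery_strict = r_fast_recovery_strict,
    recovery_size_threshold = recovery_size_threshold,
    recovery_passage = as.integer(recovery_passage),
    recovery_mode = match.arg(recovery_mode),
    filter_passage = as.integer(filter_passage)
  ), class = "archetype_config")
}

#' Screen-wide early-passage size filter
#'
#' Computes the cutoff \eqn{C^s = C^{ave} - 0.5 \, C^{SD}} from *all
#' individual culture sizes* (not genotype means) at the filter passage.
#' Genotypes whose mean size at that passage is below the cutoff have
#' already entered senescence early; the no-recovery class requires this in
#' addition to profile-shape correlation, so that slow-growing but
#' late-senescing strains are not swept in.
#'
#' @param dataset a transformed-scale [screen_dataset()].
#' @param passage filter passage (default 2).
#' @return An object of class `passage2_filter` with `c_ave`, `c_sd`,
#'   `c_s`, `passage` and `scale`.
#' @export
compute_passage2_filter <- function(dataset, passage = 2L) {
  stopifnot(inherits(dataset, "screen_dataset"))
  P <- attr(dataset, "passage_count")
  if (passage < 1L || passage > P) {
    stop("filter passage ", passage, " outside 1..", P, call. = FALSE)
  }
  sizes <- dataset$size[dataset$passage == passage]
  c_ave <- mean(sizes)
  c_sd <- if (length(sizes) > 1L) stats::sd(sizes) else 0
  structure(list(c_ave = c_ave, c_sd = c_sd, c_s = c_ave - 0.5 * c_sd,
                 passage = as.integer(passage),
                 scale = attr(dataset, "scale")),
            class = "passage2_filter")
}

#' @export
print.passage2_filter <- function(x, ...) {
  cat(sprintf(
    "passage-%d size filter (%s scale): c_ave = %.4g, c_sd = %.4g, c_s = %.4g\n",
    x$passage, x$scale, x$c_ave, x$c_sd, x$c_s))
  invisible(x)
}

#' Rank genotypes by profile correlation to an archetype
#'
#' Orders every genotype by the Pearson correlation of its MDP to the
#' archetype's MDP, most similar first. The archetype itself heads the list
#' with r = 1; ties are broken by genotype label (ascending); genotypes
#' with undefined r (constant profile) are placed last.
#'
#' @param mdps named list of `mdp` objects (see [compute_mdps()]).
#' @param archetype genotype label of the archetype; must be in `mdps`.
#' @return Data frame with columns `rank`, `genotype`, `r`, carrying class
#'   `ranked_list`.
#' @export
rank_by_archetype <- function(mdps, archetype) {
  if (!archetype %in% names(mdps)) {
    stop("archetype '", archetype, "' not found among the MDPs", call. = FALSE)
  }
  ref <- mdps[[archetype]]
  r <- vapply(mdps, function(m) {
    if (identical(m$genotype, archetype)) 1.0 else pearson_correlation(m, ref)
  }, numeric(1L))
  g <- names(mdps)
  ord <- order(is.na(r), -ifelse(is.na(r), -Inf, r), g)
  out <- data.frame(rank = seq_along(g), genotype = g[ord], r = r[ord],
                    stringsAsFactors = FALSE)
  attr(out, "archetype") <- archetype
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Mean culture size of each genotype at one passage (transformed scale).
genotype_passage_means <- function(dataset, passage) {
  sub <- dataset[dataset$passage == passage, ]
  vapply(split(sub$size, sub$genotype), mean, numeric(1L))
}

#' Classify genotypes against the three archetypes
#'
#' The headline classification: every genotype receives its correlation to
#' each of the three archetype MDPs, the early-passage filter verdict, its
#' (non-exclusive) class memberships and its recovered fraction.
#' An undefined correlation never grants a membership. Ties at the top-k
#' boundary of the fast-recovery class are resolved by including every
#' genotype tied at the k-th correlation value.
#'
#' @param mdps named list of `mdp` objects covering all genotypes.
#' @param dataset the transformed-scale [screen_dataset()] the MDPs came
#'   from (needed for the size filter and recovered fractions).
#' @param cfg an [archetype_config()].
#' @param apply_p2_filter apply the early-passage size filter to the
#'   no-recovery class (default TRUE; disabling makes every class purely
#'   correlation-based, hence scale-free).
#' @return Data frame of class `class_assignment` with one row per
#'   genotype: `genotype`, `n_repeats`, `r_normal`, `r_no_recovery`,
#'   `r_fast_recovery`, `passes_p2_filter`, `memberships`
#'   (semicolon-joined), `recovered_fraction`. The filter object is
#'   attached as attribute `p2_filter`.
#' @export
assign_classes <- function(mdps, dataset, cfg = archetype_config(),
                           apply_p2_filter = TRUE) {
  for (a in c(cfg$normal_archetype, cfg$no_recovery_archetype,
              cfg$fast_recovery_archetype)) {
    if (!a %in% names(mdps)) {
      stop("archetype '", a, "' not present in the screen", call. = FALSE)
    }
  }
  filt <- compute_passage2_filter(dataset, cfg$filter_passage)
  p2_means <- genotype_passage_means(dataset, cfg$filter_passage)

  r_to <- function(arch) {
    ref <- mdps[[arch]]
    vapply(mdps, function(m) {
      if (identical(m$genotype, arch)) 1.0 else pearson_correlation(m, ref)
    }, numeric(1L))
  }
  g <- names(mdps)
  r_n <- r_to(cfg$normal_archetype)
  r_nr <- r_to(cfg$no_recovery_archetype)
  r_fr <- r_to(cfg$fast_recovery_archetype)

  passes <- p2_means[g] < filt$c_s

  in_normal <- !is.na(r_n) & r_n > cfg$r_normal
  in_norec <- !is.na(r_nr) & r_nr > cfg$r_no_recovery &
    (!apply_p2_filter | passes)
  if (is.null(cfg$r_fast_recovery_strict)) {
    rl <- rank_by_archetype(mdps, cfg$fast_recovery_archetype)
    defined <- rl[!is.na(rl$r), ]
    k <- min(cfg$fast_recovery_top_k, nrow(defined))
    cut_r <- defined$r[k]
    top <- defined$genotype[defined$r >= cut_r]  # stable superset on ties
    in_fast <- g %in% top
  } else {
    in_fast <- !is.na(r_fr) & r_fr > cfg$r_fast_recovery_strict
  }

  memberships <- mapply(function(a, b, c) {
    paste(c("normal", "no_recovery", "fast_recovery")[c(a, b, c)],
          collapse = ";")
  }, in_normal, in_norec, in_fast)

  rec <- vapply(g, recovered_fraction, numeric(1L), dataset = dataset,
                cfg = cfg)
  out <- data.frame(
    genotype = g,
    n_repeats = vapply(mdps, function(m) m$n_repeats, integer(1L)),
    r_normal = r_n, r_no_recovery = r_nr, r_fast_recovery = r_fr,
    passes_p2_filter = unname(passes),
    memberships = unname(memberships),
    recovered_fraction = unname(rec),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "p2_filter") <- filt
  attr(out, "config") <- cfg
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Fraction of replicate cultures that recovered from senescence
#'
#' Counts a genotype's replicate cultures that recovered to
#' `recovery_size_threshold` or greater by `recovery_passage` (mode
#' `"at_passage"`, the default: the size at the deadline passage is tested;
#' `"by_passage"`: the running maximum over passages up to the deadline, so
#' a transiently large culture counts). With 8 replicates per genotype the
#' result takes the familiar 0/8 .. 8/8 values.
#'
#' @param dataset a transformed-scale [screen_dataset()].
#' @param genotype genotype label.
#' @param cfg an [archetype_config()].
#' @return Fraction in `[0, 1]`.
#' @export
recovered_fraction <- function(dataset, genotype, cfg = archetype_config()) {
  P <- attr(dataset, "passage_count")
  if (cfg$recovery_passage > P) {
    stop("recovery passage ", cfg$recovery_passage,
         " exceeds the dataset's ", P, " passages", call. = FALSE)
  }
  m <- culture_matrix(dataset, genotype)
  window <- seq_len(cfg$recovery_passage)
  score <- switch(cfg$recovery_mode,
    by_passage = apply(m[, window, drop = FALSE], 1L, max),
    at_passage = m[, cfg$recovery_passage]
  )
  mean(score >= cfg$recovery_size_threshold)
}

#' Mean recovered fraction per archetype class
#'
#' Unweighted mean of the member genotypes' recovered fractions for each of
#' the three classes. Empty classes yield `NA` (flagged, never silently 0).
#'
#' @param assignments an [assign_classes()] result.
#' @return Named numeric vector over
#'   `c("normal", "no_recovery", "fast_recovery")`.
#' @export
class_recovery_summary <- function(assignments) {
  stopifnot(inherits(assignments, "class_assignment"))
  member_list <- strsplit(assignments$memberships, ";", fixed = TRUE)
  vapply(c("normal", "no_recovery", "fast_recovery"), function(cl) {
    in_cl <- vapply(member_list, function(m) cl %in% m, logical(1L))
    if (!any(in_cl)) return(NA_real_)
    mean(assignments$recovered_fraction[in_cl])
  }, numeric(1L))
}

#' Write classification outputs
#'
#' `write_class_report` writes the per-genotype classification table;
#' `write_ranked_list` writes one archetype's ranked correlation list
#' (columns `rank`, `genotype`, `r`). Both are tab-separated text.
#'
#' @param assignments an [assign_classes()] result.
#' @param ranked a [rank_by_archetype()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_class_report <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_report
#' @export
write_ranked_list <- function(ranked, path) {
  utils::write.table(as.data.frame(ranked), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
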