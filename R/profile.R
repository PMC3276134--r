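#' Variance-stabilising power transform of culture sizes
#'
#' Raw integrated-intensity culture sizes are strongly heteroscedastic;
#' variances are stabilised with a Box-Cox power transform with power
#' parameter 0.6. Two variants are available: `plain_power`,
#' \eqn{g(x) = x^\lambda} (the default; raw sizes of order 1e6 land near
#' the 4000-unit fitness scale of healthy cultures), and `scaled_power`,
#' the textbook Box-Cox form \eqn{g(x) = (x^\lambda - 1)/\lambda} with
#' \eqn{g(0) = -1/\lambda}. Both are strictly increasing on `x >= 0`, so
#' within-passage rankings are preserved; downstream Pearson correlations
#' are invariant to the affine difference between the variants.
#'
#' @param dataset a raw-scale [screen_dataset()].
#' @param lambda_power power parameter (> 0, default 0.6).
#' @param variant `"plain_power"` or `"scaled_power"`.
#' @return A transformed-scale `screen_dataset`.
#' @export
transform_sizes <- function(dataset, lambda_power = 0.6,
                            variant = c("plain_power", "scaled_power")) {
  stopifnot(inherits(dataset, "screen_dataset"), lambda_power > 0)
  variant <- match.arg(variant)
  if (attr(dataset, "scale") != "raw") {
    stop("dataset is already on the transformed scale", call. = FALSE)
  }
  x <- dataset$size
  dataset$size <- switch(variant,
    plain_power = x^lambda_power,
    scaled_power = ifelse(x > 0, (x^lambda_power - 1) / lambda_power,
                          -1 / lambda_power)
  )
  attr(dataset, "scale") <- "transformed"
  dataset
}

#' Mean density profiles
#'
#' A mean density profile (MDP) summarises all replicate cultures of one
#' genotype: the arithmetic mean and sample standard deviation (n - 1
#' denominator; 0 for a single replicate) of culture size at each passage.
#' MDPs are the unit of all downstream similarity statistics and
#' classification.
#'
#' @param dataset a transformed-scale [screen_dataset()] (set
#'   `require_transformed = FALSE` to summarise raw sizes).
#' @param genotype genotype label.
#' @param require_transformed refuse raw-scale data (default TRUE).
#' @return An object of class `mdp`: list with `genotype`, `n_repeats`,
#'   `mean`, `sd` (numeric, length P) and `passage_count`.
#' @export
compute_mdp <- function(dataset, genotype, require_transformed = TRUE) {
  if (require_transformed && attr(dataset, "scale") != "transformed") {
    stop("MDPs are computed on the transformed scale; call transform_sizes() ",
         "first (or set require_transformed = FALSE)", call. = FALSE)
  }
  m <- culture_matrix(dataset, genotype)
  n <- nrow(m)
  structure(list(
    genotype = genotype,
    n_repeats = n,
    mean = colMeans(m),
    sd = if (n > 1L) apply(m, 2L, stats::sd) else numeric(ncol(m)),
    passage_count = ncol(m)
  ), class = "mdp")
}

#' @rdname compute_mdp
#' @return `compute_mdps` returns a named list of `mdp` objects, one per
#'   genotype in the dataset.
#' @export
compute_mdps <- function(dataset, require_transformed = TRUE) {
  gs <- genotypes(dataset)
  stats::setNames(
    lapply(gs, compute_mdp, dataset = dataset,
           require_transformed = require_transformed),
    gs)
}

#' @export
print.mdp <- function(x, ...) {
  cat(sprintf("MDP of %s: %d repeats x %d passages; area = %.4g\n",
              x$genotype, x$n_repeats, x$passage_count, mdp_area(x)))
  invisible(x)
}

#' Area under a mean density profile
#'
#' Total fitness of a genotype across the screen, computed as the plain sum
#' of the MDP mean over all passages (no normalisation by passage count).
#'
#' @param mdp an [compute_mdp()] object.
#' @return Non-negative scalar.
#' @export
mdp_area <- function(mdp) sum(mdp$mean)

#' Root-mean-square difference between two profiles
#'
#' Absolute (scale-dependent) dissimilarity between two MDPs:
#' \eqn{\sqrt{\frac{1}{P}\sum_p (a_p - b_p)^2}}.
#'
#' @param a,b `mdp` objects with equal passage counts.
#' @return Non-negative scalar; 0 iff the mean profiles are identical.
#' @export
rms_difference <- function(a, b) {
  if (a$passage_count != b$passage_count) {
    stop("profiles have different passage counts (", a$passage_count,
         " vs ", b$passage_count, ")", call. = FALSE)
  }
  sqrt(mean((a$mean - b$mean)^2))
}

#' Pearson correlation between two profiles
#'
#' Shape similarity between two MDPs: the Pearson correlation coefficient
#' of the two mean vectors. Being invariant under positive-affine rescaling
#' of either profile, r compares trajectory *shape* — a sick strain and a
#' healthy strain with similarly shaped senescence curves correlate well
#' regardless of their absolute fitness (this is what makes ranked
#' heat maps of correlated profiles look "stripy"). When either profile is
#' constant, r is undefined and returned as `NA` (never silently 0).
#'
#' @param a,b `mdp` objects with equal passage counts (P >= 3).
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_correlation <- function(a, b) {
  if (a$passage_count != b$passage_count) {
    stop("profiles have different passage counts (", a$passage_count,
         " vs ", b$passage_count, ")", call. = FALSE)
  }
  if (a$passage_count < 3L) {
    stop("at least 3 passages are required for a meaningful correlation",
         call. = FALSE)
  }
  if (stats::var(a$mean) == 0 || stats::var(b$mean) == 0) {
    return(NA_real_)
  }
  stats::cor(a$mean, b$mean)
}

#' Export MDPs as a long table
#'
#' @param mdps named list of `mdp` objects (see [compute_mdps()]).
#' @param path optional file path; when given, the table is written as
#'   tab-separated text with columns
#'   `genotype, n_repeats, passage, mean, sd`.
#' @return The long data frame (invisibly when `path` is given).
#' @export
mdp_table <- function(mdps, path = NULL) {
  tab <- do.call(rbind, lapply(mdps, function(m) {
    data.frame(genotype = m$genotype, n_repeats = m$n_repeats,
               passage = seq_len(m$passage_count), mean = m$mean, sd = m$sd,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Matrix of MDP means for heat-map display
#'
#' Returns the genotype x passage matrix of MDP means, optionally ordered
#' by correlation to a chosen archetype (most similar first), exactly as
#' ranked-profile heat maps are drawn. Values are the MDP means themselves;
#' no renormalisation is applied.
#'
#' @param mdps named list of `mdp` objects.
#' @param order_by optional archetype genotype label to rank rows by.
#' @return Numeric matrix with genotype row names.
#' @export
mdp_matrix <- function(mdps, order_by = NULL) {
  m <- do.call(rbind, lapply(mdps, function(x) x$mean))
  rownames(m) <- vapply(mdps, function(x) x$genotype, character(1L))
  if (!is.null(order_by)) {
    rl <- rank_by_archetype(mdps, order_by)
    m <- m[rl$genotype, , drop = FALSE]
  }
  m
}

#' Plot mean density profiles
#'
#' Draws MDP curves with +/- 1 sd ribbons against passage number.
#'
#' @param x an `mdp` object.
#' @param add add to an existing plot.
#' @param col line colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mdp <- function(x, add = FALSE, col = "firebrick", ...) {
  p <- seq_len(x$passage_count)
  lo <- pmax(0, x$mean - x$sd); hi <- x$mean + x$sd
  if (!add) {
    graphics::plot(p, x$mean, type = "n", ylim = c(0, max(hi)),
                   xlab = "passage", ylab = "mean culture size", ...)
  }
  graphics::polygon(c(p, rev(p)), c(lo, rev(hi)), border = NA,
                    col = grDevices::adjustcolor(col, 0.2))
  graphics::lines(p, x$mean, col = col, lwd = 2)
  invisible(x)
}
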