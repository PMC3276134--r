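#' Quality-threshold clustering configuration
#'
#' QT clustering groups profiles into clusters whose *diameter* (largest
#' pairwise distance) never exceeds a quality threshold, extracting the
#' largest admissible cluster first and repeating on the remainder — no
#' cluster count is chosen in advance. The default distance is
#' `1 - r` (Pearson correlation distance, range 0..2), matching the
#' correlation-based profile similarity used throughout; `rms` uses the
#' absolute root-mean-square profile difference instead.
#'
#' @param diameter_threshold maximum allowed cluster diameter (> 0;
#'   default 0.3 on the `1 - r` scale, i.e. members correlate above 0.7).
#' @param min_cluster_size smallest cluster that may be emitted
#'   (default 2); smaller groups are left unclustered.
#' @param distance `"one_minus_r"` or `"rms"`.
#' @return An object of class `qt_config`.
#' @export
qt_config <- function(diameter_threshold = 0.3, min_cluster_size = 2L,
                      distance = c("one_minus_r", "rms")) {
  stopifnot(diameter_threshold > 0, min_cluster_size >= 1L)
  structure(list(diameter_threshold = diameter_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 distance = match.arg(distance)),
            class = "qt_config")
}

#' Pairwise distance matrix between MDPs
#'
#' @param mdps named list of `mdp` objects.
#' @param distance `"one_minus_r"` (pairs with undefined correlation get
#'   the maximal distance 2) or `"rms"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
mdp_distances <- function(mdps, distance = c("one_minus_r", "rms")) {
  distance <- match.arg(distance)
  g <- names(mdps)
  n <- length(g)
  D <- matrix(0, n, n, dimnames = list(g, g))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- if (distance == "one_minus_r") {
        r <- pearson_correlation(mdps[[i]], mdps[[j]])
        if (is.na(r)) 2 else 1 - r
      } else {
        rms_difference(mdps[[i]], mdps[[j]])
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Grow a candidate cluster from a seed: repeatedly add the point that least
# increases the cluster diameter, while the diameter stays within the
# threshold. Ties between candidate points break alphabetically.
qt_grow <- function(seed, pool, D, threshold) {
  members <- seed
  diam <- 0
  # max distance from each pool point to the current members
  reach <- D[pool, seed]
  names(reach) <- pool
  repeat {
    open <- setdiff(pool, members)
    if (!length(open)) break
    new_diam <- pmax(diam, reach[open])
    best <- min(new_diam)
    if (best > threshold) break
    pick <- sort(open[new_diam == best])[1L]
    members <- c(members, pick)
    diam <- best
    reach <- pmax(reach, D[pool, pick])
  }
  sort(members)
}

#' Quality-threshold clustering of mean density profiles
#'
#' Classic greedy QT procedure: for every remaining genotype a candidate
#' cluster is grown around it (always adding the profile that least
#' increases the diameter, subject to the diameter threshold); the largest
#' candidate is extracted (ties go to the candidate seeded by the
#' alphabetically first genotype) and the procedure repeats until no
#' candidate reaches `min_cluster_size`. The result is deterministic and
#' independent of input order.
#'
#' @param mdps named list of `mdp` objects.
#' @param cfg a [qt_config()].
#' @return An object of class `qt_clustering`: list with `clusters`
#'   (list of genotype-label vectors, sizes non-increasing), `unclustered`
#'   (genotype labels) and `config`.
#' @export
qt_cluster <- function(mdps, cfg = qt_config()) {
  g <- sort(names(mdps))
  if (!length(g)) {
    return(structure(list(clusters = list(), unclustered = character(),
                          config = cfg), class = "qt_clustering"))
  }
  D <- mdp_distances(mdps[g], cfg$distance)
  remaining <- g
  clusters <- list()
  while (length(remaining)) {
    best <- character()
    for (s in remaining) {
      cand <- qt_grow(s, remaining, D, cfg$diameter_threshold)
      if (length(cand) > length(best)) best <- cand
    }
    if (length(best) < cfg$min_cluster_size) break
    clusters[[length(clusters) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  sizes <- vapply(clusters, length, integer(1L))
  clusters <- clusters[order(-sizes)]
  structure(list(clusters = clusters, unclustered = remaining, config = cfg),
            class = "qt_clustering")
}

#' @export
print.qt_clustering <- function(x, ...) {
  cat(sprintf("QT clustering: %d clusters (diameter <= %g, %s distance), %d unclustered\n",
              length(x$clusters), x$config$diameter_threshold,
              x$config$distance, length(x$unclustered)))
  invisible(x)
}

#' Summarise a QT clustering
#'
#' @param clustering a [qt_cluster()] result.
#' @param mdps the MDPs it was produced from.
#' @return Data frame with one row per cluster: `cluster_id`, `size`,
#'   `medoid` (member with minimal summed distance to the others, ties
#'   alphabetical), `mean_within_distance` (mean over member pairs; 0 for a
#'   singleton) and `diameter`. The matrix of mean cluster curves is
#'   attached as attribute `mean_curves`.
#' @export
cluster_summary <- function(clustering, mdps) {
  D <- mdp_distances(mdps[sort(names(mdps))], clustering$config$distance)
  rows <- lapply(seq_along(clustering$clusters), function(i) {
    cl <- clustering$clusters[[i]]
    sub <- D[cl, cl, drop = FALSE]
    med <- cl[order(rowSums(sub), cl)][1L]
    pairs <- sub[upper.tri(sub)]
    data.frame(cluster_id = i, size = length(cl), medoid = med,
               mean_within_distance = if (length(pairs)) mean(pairs) else 0,
               diameter = if (length(pairs)) max(pairs) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame()
  curves <- do.call(rbind, lapply(clustering$clusters, function(cl) {
    colMeans(do.call(rbind, lapply(mdps[cl], function(m) m$mean)))
  }))
  attr(out, "mean_curves") <- curves
  out
}

#' Write cluster assignments
#'
#' Tab-separated text with columns `genotype`, `cluster_id` (0 for
#' unclustered genotypes) and `medoid_flag`.
#'
#' @param clustering a [qt_cluster()] result.
#' @param mdps the MDPs it was produced from (needed for medoids).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignments <- function(clustering, mdps, path) {
  summ <- cluster_summary(clustering, mdps)
  rows <- lapply(seq_along(clustering$clusters), function(i) {
    cl <- clustering$clusters[[i]]
    data.frame(genotype = cl, cluster_id = i,
               medoid_flag = as.integer(cl == summ$medoid[i]),
               stringsAsFactors = FALSE)
  })
  if (length(clustering$unclustered)) {
    rows <- c(rows, list(data.frame(genotype = clustering$unclustered,
                                    cluster_id = 0L, medoid_flag = 0L,
                                    stringsAsFactors = FALSE)))
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
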