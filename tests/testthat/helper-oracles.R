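# Independent brute-force oracles and small fixture builders.

# Build an mdp object directly from a mean vector.
make_mdp <- function(genotype, mean, sd = rep(0, length(mean)), n = 1L) {
  structure(list(genotype = genotype, n_repeats = as.integer(n),
                 mean = as.numeric(mean), sd = as.numeric(sd),
                 passage_count = length(mean)),
            class = "mdp")
}

# Pearson r straight from the definition (no stats::cor).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

rms_oracle <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / length(x))
}

# Venn region counts by exhaustive enumeration of the union.
venn_oracle <- function(member_lists) {
  nm <- names(member_lists)
  universe <- unique(unlist(member_lists))
  k <- length(member_lists)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- integer(nrow(patterns))
  for (g in universe) {
    inset <- vapply(member_lists, function(s) g %in% s, logical(1))
    for (r in seq_len(nrow(patterns))) {
      if (all(inset == as.logical(patterns[r, ]))) {
        counts[r] <- counts[r] + 1L
      }
    }
  }
  region <- apply(patterns, 1, function(p) paste(nm[as.logical(p)],
                                                 collapse = "&"))
  stats::setNames(counts, region)
}

# Independent QT clustering: full diameter recomputation at every step,
# same declared tie rules (alphabetical point/seed preference).
qt_oracle <- function(mdps, cfg) {
  labs <- sort(names(mdps))
  dist_fn <- function(a, b) {
    if (cfg$distance == "rms") {
      rms_oracle(a$mean, b$mean)
    } else {
      if (stats::var(a$mean) == 0 || stats::var(b$mean) == 0) return(2)
      1 - pearson_oracle(a$mean, b$mean)
    }
  }
  diam <- function(set) {
    if (length(set) < 2L) return(0)
    m <- 0
    for (i in seq_len(length(set) - 1L)) {
      for (j in seq(i + 1L, length(set))) {
        m <- max(m, dist_fn(mdps[[set[i]]], mdps[[set[j]]]))
      }
    }
    m
  }
  grow <- function(seed, pool) {
    members <- seed
    repeat {
      open <- sort(setdiff(pool, members))
      if (!length(open)) break
      ds <- vapply(open, function(p) diam(c(members, p)), numeric(1))
      if (min(ds) > cfg$diameter_threshold) break
      members <- c(members, open[which.min(ds)])
    }
    sort(members)
  }
  remaining <- labs
  clusters <- list()
  while (length(remaining)) {
    cands <- lapply(remaining, grow, pool = remaining)
    best <- cands[[which.max(lengths(cands))]]
    if (length(best) < cfg$min_cluster_size) break
    clusters <- c(clusters, list(best))
    remaining <- setdiff(remaining, best)
  }
  list(clusters = clusters[order(-lengths(clusters))],
       unclustered = sort(remaining))
}

# Canonical form for comparing clusterings.
canonical_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  first <- vapply(cl, `[`, "", 1L)
  cl[order(-lengths(cl), first)]
}

# A tiny valid screen dataset built by hand: 2 genotypes x 2 replicates x
# 3 passages on one liquid plate.
tiny_dataset <- function(scale = "transformed") {
  tab <- expand.grid(col = 1:4, passage = 1:3)
  tab$plate_id <- "P1"
  tab$row <- 1L
  tab$genotype <- ifelse(tab$col <= 2, "gA", "gB")
  tab$size <- c(4000, 4000, 3000, 3000,
                2000, 2400, 300, 500,
                3500, 3900, 100, 0)[(tab$passage - 1) * 4 + tab$col]
  screen_dataset(tab, scale = scale, design = "liquid", passage_count = 3L)
}

# Random mdp collection over P passages (positive means).
random_mdps <- function(n, P, scale = 1) {
  labs <- sprintf("g%03d", seq_len(n))
  stats::setNames(lapply(labs, function(l) {
    make_mdp(l, abs(stats::rnorm(P, 10, 5)) * scale, n = 2L)
  }), labs)
}

# Build a transformed-scale dataset with one culture per genotype whose
# sizes equal the given profile vectors (all equal length).
dataset_from_profiles <- function(profiles, reps = 1L) {
  P <- length(profiles[[1]])
  rows <- list()
  i <- 0L
  for (g in names(profiles)) {
    for (r in seq_len(reps)) {
      i <- i + 1L
      rows[[i]] <- data.frame(plate_id = "P1",
                              row = ((i - 1L) %/% 48L) + 1L,
                              col = ((i - 1L) %% 48L) + 1L,
                              genotype = g, passage = seq_len(P),
                              size = profiles[[g]])
    }
  }
  screen_dataset(do.call(rbind, rows), "transformed", "solid",
                 passage_count = P)
}

# Stylised archetype profiles over 22 passages (transformed scale).
stylised_profiles <- function() {
  p <- 1:22
  list(
    his3 = c(4000, 4000, 2500, 1400, 800, 400, 380, 380, 400, 500,
             800, 1300, 1900, 2400, 2700, 2900, 3000, 3050, 3080, 3100,
             3100, 3100),
    rad52 = c(2600, 1700, 900, 450, 260, 250, 240, 230, 225, 220,
              215, 210, 208, 206, 205, 204, 203, 202, 201, 200, 200, 200),
    rif1 = c(4000, 2600, 1200, 500, 400, 900, 2200, 3300, 3800, 3950,
             4000, 4000, 4000, 4000, 4000, 4000, 4000, 4000, 4000, 4000,
             4000, 4000)
  )
}
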