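#' Screen datasets of serially passaged culture sizes
#'
#' A `screen_dataset` holds one record per culture per passage, in a long
#' data frame with columns `plate_id`, `row`, `col`, `genotype`, `passage`,
#' `size`, plus attributes `passage_count` (P), `scale` (`"raw"` or
#' `"transformed"`) and `design` (`"liquid"` or `"solid"`). Every culture
#' must carry a complete series of passages `1..P` and non-negative sizes;
#' a permanently sterile culture simply has size 0 from some passage on.
#'
#' @param tab data frame with the six columns above.
#' @param scale measurement scale flag.
#' @param design screen design flag.
#' @param passage_count number of passages P; inferred from the data when
#'   missing.
#' @return A validated `screen_dataset`.
#' @export
screen_dataset <- function(tab, scale = c("raw", "transformed"),
                           design = c("liquid", "solid"),
                           passage_count = NULL) {
  scale <- match.arg(scale)
  design <- match.arg(design)
  need <- c("plate_id", "row", "col", "genotype", "passage", "size")
  if (!all(need %in% names(tab))) {
    stop("culture table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty culture table", call. = FALSE)
  tab <- as.data.frame(tab)[need]
  tab$plate_id <- as.character(tab$plate_id)
  tab$genotype <- as.character(tab$genotype)
  tab$row <- as.integer(tab$row); tab$col <- as.integer(tab$col)
  tab$passage <- as.integer(tab$passage)
  tab$size <- as.numeric(tab$size)
  if (anyNA(tab$size) || any(tab$size < 0)) {
    bad <- which(is.na(tab$size) | tab$size < 0)[1L]
    stop("negative or missing size at row ", bad, " (culture ",
         tab$plate_id[bad], ":", tab$row[bad], ",", tab$col[bad], ")",
         call. = FALSE)
  }
  P <- as.integer(passage_count %||% max(tab$passage))
  cid <- paste(tab$plate_id, tab$row, tab$col, sep = ":")
  ok <- vapply(split(tab$passage, cid), function(p) {
    length(p) == P && all(sort(p) == seq_len(P))
  }, logical(1L))
  if (!all(ok)) {
    stop("culture ", names(ok)[!ok][1L], " does not cover passages 1..", P,
         call. = FALSE)
  }
  tab <- tab[order(tab$plate_id, tab$row, tab$col, tab$passage), ]
  rownames(tab) <- NULL
  structure(tab, passage_count = P, scale = scale, design = design,
            class = c("screen_dataset", "data.frame"))
}

#' @export
print.screen_dataset <- function(x, ...) {
  cid <- paste(x$plate_id, x$row, x$col, sep = ":")
  cat(sprintf(
    "screen_dataset: %d cultures x %d passages (%s design, %s scale), %d genotypes\n",
    length(unique(cid)), attr(x, "passage_count"), attr(x, "design"),
    attr(x, "scale"), length(unique(x$genotype))))
  invisible(x)
}

#' Number of passages, genotypes and cultures in a dataset
#' @param dataset a [screen_dataset()].
#' @return `passage_count`: integer P. `genotypes`: character vector of
#'   genotype labels. `n_cultures`: number of distinct cultures.
#' @export
passage_count <- function(dataset) attr(dataset, "passage_count")

#' @rdname passage_count
#' @export
genotypes <- function(dataset) sort(unique(dataset$genotype))

#' @rdname passage_count
#' @export
n_cultures <- function(dataset) {
  length(unique(paste(dataset$plate_id, dataset$row, dataset$col, sep = ":")))
}

# Per-culture size matrix (cultures x passages) for one genotype.
culture_matrix <- function(dataset, genotype) {
  sub <- dataset[dataset$genotype == genotype, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("unknown genotype: ", genotype, call. = FALSE)
  }
  P <- attr(dataset, "passage_count")
  cid <- paste(sub$plate_id, sub$row, sub$col, sep = ":")
  sub <- sub[order(cid, sub$passage), ]
  cid <- sort(cid)
  m <- matrix(sub$size, ncol = P, byrow = TRUE,
              dimnames = list(unique(cid), NULL))
  m
}

#' Read and write culture-size tables
#'
#' Culture tables are delimiter-separated text (tab by default, comma
#' accepted on read) with header columns
#' `plate_id,row,col,genotype,passage,size` and one comment line
#' `#scale=... #design=... #passages=P`. Sizes are written as decimal text
#' at full precision (17 significant digits), so a write/read round trip
#' reproduces the dataset bit-exactly.
#'
#' @param dataset a [screen_dataset()].
#' @param path file path.
#' @param sep field separator used when writing (default tab).
#' @return `read_culture_table` returns a `screen_dataset`;
#'   `write_culture_table` returns `path` invisibly.
#' @export
write_culture_table <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "screen_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale=%s #design=%s #passages=%d",
                     attr(dataset, "scale"), attr(dataset, "design"),
                     attr(dataset, "passage_count")), con)
  out <- as.data.frame(dataset)
  out$size <- formatC(out$size, digits = 17, format = "g")
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_culture_table
#' @export
read_culture_table <- function(path) {
  lines <- readLines(path, n = 3L)
  if (length(lines) < 3L) stop("empty culture table: ", path, call. = FALSE)
  meta <- lines[1L]
  if (!startsWith(meta, "#")) {
    stop("culture table must start with a '#scale=... #design=... #passages=' ",
         "comment line", call. = FALSE)
  }
  scale <- sub(".*#scale=(\\w+).*", "\\1", meta)
  design <- sub(".*#design=(\\w+).*", "\\1", meta)
  P <- as.integer(sub(".*#passages=(\\d+).*", "\\1", meta))
  sep <- if (grepl(",", lines[2L], fixed = TRUE) &&
             !grepl("\t", lines[2L], fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "numeric"))
  if (nrow(tab) == 0L) stop("empty culture table: ", path, call. = FALSE)
  screen_dataset(tab, scale = scale, design = design, passage_count = P)
}

#' Validate a screen dataset
#'
#' Produces a structured quality report: per-genotype replicate counts,
#' passage completeness, and the number of all-zero (sterile-from-start)
#' cultures. Validation never raises; problems appear as report entries.
#'
#' @param dataset a [screen_dataset()].
#' @param min_replicates replicate count below which a genotype is flagged
#'   (default 2).
#' @return A list of class `screen_validation` with elements
#'   `replicate_counts` (named integer vector), `passage_count`,
#'   `n_cultures`, `n_sterile_from_start`, `below_minimum` (character
#'   vector of flagged genotypes) and `complete` (logical).
#' @export
validate_dataset <- function(dataset, min_replicates = 2L) {
  stopifnot(inherits(dataset, "screen_dataset"))
  P <- attr(dataset, "passage_count")
  cid <- paste(dataset$plate_id, dataset$row, dataset$col, sep = ":")
  first <- !duplicated(cid)
  reps <- table(dataset$genotype[first])
  reps <- stats::setNames(as.integer(reps), names(reps))
  all_zero <- vapply(split(dataset$size, cid), function(s) all(s == 0),
                     logical(1L))
  structure(list(
    replicate_counts = reps,
    passage_count = P,
    n_cultures = sum(first),
    n_sterile_from_start = sum(all_zero),
    below_minimum = names(reps)[reps < min_replicates],
    complete = TRUE
  ), class = "screen_validation")
}

#' @export
print.screen_validation <- function(x, ...) {
  cat(sprintf("screen validation: %d cultures, %d genotypes, %d passages\n",
              x$n_cultures, length(x$replicate_counts), x$passage_count))
  cat(sprintf("  sterile-from-start cultures: %d\n", x$n_sterile_from_start))
  if (length(x$below_minimum)) {
    cat("  below-minimum replicates:",
        paste(x$below_minimum, collapse = ", "), "\n")
  }
  invisible(x)
}
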