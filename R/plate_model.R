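#' Plate layouts for senescence screens
#'
#' A plate layout records which genotype occupies each well (or pin
#' position) of one plate. Layouts are plain data frames with columns
#' `plate_id`, `row`, `col`, `genotype` plus attributes `format`
#' (96, 384 or 1536) and `design` (`"liquid"` or `"solid"`), carrying S3
#' class `plate_layout`. Coordinates are 1-based and row-major.
#'
#' @param plate_id plate label.
#' @param row,col 1-based well coordinates.
#' @param genotype genotype label per well.
#' @param format plate format: 96 (8 x 12), 384 (16 x 24) or 1536 (32 x 48).
#' @param design screen design, `"liquid"` or `"solid"`.
#' @return A `plate_layout` data frame.
#' @export
plate_layout <- function(plate_id, row, col, genotype, format, design) {
  format <- as.integer(format)
  design <- match.arg(design, c("liquid", "solid"))
  check_positions(format, row, col)
  key <- paste(row, col)
  if (anyDuplicated(key)) {
    stop("duplicate well assignment on plate ", plate_id[1L], call. = FALSE)
  }
  out <- data.frame(
    plate_id = as.character(plate_id), row = as.integer(row),
    col = as.integer(col), genotype = as.character(genotype),
    stringsAsFactors = FALSE
  )
  attr(out, "format") <- format
  attr(out, "design") <- design
  class(out) <- c("plate_layout", "data.frame")
  out
}

# Well fill order that places the outer frame of the grid first (row-major
# within the frame), then the interior row-major. Control strains sit on the
# plate edge, mirroring the spatial design of the screens this package
# models, where control cultures occupy the outer rows/columns.
outer_frame_order <- function(format) {
  g <- plate_grid(format)
  rows <- g[["rows"]]; cols <- g[["cols"]]
  all_pos <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  on_frame <- all_pos$row %in% c(1L, rows) | all_pos$col %in% c(1L, cols)
  rbind(all_pos[on_frame, ], all_pos[!on_frame, ])
}

#' Build liquid-design 96-well screen layouts
#'
#' Generates the layout of a liquid senescence screen: each 96-well plate
#' carries a fixed number of control replicate cultures on the outer frame
#' of the plate (filled first, deterministically) and one well for each of
#' the plate's query genotypes. The default design is 16 plates of 60 query
#' genotypes plus 36 controls, i.e. 576 control cultures in total.
#'
#' @param genotypes_per_plate a list with one character vector per plate,
#'   each of length `96 - controls_per_plate`, or a single character vector
#'   recycled to every plate.
#' @param n_plates number of plates (default 16).
#' @param controls_per_plate control wells per plate (default 36, exactly
#'   the outer ring of a 96-well plate).
#' @param control_label genotype label of the control strain (default
#'   `"his3"`).
#' @return A list of [plate_layout()] objects, one per plate.
#' @examples
#' layouts <- build_liquid_layout(list(sprintf("g%02d", 1:60)), n_plates = 2)
#' sum(vapply(layouts, function(l) sum(l$genotype == "his3"), 0L))
#' @export
build_liquid_layout <- function(genotypes_per_plate, n_plates = 16L,
                                controls_per_plate = 36L,
                                control_label = "his3") {
  n_plates <- as.integer(n_plates)
  stopifnot(n_plates >= 1L, controls_per_plate >= 1L)
  if (!is.list(genotypes_per_plate)) genotypes_per_plate <- list(genotypes_per_plate)
  if (length(genotypes_per_plate) == 1L && n_plates > 1L) {
    genotypes_per_plate <- rep(genotypes_per_plate, n_plates)
  }
  if (length(genotypes_per_plate) != n_plates) {
    stop("genotypes_per_plate must supply one genotype vector per plate",
         call. = FALSE)
  }
  need <- 96L - as.integer(controls_per_plate)
  ord <- outer_frame_order(96L)
  lapply(seq_len(n_plates), function(i) {
    g <- as.character(genotypes_per_plate[[i]])
    if (length(g) != need) {
      stop("plate ", i, ": expected ", need, " query genotypes (96 - ",
           controls_per_plate, " controls), got ", length(g), call. = FALSE)
    }
    labels <- c(rep(control_label, controls_per_plate), g)
    plate_layout(
      plate_id = sprintf("L%02d", i),
      row = ord$row, col = ord$col, genotype = labels,
      format = 96L, design = "liquid"
    )
  })
}

#' Build solid-design 1536-position screen layouts
#'
#' Generates layouts for a pinned solid-agar screen. Each genotype receives
#' the replicate count given by `replicate_scheme` (default 8); the control
#' label defaults to 144 replicates. Positions are filled row-major and
#' overflow onto additional 1536-format plates.
#'
#' @param genotype_list character vector of query genotype labels.
#' @param replicate_scheme named integer vector mapping genotype to
#'   replicate count; unnamed genotypes get `default_replicates`. The
#'   control label gets `control_replicates` unless overridden explicitly.
#' @param control_label control genotype label (default `"his3"`).
#' @param default_replicates replicates per query genotype (default 8).
#' @param control_replicates replicates for the control (default 144).
#' @return A list of [plate_layout()] objects.
#' @export
build_solid_layout <- function(genotype_list, replicate_scheme = NULL,
                               control_label = "his3",
                               default_replicates = 8L,
                               control_replicates = 144L) {
  genotype_list <- as.character(genotype_list)
  if (!control_label %in% genotype_list) {
    genotype_list <- c(control_label, genotype_list)
  }
  reps <- stats::setNames(rep(as.integer(default_replicates),
                              length(genotype_list)), genotype_list)
  reps[control_label] <- as.integer(control_replicates)
  if (!is.null(replicate_scheme)) {
    if (is.null(names(replicate_scheme)) || any(names(replicate_scheme) == "")) {
      stop("replicate_scheme must be a named vector", call. = FALSE)
    }
    reps[names(replicate_scheme)] <- as.integer(replicate_scheme)
  }
  if (any(reps <= 0L)) {
    stop("replicate counts must be positive; offending genotype: ",
         names(reps)[reps <= 0L][1L], call. = FALSE)
  }
  labels <- rep(names(reps), reps)
  g <- plate_grid(1536L)
  per_plate <- g[["rows"]] * g[["cols"]]
  n_plates <- ceiling(length(labels) / per_plate)
  all_pos <- expand.grid(col = seq_len(g[["cols"]]), row = seq_len(g[["rows"]]))
  out <- vector("list", n_plates)
  for (i in seq_len(n_plates)) {
    idx <- ((i - 1L) * per_plate + 1L):min(i * per_plate, length(labels))
    k <- seq_along(idx)
    out[[i]] <- plate_layout(
      plate_id = sprintf("S%02d", i),
      row = all_pos$row[k], col = all_pos$col[k],
      genotype = labels[idx], format = 1536L, design = "solid"
    )
  }
  out
}

#' Write or read a plate layout table
#'
#' Layout files are tab-separated text with columns
#' `plate_id`, `row`, `col`, `genotype` and one comment header line
#' recording format and design.
#'
#' @param layouts a list of [plate_layout()] objects (or a single layout).
#' @param path file path.
#' @return `read_layout_table` returns a list of `plate_layout` objects.
#' @export
write_layout_table <- function(layouts, path) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  fmt <- attr(layouts[[1L]], "format")
  design <- attr(layouts[[1L]], "design")
  tab <- do.call(rbind, lapply(layouts, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#format=%d #design=%s", fmt, design), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_table
#' @export
read_layout_table <- function(path) {
  header <- readLines(path, n = 1L)
  fmt <- as.integer(sub(".*#format=([0-9]+).*", "\\1", header))
  design <- sub(".*#design=(\\w+).*", "\\1", header)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  lapply(split(tab, tab$plate_id), function(p) {
    plate_layout(p$plate_id, p$row, p$col, p$genotype, fmt, design)
  })
}
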