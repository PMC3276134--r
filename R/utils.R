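# Internal helpers: plate geometry, deterministic hashing, scoped RNG.

# Supported plate formats and their grids.
.plate_grids <- list(
  "96"   = c(rows = 8L,  cols = 12L),
  "384"  = c(rows = 16L, cols = 24L),
  "1536" = c(rows = 32L, cols = 48L)
)

plate_grid <- function(format) {
  key <- as.character(as.integer(format))
  g <- .plate_grids[[key]]
  if (is.null(g)) {
    stop("unsupported plate format: ", format,
         " (supported: 96, 384, 1536)", call. = FALSE)
  }
  g
}

#' @keywords internal
check_positions <- function(format, row, col) {
  g <- plate_grid(format)
  bad <- row < 1L | row > g[["rows"]] | col < 1L | col > g[["cols"]]
  if (any(bad)) {
    stop("position out of range for ", format, "-well format: row ",
         row[bad][1L], ", col ", col[bad][1L], call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic 31-adic string hash modulo a prime small enough that all
# intermediate products stay exact in double arithmetic. Used to derive
# per-culture RNG substreams keyed by (seed, plate, row, col) so that adding
# plates to a simulation never perturbs existing cultures.
.hash_prime <- 67108859  # largest prime < 2^26

string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% .hash_prime
  h
}

culture_seed <- function(seed, plate_id, row, col) {
  key <- paste(plate_id, row, col, sep = "\r")
  h <- string_hash(key)
  as.integer((h * 7919 + (seed %% .hash_prime) * 104729 + 1) %% 2147483629)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
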