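# Internal helpers: seed management and small validators.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb the session stream.
#' A `NULL` seed evaluates `expr` on the current stream.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a root seed and a stage tag
#'
#' Deterministic, stays below 2^31 so the result is a valid integer seed.
#' Distinct tags give distinct streams for the same root.
#' @param root integer root seed
#' @param tag character stage label
#' @return integer seed
#' @export
childSeed <- function(root, tag) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(tag))
  m <- 2147483629
  h <- 0
  for (k in utf8ToInt(paste(tag, collapse = "/")))
    h <- (h * 131 + k) %% m
  as.integer((((abs(root) %% m) * 48271) %% m + h) %% m) + 1L
}

# row/col <-> linear index helpers for matrices stored column-major,
# row 1 = southernmost row, y increasing with row index
cellRow <- function(idx, nr) (idx - 1L) %% nr + 1L
cellCol <- function(idx, nr) (idx - 1L) %/% nr + 1L

# 4-neighbourhood of linear indices within an nr x nc matrix
neighbors4 <- function(idx, nr, nc) {
  r <- cellRow(idx, nr); c <- cellCol(idx, nr)
  out <- c(idx[r > 1L] - 1L, idx[r < nr] + 1L,
           idx[c > 1L] - nr, idx[c < nc] + nr)
  out
}

# coordinates of cell centres (origin = lower-left corner of the grid)
cellCenters <- function(idx, nr, cell_size, origin) {
  cbind(x = origin[1] + (cellCol(idx, nr) - 0.5) * cell_size,
        y = origin[2] + (cellRow(idx, nr) - 0.5) * cell_size)
}

# linear index of the cell containing points (matrix xy), NA outside the grid
cellAt <- function(xy, nr, nc, cell_size, origin) {
  ci <- floor((xy[, 1] - origin[1]) / cell_size) + 1
  ri <- floor((xy[, 2] - origin[2]) / cell_size) + 1
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- rep(NA_integer_, nrow(xy))
  out[ok] <- as.integer((ci[ok] - 1) * nr + ri[ok])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
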