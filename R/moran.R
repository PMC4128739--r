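# Configurational heterogeneity: block aggregation and global Moran's I.

#' Aggregate a functional landscape into blocks of usable-habitat fraction
#'
#' Partitions the grid into square blocks and returns, per block, the
#' fraction of usable cells (any non-zero functional class). Partial blocks
#' at the north/east edges are dropped.
#'
#' @param landscape a functional-level \linkS4class{GridLandscape}
#' @param block_size_m block edge length in metres (default 100)
#' @return numeric matrix of usable fractions (one entry per block)
#' @export
aggregateToBlocks <- function(landscape, block_size_m = 100) {
  stopifnot(is(landscape, "GridLandscape"))
  if (landscapeLevel(landscape) != "functional")
    stop("aggregateToBlocks() expects a functional-level landscape")
  if (block_size_m < cellSize(landscape))
    stop("block_size_m must be at least the landscape cell size")
  bs <- as.integer(floor(block_size_m / cellSize(landscape)))
  u <- (classGrid(landscape) != 0L) + 0
  nbr <- nrow(u) %/% bs; nbc <- ncol(u) %/% bs
  if (nbr < 1L || nbc < 1L) stop("landscape smaller than one block")
  u <- u[seq_len(nbr * bs), seq_len(nbc * bs), drop = FALSE]
  # block means via two reshapes
  a <- array(u, dim = c(bs, nbr, bs * nbc))
  colsum <- colSums(a)                       # nbr x (bs*nbc)
  a2 <- array(t(colsum), dim = c(bs, nbc, nbr))
  t(colSums(a2)) / bs^2                      # nbr x nbc
}

#' Global Moran's I for a gridded field
#'
#' Computes global Moran's I with binary contiguity weights on a regular
#' block grid, its expectation -1/(n-1), and the analytical variance under
#' either the normality or the randomization (permutation-moment) null,
#' giving an asymptotically normal Z-score and two-sided p-value. Positive
#' Z indicates clumping of similar values (e.g. usable habitat aggregated in
#' blocks), Z near zero a random (interspersed) arrangement.
#'
#' @param values numeric matrix of block values (e.g. from
#'   \code{\link{aggregateToBlocks}})
#' @param weights `"rook"` (edge-sharing neighbours) or `"queen"` (adds
#'   diagonals)
#' @param null `"randomization"` (default) or `"normality"`
#' @return a \linkS4class{MoranResult}
#' @examples
#' checker <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
#' globalMoransI(checker)@I   # perfect alternation: exactly -1
#' @export
globalMoransI <- function(values, weights = c("rook", "queen"),
                          null = c("randomization", "normality")) {
  weights <- match.arg(weights)
  null <- match.arg(null)
  stopifnot(is.matrix(values))
  n <- length(values)
  if (n < 9L) stop("need at least 9 spatial units")
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("constant field: Moran's I undefined (zero variance)")
  nr <- nrow(values); nc <- ncol(values)

  # sum over ordered neighbour pairs of z_i z_j, and total weight W
  cross <- 2 * (sum(z[-nr, , drop = FALSE] * z[-1, , drop = FALSE]) +
                sum(z[, -nc, drop = FALSE] * z[, -1, drop = FALSE]))
  W <- 2 * ((nr - 1) * nc + nr * (nc - 1))
  deg <- matrix(4, nr, nc)
  deg[c(1, nr), ] <- deg[c(1, nr), ] - 1
  deg[, c(1, nc)] <- deg[, c(1, nc)] - 1
  if (weights == "queen") {
    cross <- cross + 2 * (sum(z[-nr, -nc, drop = FALSE] * z[-1, -1, drop = FALSE]) +
                          sum(z[-nr, -1, drop = FALSE] * z[-1, -nc, drop = FALSE]))
    W <- W + 4 * (nr - 1) * (nc - 1)
    dq <- matrix(4, nr, nc)
    dq[c(1, nr), ] <- dq[c(1, nr), ] - 2
    dq[, c(1, nc)] <- dq[, c(1, nc)] - 2
    dq[1, 1] <- dq[1, nc] <- dq[nr, 1] <- dq[nr, nc] <- 1
    deg <- deg + dq
  }
  I <- (n / W) * cross / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 2 * W            # binary symmetric weights: 0.5 * sum (w_ij+w_ji)^2
  S2 <- sum((2 * deg)^2) # row sum + column sum per unit
  varI <- if (null == "normality") {
    (n^2 * S1 - n * S2 + 3 * W^2) / (W^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / sum(z^2)^2
    (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
       b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
      ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  }
  zsc <- (I - EI) / sqrt(varI)
  p <- max(2 * pnorm(-abs(zsc)), .Machine$double.xmin)
  new("MoranResult", I = I, expectedI = EI, varianceI = varI, zScore = zsc,
      pValue = min(p, 1), nUnits = as.integer(n),
      weightsSpec = sprintf("binary %s contiguity, not row-standardized, %s null",
                            weights, null))
}
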