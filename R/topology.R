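#' Toroidal grid geometry
#'
#' Places an excitatory population on an `nrows` x `nrows` integer lattice
#' (spacing 1) and an inhibitory population, four times smaller, at the
#' centers of 2x2 cells of excitatory sites (offset lattice at +0.5 with
#' spacing 2).  The boundaries are periodic: the grid is a torus, so there
#' are no edge effects and every site is statistically equivalent.
#'
#' @param nrows even integer >= 8; side length of the grid in grid points.
#' @return An object of class `stas_grid` with components
#'   \item{nrows}{grid side length}
#'   \item{exc_positions}{`nrows^2` x 2 matrix of excitatory (x, y) coordinates}
#'   \item{inh_positions}{`nrows^2/4` x 2 matrix of inhibitory coordinates}
#'   \item{periodic}{always `TRUE`}
#' @examples
#' g <- build_grid(8)
#' nrow(g$exc_positions)  # 64
#' nrow(g$inh_positions)  # 16
#' @export
build_grid <- function(nrows) {
  if (length(nrows) != 1L || !is.finite(nrows) || nrows != as.integer(nrows))
    stop("`nrows` must be a single integer")
  nrows <- as.integer(nrows)
  if (nrows %% 2L != 0L || nrows < 8L)
    stop("`nrows` must be even and >= 8, got ", nrows)
  # x = column, y = row, both 0-based
  exc <- as.matrix(expand.grid(x = 0:(nrows - 1L), y = 0:(nrows - 1L)))
  inh <- as.matrix(expand.grid(
    x = seq(0.5, by = 2, length.out = nrows %/% 2L),
    y = seq(0.5, by = 2, length.out = nrows %/% 2L)
  ))
  storage.mode(exc) <- "double"
  structure(
    list(nrows = nrows, exc_positions = unname(exc),
         inh_positions = unname(inh), periodic = TRUE),
    class = "stas_grid"
  )
}

#' @method print stas_grid
#' @export
print.stas_grid <- function(x, ...) {
  cat("stas_grid: ", x$nrows, " x ", x$nrows, " torus, ",
      nrow(x$exc_positions), " excitatory / ",
      nrow(x$inh_positions), " inhibitory sites\n", sep = "")
  invisible(x)
}

#' Minimal-image (toroidal) Euclidean distance
#'
#' Distance between points on the `nrows` x `nrows` torus: each coordinate
#' difference is wrapped to `[-nrows/2, nrows/2]` before the Euclidean norm
#' is taken.  The result is symmetric and never exceeds `nrows * sqrt(2) / 2`.
#'
#' @param a,b numeric 2-vectors or n x 2 matrices of (x, y) coordinates.
#' @param nrows grid side length.
#' @return numeric vector of distances (grid points).
#' @export
toroidal_distance <- function(a, b, nrows) {
  a <- rbind(a); b <- rbind(b)
  d <- abs(a - b)
  d <- pmin(d, nrows - d)
  unname(sqrt(rowSums(d^2)))
}

# Wrapped coordinate differences b - a, mapped to (-nrows/2, nrows/2].
toroidal_delta <- function(a, b, nrows) {
  d <- (rbind(b) - rbind(a)) %% nrows
  d[d > nrows / 2] <- d[d > nrows / 2] - nrows
  dimnames(d) <- NULL
  d
}

#' Neurons inside a toroidal disk
#'
#' Returns the ids (row indices into the population's position matrix) of all
#' neurons whose minimal-image distance from `center` is at most `radius`
#' (closed disk).  Used for modulation patches (radius 6) and detection spots
#' (radius 2).
#'
#' @param center numeric 2-vector, disk center in grid coordinates.
#' @param radius positive disk radius in grid points.
#' @param geometry a [build_grid()] object.
#' @param population `"exc"` or `"inh"`.
#' @return integer vector of neuron ids (possibly empty).
#' @examples
#' g <- build_grid(100)
#' length(neurons_in_disk(c(50, 50), 6, g))  # 113
#' @export
neurons_in_disk <- function(center, radius, geometry, population = c("exc", "inh")) {
  population <- match.arg(population)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number")
  pos <- if (population == "exc") geometry$exc_positions else geometry$inh_positions
  d <- toroidal_distance(pos, matrix(center, nrow(pos), 2, byrow = TRUE),
                         geometry$nrows)
  which(d <= radius)
}
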