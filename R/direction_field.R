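# Spatially correlated preferred-direction field.
#
# Sequences require (1) each excitatory neuron to shift a small fraction of
# its outgoing targets along a preferred direction phi, and (2) phi of
# neighboring neurons to be similar.  Both are obtained by sampling a scalar
# 2D gradient-noise field on the torus and mapping its value linearly to an
# angle in [0, 2pi).

# Classic 2D lattice gradient noise (Perlin), vectorized, with the gradient
# lattice wrapped modulo `cells` so the field is exactly periodic on [0, cells).
# `px`, `py` are sample coordinates in lattice units.
perlin2d <- function(px, py, cells, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  theta <- matrix(stats::runif(cells * cells, 0, 2 * pi), cells, cells)
  gx <- cos(theta); gy <- sin(theta)

  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0;   fy <- py - y0
  # quintic fade for C2-continuous interpolation
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(fx); v <- fade(fy)

  corner <- function(ix, iy, dx, dy) {
    i <- (ix %% cells) + 1L
    j <- (iy %% cells) + 1L
    idx <- cbind(i, j)
    gx[idx] * dx + gy[idx] * dy
  }
  n00 <- corner(x0,      y0,      fx,     fy)
  n10 <- corner(x0 + 1L, y0,      fx - 1, fy)
  n01 <- corner(x0,      y0 + 1L, fx,     fy - 1)
  n11 <- corner(x0 + 1L, y0 + 1L, fx - 1, fy - 1)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

#' Sample a spatially correlated direction field
#'
#' Draws a scalar gradient-noise field on the torus and assigns every
#' excitatory neuron a preferred projection angle `phi`.  `noise_cells`
#' controls the spatial correlation length: few cells give large coherent
#' domains of similar `phi` (wide pathways); `noise_cells = nrows` decorrelates
#' neighboring neurons.  The gradient lattice is wrapped modulo `noise_cells`,
#' so the field is exactly periodic across the torus seam.
#'
#' The scalar noise value is mapped linearly from its observed `[min, max]`
#' onto `[0, 2*pi)`, which preserves the spatial smoothness of the field.
#'
#' @param geometry a [build_grid()] object.
#' @param noise_cells integer in `[2, nrows]`, gradient-noise cells per side.
#' @param seed integer RNG seed for the gradient vectors.
#' @return An object of class `stas_field`: list with `phi` (radians, one per
#'   excitatory neuron), `has_direction` (logical; `TRUE` for noise fields),
#'   `noise_cells`, and `seed`.
#' @export
sample_direction_field <- function(geometry, noise_cells, seed) {
  nrows <- geometry$nrows
  if (noise_cells < 2 || noise_cells > nrows)
    stop("`noise_cells` must be in [2, nrows]")
  pos <- geometry$exc_positions
  # sample at cell-interior points: lattice sites of the gradient grid have
  # value 0 by construction, so neurons are offset by half a grid spacing
  scale <- noise_cells / nrows
  val <- perlin2d((pos[, 1] + 0.5) * scale, (pos[, 2] + 0.5) * scale,
                  as.integer(noise_cells), seed)
  rng <- range(val)
  phi <- if (diff(rng) > 0) (val - rng[1]) / diff(rng) * 2 * pi else rep(0, length(val))
  phi[phi >= 2 * pi] <- 0
  structure(
    list(phi = phi, has_direction = rep(TRUE, length(phi)),
         noise_cells = as.integer(noise_cells), seed = seed),
    class = "stas_field"
  )
}

#' Circular (angular) correlation between two angle vectors
#'
#' Fisher-Lee circular correlation coefficient, used to quantify how similar
#' the preferred directions of neighboring neurons are (lag-1 smoothness of a
#' direction field).
#'
#' @param a,b numeric vectors of angles (radians), equal length.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  num <- sum(sin(a - mean_angle(a)) * sin(b - mean_angle(b)))
  den <- sqrt(sum(sin(a - mean_angle(a))^2) * sum(sin(b - mean_angle(b))^2))
  if (den == 0) return(0)
  num / den
}

mean_angle <- function(a) atan2(mean(sin(a)), mean(cos(a)))

#' Lag-1 circular correlation of a direction field
#'
#' Correlates every neuron's angle with that of its right-hand neighbor
#' (toroidal wrap), a scalar summary of the field's spatial smoothness.
#'
#' @param field a [sample_direction_field()] object.
#' @param geometry matching [build_grid()] object.
#' @return circular correlation at spatial lag 1.
#' @export
field_lag1_correlation <- function(field, geometry) {
  n <- geometry$nrows
  m <- matrix(field$phi, n, n)  # x varies fastest -> rows index x
  shifted <- m[c(2:n, 1), , drop = FALSE]
  circular_correlation(as.vector(m), as.vector(shifted))
}
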