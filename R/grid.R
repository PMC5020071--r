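#' Periodic square lattice for the neural field
#'
#' Discretizes the two-dimensional feature space on a flat torus. Nodes are
#' uniformly spaced with coordinates in `(-length/2, length/2]` per axis; all
#' displacement computations use the nearest periodic image.
#'
#' @param n_side Number of nodes per axis (>= 8).
#' @param length Domain extent per axis, in radians. Default `2*pi`.
#' @return An object of class `cann_grid`: a list with `n_side`, `length`,
#'   `spacing`, coordinate vector `x` (shared by both axes), coordinate
#'   matrices `X`, `Y` (node layout: rows index x, columns index y), and
#'   `cell_area`.
#' @examples
#' g <- build_grid(16)
#' g$spacing                     # 2*pi/16
#' range(g$x)                    # (-pi, pi]
#' @export
build_grid <- function(n_side, length = 2 * pi) {
  if (!is.numeric(n_side) || length(n_side) != 1L || n_side != round(n_side) ||
      n_side < 8) {
    stop("`n_side` must be a single integer >= 8", call. = FALSE)
  }
  if (!is.numeric(length) || length(length) != 1L || length <= 0) {
    stop("`length` must be a single positive number", call. = FALSE)
  }
  n_side <- as.integer(n_side)
  h <- length / n_side
  x <- -length / 2 + h * seq_len(n_side)      # in (-L/2, L/2]
  structure(
    list(
      n_side = n_side,
      length = length,
      spacing = h,
      x = x,
      X = matrix(x, n_side, n_side, byrow = FALSE),
      Y = matrix(x, n_side, n_side, byrow = TRUE),
      cell_area = h^2
    ),
    class = "cann_grid"
  )
}

#' @export
print.cann_grid <- function(x, ...) {
  cat(sprintf("<cann_grid> %d x %d nodes on (-%.4g, %.4g]^2, spacing %.4g\n",
              x$n_side, x$n_side, x$length / 2, x$length / 2, x$spacing))
  invisible(x)
}

#' Nearest-image displacement on the torus
#'
#' Maps displacements into `(-length/2, length/2]` so that distances between
#' points near opposite edges wrap correctly.
#'
#' @param d Numeric displacement(s), radians.
#' @param length Domain extent (radians).
#' @return Wrapped displacement(s) in `(-length/2, length/2]`.
#' @export
torus_diff <- function(d, length = 2 * pi) {
  w <- d - length * floor(d / length + 0.5)
  # floor-based wrap puts exactly -L/2 at the lower edge; fold onto +L/2
  w[w <= -length / 2] <- w[w <= -length / 2] + length
  w
}

same_grid <- function(a, b) {
  a$n_side == b$n_side && isTRUE(all.equal(a$length, b$length))
}

#' Gaussian recurrent interaction kernel on the torus
#'
#' Translation-invariant coupling
#' \deqn{J(\Delta) = \frac{J_0}{2\pi a^2}\exp\!\left(-\frac{|\Delta|^2}{2a^2}\right)}
#' evaluated at nearest-image lattice offsets and arranged for FFT-based
#' circular convolution (zero offset at index `[1, 1]`). The kernel's 2D FFT
#' is precomputed.
#'
#' @param grid A `cann_grid`.
#' @param J0 Coupling strength.
#' @param a Interaction range (radians), `a > 0` and well below `grid$length`.
#' @return An object of class `cann_kernel`: list with the kernel matrix `K`,
#'   its FFT `K_fft`, and `J0`, `a`.
#' @export
interaction_kernel <- function(grid, J0, a) {
  stopifnot(inherits(grid, "cann_grid"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("interaction range `a` must be positive", call. = FALSE)
  }
  offs <- torus_diff(grid$spacing * (seq_len(grid$n_side) - 1L), grid$length)
  D2 <- outer(offs^2, offs^2, `+`)
  K <- J0 / (2 * pi * a^2) * exp(-D2 / (2 * a^2))
  structure(list(K = K, K_fft = stats::fft(K), J0 = J0, a = a),
            class = "cann_kernel")
}

#' Circular convolution of a field with an interaction kernel
#'
#' Computes the Riemann sum \eqn{\sum_{x'} J(x - x') F(x')\,\Delta A} over the
#' torus via the discrete Fourier transform.
#'
#' @param kernel A `cann_kernel`.
#' @param field Matrix of per-node values on the same grid.
#' @param cell_area Lattice cell area (`grid$cell_area`).
#' @return Matrix of the same shape as `field`.
#' @export
circular_convolve <- function(kernel, field, cell_area) {
  n2 <- length(field)
  Re(stats::fft(kernel$K_fft * stats::fft(field), inverse = TRUE)) / n2 * cell_area
}
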