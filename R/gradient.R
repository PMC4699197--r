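# Signed vertical gradients and their conversion to graph edge weights.
# Large gradients of the requested polarity must yield small weights so
# that the minimum-weight path follows the strongest layer transition.

# Separable Gaussian smoothing with reflection padding.  Hand-rolled FIR:
# no general image-filtering package is available, and the kernel is tiny
# (truncated at 4 sigma).
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

convolve_axis <- function(mat, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (axis == 2L) return(t(convolve_axis(t(mat), kernel, 1L)))
  n <- nrow(mat)
  # reflect-pad rows, then weighted sum of shifted copies
  idx <- c(pmin(n, pmax(1L, rev(seq_len(r) + 1L))), seq_len(n),
           pmin(n, pmax(1L, n - seq_len(r))))
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Gaussian-smooth a B-scan
#'
#' Separable 2-D Gaussian filter (reflection padding, kernel truncated at
#' 4 sigma), used to suppress speckle before gradient computation.
#' `sigma = 0` returns the input unchanged.
#'
#' @param bscan Numeric matrix (depth rows x A-scan columns).
#' @param sigma Standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(bscan, sigma) {
  stopifnot(is.matrix(bscan), sigma >= 0)
  if (sigma == 0) return(bscan)
  k <- gaussian_kernel(sigma)
  convolve_axis(convolve_axis(bscan, k, 1L), k, 2L)
}

#' Signed vertical intensity gradient of a B-scan
#'
#' Central-difference derivative along the depth (row) axis after optional
#' Gaussian pre-smoothing; first-order one-sided differences at the top and
#' bottom rows.  Positive values mark dark-to-bright transitions (intensity
#' increasing with depth: dark above, bright below).
#'
#' @param bscan Numeric matrix (depth rows x A-scan columns), values in `[0,1]`.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels; 0 disables.
#' @return Signed gradient matrix, same shape as `bscan`.
#' @export
#' @examples
#' b <- rbind(matrix(0, 4, 3), matrix(1, 4, 3))
#' vertical_gradient(b, smooth_sigma = 0)[3:6, 1]
vertical_gradient <- function(bscan, smooth_sigma = 1) {
  stopifnot(is.matrix(bscan))
  n <- nrow(bscan)
  if (n < 3L) stop("B-scan must have at least 3 depth rows", call. = FALSE)
  if (smooth_sigma > 0) bscan <- gaussian_smooth(bscan, smooth_sigma)
  g <- matrix(0, n, ncol(bscan))
  g[1L, ] <- bscan[2L, ] - bscan[1L, ]
  g[n, ] <- bscan[n, ] - bscan[n - 1L, ]
  mid <- 2L:(n - 1L)
  g[mid, ] <- (bscan[mid + 1L, , drop = FALSE] - bscan[mid - 1L, , drop = FALSE]) / 2
  g
}

#' Rectify and normalize a signed gradient for one polarity
#'
#' Keeps only gradients of the requested sign (positive for dark-to-bright,
#' negative for bright-to-dark), then rescales by the B-scan's maximum
#' retained magnitude so the strongest transition maps to 1.  An all-zero
#' rectified gradient maps to an all-zero output.
#'
#' @param gradient Signed gradient matrix from [vertical_gradient()].
#' @param polarity `"DARK_TO_BRIGHT"` or `"BRIGHT_TO_DARK"`.
#' @return Matrix of normalized gradient magnitudes `g` in `[0, 1]`.
#' @export
normalized_gradient <- function(gradient, polarity = polarities()) {
  polarity <- match_polarity(polarity)
  stopifnot(is.matrix(gradient), all(is.finite(gradient)))
  g <- if (polarity == "DARK_TO_BRIGHT") pmax(gradient, 0) else pmax(-gradient, 0)
  m <- max(g)
  if (m > 0) g <- g / m
  g
}

#' Graph edge weight from two adjacent normalized gradients
#'
#' The weight of the edge joining two laterally adjacent graph nodes with
#' normalized gradient magnitudes `g_a` and `g_b`:
#' `w = 2 - (g_a + g_b) + w_min`.  Strictly positive, and strictly
#' decreasing in `g_a + g_b`, so large gradients yield small weights and the
#' minimum-weight path tracks the strongest transition of the chosen polarity.
#'
#' @param g_a,g_b Normalized gradients in `[0, 1]` (vectorized).
#' @param w_min Small positive weight floor (default `1e-5`).
#' @return Edge weight(s), `>= w_min`.
#' @export
#' @examples
#' edge_weight(1, 1)   # maximal gradient: weight floor
#' edge_weight(0, 0)   # no gradient: 2 + w_min
edge_weight <- function(g_a, g_b, w_min = 1e-5) {
  stopifnot(w_min > 0)
  2 - (g_a + g_b) + w_min
}
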