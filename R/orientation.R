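# Structure-tensor estimation of fiber orientations in 2D grayscale
# images, mirroring OrientationJ-style analysis (Gaussian window,
# cubic-spline gradients), and the 2D nematic order parameter.

# cubic B-spline prefilter along the columns of a matrix (recursive
# causal/anticausal filter, pole sqrt(3) - 2)
bspline_prefilter_cols <- function(m) {
  z1 <- sqrt(3) - 2
  n <- nrow(m)
  if (n < 2) {
    return(m * 6 / (1 + 4 + 1))
  }
  # causal init: truncated geometric sum of the leading samples
  k0 <- min(n, ceiling(log(1e-10) / log(abs(z1))))
  w <- z1^(seq_len(k0) - 1)
  init <- as.vector(w %*% m[seq_len(k0), , drop = FALSE])
  cplus <- m
  cplus[1, ] <- init
  for (i in 2:n) cplus[i, ] <- m[i, ] + z1 * cplus[i - 1, ]
  cminus <- cplus
  cminus[n, ] <- (z1 / (z1 * z1 - 1)) * (cplus[n, ] + z1 * cplus[n - 1, ])
  for (i in (n - 1):1) cminus[i, ] <- z1 * (cminus[i + 1, ] - cplus[i, ])
  6 * cminus
}

# separable convolution of matrix columns with a symmetric kernel,
# replicate-padded at the boundaries
conv_cols <- function(m, kern) {
  r <- (length(kern) - 1) %/% 2
  n <- nrow(m)
  pad <- rbind(
    m[rep(1, r), , drop = FALSE], m,
    m[rep(n, r), , drop = FALSE]
  )
  out <- stats::filter(pad, kern, sides = 2)
  matrix(out[(r + 1):(r + n), ], n, ncol(m))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Per-pixel fiber orientation by structure-tensor analysis
#'
#' Image gradients are computed from a cubic B-spline interpolation model
#' (recursive prefilter followed by the spline derivative kernel), their
#' outer products are smoothed with a Gaussian window of standard
#' deviation `window_sigma` pixels, and the local fiber orientation is
#' taken as the eigenvector of the smaller structure-tensor eigenvalue.
#' Per-pixel weights are coherence times energy; pixels with energy below
#' `energy_floor` times the image maximum are excluded (background
#' suppression).
#'
#' Angles are axial (theta and theta + pi are equivalent), measured from
#' the image x axis (columns) towards the y axis (rows), and reported in
#' `(-pi/2, pi/2]`.
#'
#' @param image numeric matrix (rows = y, columns = x), at least 32 x 32.
#' @param window_sigma Gaussian window, pixels (default 4).
#' @param energy_floor background-exclusion fraction of the maximum
#'   gradient energy (default 0.01).
#' @param n_bins number of angular histogram bins (default 180).
#' @return object of class `orientation_field`: list with `angles`
#'   (matrix), `weights` (matrix), `P_theta` (data.frame `theta`,
#'   `density`; normalized so that its integral is 1), `S2d`, and
#'   `valid` (FALSE for degenerate, e.g. constant, images).
#' @export
orientation_field <- function(image, window_sigma = 4, energy_floor = 0.01,
                              n_bins = 180) {
  image <- as.matrix(image)
  if (nrow(image) < 32 || ncol(image) < 32) {
    stop("image must be at least 32 x 32 pixels")
  }
  storage.mode(image) <- "double"
  # spline derivative kernel at integer offsets: g(i) = (c(i+1) - c(i-1))/2
  d_kern <- c(1 / 2, 0, -1 / 2) # stats::filter correlates, so reversed
  cy <- bspline_prefilter_cols(image)
  gy <- conv_cols(cy, d_kern) # gradient along rows (y)
  cx <- t(bspline_prefilter_cols(t(image)))
  gx <- t(conv_cols(t(cx), d_kern)) # gradient along columns (x)
  g <- gaussian_kernel(window_sigma)
  smooth2 <- function(m) t(conv_cols(t(conv_cols(m, g)), g))
  jxx <- smooth2(gx * gx)
  jyy <- smooth2(gy * gy)
  jxy <- smooth2(gx * gy)
  energy <- jxx + jyy
  coher <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / pmax(energy, 1e-300)
  # dominant gradient direction + pi/2 = fiber direction
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2
  theta <- ((theta + pi / 2) %% pi) - pi / 2 # fold to (-pi/2, pi/2]
  emax <- max(energy)
  weights <- coher * energy
  weights[energy < energy_floor * emax] <- 0
  # degenerate (e.g. constant) images carry no gradient energy beyond
  # numerical dust
  rng <- diff(range(image))
  valid <- rng > 0 && emax > (1e-8 * rng)^2 && sum(weights) > 0
  if (!valid) {
    warning("degenerate image: no oriented signal; P(theta) undefined")
    P <- data.frame(
      theta = seq(-pi / 2 + pi / n_bins / 2, pi / 2, length.out = n_bins),
      density = NA_real_
    )
    out <- list(
      angles = theta, weights = weights * 0, P_theta = P,
      S2d = NA_real_, valid = FALSE
    )
    class(out) <- "orientation_field"
    return(out)
  }
  bin_w <- pi / n_bins
  centers <- seq(-pi / 2 + bin_w / 2, pi / 2 - bin_w / 2, length.out = n_bins)
  idx <- pmin(n_bins, floor((as.vector(theta) + pi / 2) / bin_w) + 1)
  h <- vapply(
    split(as.vector(weights), factor(idx, levels = seq_len(n_bins))),
    sum, numeric(1)
  )
  dens <- h / (sum(h) * bin_w)
  P <- data.frame(theta = centers, density = as.numeric(dens))
  out <- list(
    angles = theta, weights = weights, P_theta = P,
    S2d = nematic_2d(P), valid = TRUE
  )
  class(out) <- "orientation_field"
  out
}

#' 2D nematic order parameter from an angular distribution
#'
#' Largest eigenvalue of the averaged 2D nematic tensor
#' `<Q2D> = integral P(theta) (2 t t' - I) dtheta` with
#' `t = (cos theta, sin theta)`, evaluated by quadrature over the
#' histogram bins. Equals 1 for a delta distribution, 0 for a uniform
#' one, and 0 for an equal mixture of two orthogonal deltas.
#'
#' @param P_theta data.frame with columns `theta` (bin centers, radians)
#'   and `density`, or an [orientation_field()] object. The distribution
#'   must be normalized (`sum(density) * bin_width = 1`); if not it is
#'   normalized with a warning.
#' @return scalar `S2d` in `[0, 1]`.
#' @export
#' @examples
#' th <- seq(-pi / 2 + pi / 360, pi / 2 - pi / 360, length.out = 180)
#' u <- data.frame(theta = th, density = rep(1 / pi, 180))
#' nematic_2d(u) # 0: isotropic
nematic_2d <- function(P_theta) {
  if (inherits(P_theta, "orientation_field")) P_theta <- P_theta$P_theta
  theta <- P_theta$theta
  dens <- P_theta$density
  if (anyNA(dens)) stop("undefined angular distribution")
  bin_w <- if (length(theta) > 1) theta[2] - theta[1] else pi
  tot <- sum(dens) * bin_w
  if (abs(tot - 1) > 1e-6) {
    warning("P(theta) not normalized (integral = ", signif(tot, 4),
            "); normalizing")
    dens <- dens / tot
  }
  a <- sum(dens * cos(2 * theta)) * bin_w
  b <- sum(dens * sin(2 * theta)) * bin_w
  q <- matrix(c(a, b, b, -a), 2, 2)
  max(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
}
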