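# Synthetic-data generation: idealized chain configurations with known
# orientation statistics, and micrograph-like renderings of simulated
# states. These fixtures are the closed-form oracles of the analysis
# stack; nothing is bundled as binary data, everything is generated.

#' Ideal spool configuration on a sphere
#'
#' Lays the chain along latitude circles of a sphere of radius
#' `R - sigma`, winding from pole to pole with an inter-ring spacing of
#' at least `sigma`. Bond angles are small, all mass sits in the
#' outermost radial shells, and within any octant sector the tangents are
#' nearly parallel, so the sector-resolved peripheral alignment is ~1
#' while the whole-shell pooled Q-tensor is planar-degenerate.
#'
#' @param n_turns number of latitude rings.
#' @param R sphere radius (model units).
#' @param sigma bond length.
#' @return list: `positions` (`N x 3`), `chain_id` (single chain).
#' @export
make_ideal_spool <- function(n_turns = 12, R = 12, sigma = 1) {
  r_sp <- R - sigma
  if (n_turns * sigma > pi * r_sp) {
    stop("rings would overlap: reduce n_turns or increase R")
  }
  # polar angles away from the poles, uniformly spaced
  th <- seq(pi / (n_turns + 1), pi - pi / (n_turns + 1), length.out = n_turns)
  pos <- NULL
  for (k in seq_len(n_turns)) {
    rho <- r_sp * sin(th[k])
    n_pts <- max(6, floor(2 * pi * rho / sigma))
    phi <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
    if (k %% 2 == 0) phi <- rev(phi) # alternate winding for short joins
    ring <- cbind(rho * cos(phi), rho * sin(phi), r_sp * cos(th[k]))
    pos <- rbind(pos, ring)
  }
  dimnames(pos) <- NULL
  list(positions = pos, chain_id = rep(1L, nrow(pos)))
}

#' Bundle of straight axial fibers
#'
#' Parallel fibers along +z arranged on a square grid, the geometric
#' idealization of a perfectly aligned state (alpha = 1, S2d = 1 in a
#' longitudinal section).
#'
#' @param n_fibers number of fibers.
#' @param length fiber length (monomer count per fiber = `length/sigma`).
#' @param spacing center-to-center fiber spacing.
#' @param sigma bond length.
#' @return list: `positions`, `chain_id` (one id per fiber).
#' @export
make_axial_bundle <- function(n_fibers = 9, length = 30, spacing = 2,
                              sigma = 1) {
  side <- ceiling(sqrt(n_fibers))
  n_mon <- max(2, round(length / sigma))
  z <- (seq_len(n_mon) - (n_mon + 1) / 2) * sigma
  pos <- NULL
  id <- integer(0)
  f <- 0L
  for (ix in seq_len(side)) {
    for (iy in seq_len(side)) {
      if (f >= n_fibers) break
      f <- f + 1L
      x0 <- (ix - (side + 1) / 2) * spacing
      y0 <- (iy - (side + 1) / 2) * spacing
      pos <- rbind(pos, cbind(x0, y0, z))
      id <- c(id, rep(f, n_mon))
    }
  }
  dimnames(pos) <- NULL
  list(positions = pos, chain_id = id)
}

#' Helically twisted fiber bundle
#'
#' Each fiber of an axial bundle is rotated about the common axis by an
#' angle growing linearly with z (`twist_per_length` radians per unit
#' length), producing the screw-like cross-section pattern of twisted
#' nuclei. With `twist_per_length = 0` this reduces to
#' [make_axial_bundle()].
#'
#' @inheritParams make_axial_bundle
#' @param twist_per_length twist rate, radians per unit length.
#' @return list: `positions`, `chain_id`, `twist_per_length`.
#' @export
make_twisted_bundle <- function(n_fibers = 9, length = 30,
                                twist_per_length = 0, spacing = 2,
                                sigma = 1) {
  b <- make_axial_bundle(n_fibers, length, spacing, sigma)
  z <- b$positions[, 3]
  phi <- twist_per_length * (z - min(z))
  x <- b$positions[, 1]
  y <- b$positions[, 2]
  b$positions <- unname(cbind(
    x * cos(phi) - y * sin(phi),
    x * sin(phi) + y * cos(phi), z
  ))
  b$twist_per_length <- twist_per_length
  b
}

#' Isotropic random-coil configuration
#'
#' Freely jointed unit-step random walk, optionally folded into a sphere
#' by rejection; its rendered sections are the isotropy control of the
#' image pipeline.
#'
#' @param n_monomers walk length.
#' @param seed RNG seed.
#' @return list: `positions`, `chain_id`.
#' @export
make_random_coil <- function(n_monomers = 500, seed = 1L) {
  pos <- with_seed(seed, {
    steps <- matrix(rnorm(3 * (n_monomers - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  })
  list(positions = pos, chain_id = rep(1L, n_monomers))
}

#' Render a planar section of a particle configuration
#'
#' Monomers within `thickness/2` of the section plane are splatted as
#' disks of diameter `sigma`, at `px_per_sigma` pixels per model length
#' unit, then blurred with a Gaussian PSF and overlaid with Gaussian
#' noise. Deterministic for a given seed. Emulates a micrograph of a
#' thin longitudinal or transverse section.
#'
#' @param positions `N x 3` matrix (or a list with a `positions` field,
#'   or a [system_state()] whose monomers are rendered).
#' @param plane `"xz"`, `"yz"` or `"xy"`: the two axes kept in the image
#'   (the third is sectioned).
#' @param offset position of the section plane along the sectioned axis.
#' @param thickness slab thickness.
#' @param px_per_sigma image sampling (default 6 px per fiber diameter).
#' @param psf_sigma Gaussian blur, pixels.
#' @param noise_sigma Gaussian noise amplitude relative to the disk
#'   intensity (1).
#' @param pad margin around the particle cloud, model units.
#' @param seed RNG seed for the noise.
#' @return numeric image matrix in `[0, ~1+noise]`, rows = y/second axis,
#'   columns = x/first axis; empty slabs give a blank image with a
#'   warning.
#' @export
render_section <- function(positions, plane = c("xz", "yz", "xy"),
                           offset = 0, thickness = 2, px_per_sigma = 6,
                           psf_sigma = 1, noise_sigma = 0.05, pad = 2,
                           seed = 1L) {
  plane <- match.arg(plane)
  if (inherits(positions, "system_state")) {
    positions <- monomer_positions(positions)
  }
  if (is.list(positions) && !is.null(positions$positions)) {
    positions <- positions$positions
  }
  positions <- as.matrix(positions)
  ax <- switch(plane, xz = c(1, 3, 2), yz = c(2, 3, 1), xy = c(1, 2, 3))
  keep <- abs(positions[, ax[3]] - offset) <= thickness / 2
  u <- positions[keep, ax[1]]
  v <- positions[keep, ax[2]]
  if (length(u) == 0) {
    warning("empty slab: no particle intersects the section")
    return(matrix(0, 64, 64))
  }
  lim_u <- range(u) + c(-pad, pad)
  lim_v <- range(v) + c(-pad, pad)
  n_col <- max(32, ceiling(diff(lim_u) * px_per_sigma))
  n_row <- max(32, ceiling(diff(lim_v) * px_per_sigma))
  img <- matrix(0, n_row, n_col)
  rad <- px_per_sigma / 2
  ir <- ceiling(rad)
  disk_off <- expand.grid(dy = -ir:ir, dx = -ir:ir)
  disk_off <- disk_off[disk_off$dx^2 + disk_off$dy^2 <= rad^2, ]
  ci <- pmin(n_col, pmax(1, round((u - lim_u[1]) * px_per_sigma)))
  ri <- pmin(n_row, pmax(1, round((v - lim_v[1]) * px_per_sigma)))
  for (k in seq_along(ci)) {
    rr <- ri[k] + disk_off$dy
    cc <- ci[k] + disk_off$dx
    ok <- rr >= 1 & rr <= n_row & cc >= 1 & cc <= n_col
    img[cbind(rr[ok], cc[ok])] <- 1
  }
  if (psf_sigma > 0) {
    g <- gaussian_kernel(psf_sigma)
    img <- t(conv_cols(t(conv_cols(img, g)), g))
  }
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, matrix(
      rnorm(length(img), sd = noise_sigma), n_row, n_col
    ))
  }
  img
}

#' Synthetic stripe and noise test images
#'
#' `stripe_image` renders a sinusoidal grating whose fiber direction
#' makes the given angle with the image x axis; `noise_image` is white
#' Gaussian noise. Both are closed-form oracles for the orientation
#' pipeline.
#'
#' @param width,height image size in pixels.
#' @param angle fiber (stripe) direction, radians from the x axis.
#' @param period stripe period, pixels.
#' @param seed RNG seed (noise image).
#' @return numeric image matrix.
#' @export
stripe_image <- function(width = 128, height = 128, angle = 0, period = 8) {
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), width), height, width)
  # intensity varies along the normal to the fiber direction
  n <- c(-sin(angle), cos(angle))
  0.5 + 0.5 * sin(2 * pi * (x * n[1] + y * n[2]) / period)
}

#' @rdname stripe_image
#' @export
noise_image <- function(width = 256, height = 256, seed = 1L) {
  with_seed(seed, matrix(rnorm(width * height), height, width))
}

#' Read / write grayscale images
#'
#' Thin wrappers over the `png`/`tiff` packages keyed on the file
#' extension; images are clamped to `[0, 1]` on write.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image numeric matrix.
#' @return `read_image` returns a matrix; `write_image` returns `path`.
#' @export
write_image <- function(image, path) {
  img <- image
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package png required")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package tiff required")
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package png required")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package tiff required")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
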