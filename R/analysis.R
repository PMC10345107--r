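# Orientational order and density quantification of simulated states.

#' Landau-de Gennes Q-tensor of a set of bond vectors
#'
#' `Q = < (3 t t' - I) / 2 >` over normalized bond vectors `t`; head-tail
#' symmetry is built in (t and -t contribute identically). The tensor is
#' symmetric and traceless to machine precision.
#'
#' @param bonds `n x 3` matrix of bond vectors; zero-length bonds are
#'   excluded with a warning.
#' @return 3x3 symmetric traceless matrix.
#' @export
#' @examples
#' q_tensor_3d(matrix(c(0, 0, 1), 1))  # eigenvalues -1/2, -1/2, 1
q_tensor_3d <- function(bonds) {
  bonds <- matrix(as.numeric(bonds), ncol = 3)
  n <- sqrt(rowSums(bonds^2))
  if (any(n == 0)) {
    warning(sum(n == 0), " zero-length bond(s) excluded")
    bonds <- bonds[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  if (nrow(bonds) == 0) stop("need at least one non-zero bond vector")
  t <- bonds / n
  (3 * crossprod(t) / nrow(t) - diag(3)) / 2
}

#' Alignment parameter from a Q-tensor
#'
#' `alpha = 2 (lambda3 - lambda2) / 3` with ascending eigenvalues; 0 for
#' an isotropic or degenerate (planar) distribution, 1 for perfect
#' uniaxial alignment.
#'
#' @param Q a 3x3 Q-tensor.
#' @return scalar in `[0, 1]`.
#' @export
alignment_from_q <- function(Q) {
  ev <- sort(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  max(0, min(1, 2 * (ev[3] - ev[2]) / 3))
}

resolve_bonds <- function(x, mid = NULL) {
  if (inherits(x, "system_state")) {
    cb <- chain_bonds(x)
    list(bonds = cb$bonds, mid = cb$mid, R = x$params$R,
         center = nucleus_center(x))
  } else {
    list(bonds = as.matrix(x), mid = mid, R = NULL, center = NULL)
  }
}

#' Radial profile of local nematic alignment
#'
#' The nucleus is partitioned into `n_shells` concentric equal-volume
#' shells, each subdivided into `n_sectors` equal-solid-angle angular
#' sectors (latitude bands of equal `cos(theta)` width split into
#' longitude bins; the default 8 gives the octants, so the element count
#' is of order 100); a Q-tensor is accumulated per element from the
#' bonds whose midpoint falls inside it, and `alpha(r)` is the mean of
#' the element alignments over each shell's occupied sectors. Elements
#' with no bonds are skipped; shells with no occupied element report
#' `NA`. Note that the sector size bounds the measurable alignment of
#' curved arrangements: the azimuthal tangents of an ideal spool span a
#' quarter turn inside an octant, capping alpha at ~0.64 there, while a
#' finer partition (e.g. `n_sectors = 32`) resolves them as nearly
#' parallel.
#'
#' @param x a [system_state()], or an `n x 3` matrix of bond vectors.
#' @param mid bond midpoint positions (required when `x` is a matrix).
#' @param R nuclear radius used for the partition.
#' @param n_shells number of equal-volume shells (default 10).
#' @param n_sectors angular sectors per shell (default 8 = octants;
#'   1 pools whole shells).
#' @param center nucleus center (default envelope centroid / origin).
#' @param min_bonds minimum bonds for an element to count (default 1).
#' @return data.frame of class `order_profile`: `radius` (shell midpoint,
#'   fraction of `R`), `alpha_r`, `n_bonds`.
#' @export
local_alignment <- function(x, mid = NULL, R = NULL, n_shells = 10,
                            n_sectors = 8, center = NULL, min_bonds = 1) {
  if (n_sectors < 1) stop("n_sectors must be at least 1")
  rb <- resolve_bonds(x, mid)
  if (is.null(R)) R <- rb$R
  if (is.null(center)) center <- if (is.null(rb$center)) c(0, 0, 0) else rb$center
  if (is.null(R)) stop("R must be supplied")
  bonds <- rb$bonds
  mid <- sweep(rb$mid, 2, center)
  r <- sqrt(rowSums(mid^2))
  # equal-volume shell boundaries; midpoints beyond R go to the last shell
  shell <- pmin(n_shells, floor(n_shells * pmin(r / R, 1 - 1e-12)^3) + 1)
  sector <- if (n_sectors == 1) {
    rep(1, nrow(mid))
  } else {
    # equal-area partition: bands uniform in cos(latitude), each split
    # into longitude bins (n_lat = 2, n_lon = 4 reproduces the octants)
    n_lat <- max(1L, floor(sqrt(n_sectors / 2)))
    n_lon <- max(1L, as.integer(round(n_sectors / n_lat)))
    ct <- mid[, 3] / pmax(r, 1e-300)
    band <- pmin(n_lat, floor(n_lat * (ct + 1) / 2) + 1)
    lon <- atan2(mid[, 2], mid[, 1]) # (-pi, pi]
    lbin <- pmin(n_lon, floor(n_lon * (lon + pi) / (2 * pi)) + 1)
    (band - 1) * n_lon + lbin
  }
  out <- data.frame(
    radius = ((seq_len(n_shells) - 0.5) / n_shells)^(1 / 3),
    alpha_r = NA_real_, n_bonds = 0L
  )
  for (s in seq_len(n_shells)) {
    in_shell <- shell == s
    out$n_bonds[s] <- sum(in_shell)
    if (!any(in_shell)) next
    alphas <- c()
    for (o in unique(sector[in_shell])) {
      sel <- in_shell & sector == o
      if (sum(sel) < min_bonds) next
      alphas <- c(alphas, alignment_from_q(q_tensor_3d(bonds[sel, , drop = FALSE])))
    }
    if (length(alphas) > 0) out$alpha_r[s] <- mean(alphas)
  }
  class(out) <- c("order_profile", class(out))
  out
}

#' Bulk and surface nematic alignment
#'
#' A single Q-tensor is accumulated over all bonds with midpoint at
#' radial distance below `cut * R` (bulk) and one over the rest
#' (surface), and each is reduced to the alignment parameter. An empty
#' region yields `NA`.
#'
#' @inheritParams local_alignment
#' @param cut bulk/surface threshold as a fraction of `R` (default 0.85).
#' @return list with `alpha_bulk`, `alpha_surface`, `n_bulk`, `n_surface`.
#' @export
bulk_surface_alignment <- function(x, mid = NULL, R = NULL, cut = 0.85,
                                   center = NULL) {
  rb <- resolve_bonds(x, mid)
  if (is.null(R)) R <- rb$R
  if (is.null(center)) center <- if (is.null(rb$center)) c(0, 0, 0) else rb$center
  if (is.null(R)) stop("R must be supplied")
  m <- sweep(rb$mid, 2, center)
  r <- sqrt(rowSums(m^2))
  bulk <- r < cut * R
  a <- function(sel) {
    if (!any(sel)) {
      return(NA_real_)
    }
    alignment_from_q(q_tensor_3d(rb$bonds[sel, , drop = FALSE]))
  }
  list(
    alpha_bulk = a(bulk), alpha_surface = a(!bulk),
    n_bulk = sum(bulk), n_surface = sum(!bulk)
  )
}

#' Radius accessible to monomer centers
#'
#' Envelope vertices sit at radius ~`R` and repel monomers within
#' `Sigma = r0 + sigma`, so monomer centers are confined to a ball of
#' radius about `R - Sigma` (states compressed against the wall can
#' push slightly past it; [radial_density()] folds such overflow into
#' its outermost shell). Radial profiles of scaled-down systems, whose
#' exclusion shell is proportionally fatter than at full scale, should
#' be normalized by this radius rather than by `R`.
#'
#' @param state a [system_state()] (or a `sim_params` object).
#' @return accessible radius in model units.
#' @export
accessible_radius <- function(state) {
  p <- if (inherits(state, "sim_params")) state else state$params
  p$R - p$Sigma_exc
}

#' Radial monomer density profile
#'
#' Monomer counts per equal-volume concentric shell, divided by the shell
#' volume and normalized by the mean nuclear concentration
#' `rho0 = N / (4/3 pi R^3)`. Monomers beyond `R` are counted in the
#' outermost shell, so the volume-weighted mean of `rho/rho0` is exactly 1
#' (counting identity).
#'
#' @param positions `N x 3` monomer positions (or a [system_state()]).
#' @param R nuclear radius.
#' @param n_shells number of equal-volume shells (>= 2).
#' @param center nucleus center.
#' @return data.frame: `radius` (shell midpoint as fraction of `R`),
#'   `rho_r` (normalized density), `n` (counts).
#' @export
radial_density <- function(positions, R = NULL, n_shells = 10,
                           center = NULL) {
  if (inherits(positions, "system_state")) {
    st <- positions
    positions <- monomer_positions(st)
    if (is.null(R)) R <- st$params$R
    if (is.null(center)) center <- nucleus_center(st)
  }
  if (is.null(center)) center <- c(0, 0, 0)
  if (n_shells < 2) stop("n_shells must be at least 2")
  pos <- sweep(as.matrix(positions), 2, center)
  r <- sqrt(rowSums(pos^2))
  shell <- pmin(n_shells, floor(n_shells * pmin(r / R, 1 - 1e-12)^3) + 1)
  counts <- tabulate(shell, nbins = n_shells)
  v_shell <- (4 / 3) * pi * R^3 / n_shells
  rho0 <- nrow(pos) / ((4 / 3) * pi * R^3)
  data.frame(
    radius = ((seq_len(n_shells) - 0.5) / n_shells)^(1 / 3),
    rho_r = counts / v_shell / rho0,
    n = counts
  )
}

#' Persistence length from tangent-tangent correlations
#'
#' Computes `C(s) = < t(i) . t(i+s) >` over all monomer offsets and all
#' supplied frames, and fits `log C(s) = -s b / l_p` (with `b` the
#' contour length per bond) over the window where the correlation
#' exceeds `exp(-2)` (and is positive). For the discrete worm-like chain
#' this recovers `l_p = -b / log(<cos theta>)`, which approaches
#' `k_bend sigma / kB T` in the stiff regime. With extensible bonds the
#' realized mean bond length exceeds the rest length (the harmonic bond
#' at stiffness 15 stretches to ~1.13 sigma at `kT`), so by default the
#' contour scale `b` is measured from the frames themselves.
#'
#' @param frames a `3 x N x n_frames` array (as stored by [md_run()]), a
#'   list of `N x 3` position matrices, or a single matrix.
#' @param sigma contour length per bond; `NULL` (default) uses the mean
#'   realized bond length of the supplied frames.
#' @param max_lag largest contour offset to correlate (default `N/2`).
#' @return list: `l_p`, `se` (standard error from the fit), `reliable`
#'   (FALSE when fewer than 3 usable lags or less than one decade of
#'   decay is observed), `bond_length` (the contour scale used),
#'   `correlation` (data.frame `lag`, `C`).
#' @export
persistence_length_estimate <- function(frames, sigma = NULL,
                                        max_lag = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) t(frames[, , k]))
  } else if (is.matrix(frames)) {
    frames <- list(frames)
  }
  nb <- nrow(frames[[1]]) - 1
  if (is.null(max_lag)) max_lag <- max(3, nb %/% 2)
  max_lag <- min(max_lag, nb - 1)
  acc <- numeric(max_lag)
  cnt <- numeric(max_lag)
  blen_sum <- 0
  blen_n <- 0
  for (f in frames) {
    b <- diff(f)
    bl <- sqrt(rowSums(b^2))
    blen_sum <- blen_sum + sum(bl)
    blen_n <- blen_n + length(bl)
    b <- b / bl
    for (lag in seq_len(max_lag)) {
      i <- seq_len(nrow(b) - lag)
      acc[lag] <- acc[lag] + sum(rowSums(b[i, , drop = FALSE] *
                                           b[i + lag, , drop = FALSE]))
      cnt[lag] <- cnt[lag] + length(i)
    }
  }
  C <- acc / cnt
  # leading contiguous window where the correlation is positive and above
  # the e^-2 floor
  drop <- which(C <= exp(-2) | C <= 0)
  end <- if (length(drop) > 0) drop[1] - 1 else max_lag
  reliable <- end >= 3
  usable <- seq_len(max(end, 1))
  if (end < 3) {
    usable <- which(C > 0)
    usable <- usable[seq_len(min(3, length(usable)))]
    reliable <- FALSE
  }
  if (length(usable) < 2) stop("too few positive correlations to fit")
  if (is.null(sigma)) sigma <- blen_sum / blen_n
  fit <- lm(log(C[usable]) ~ 0 + usable)
  slope <- coef(fit)[[1]]
  se <- tryCatch(summary(fit)$coefficients[1, 2], error = function(e) NA_real_)
  # a window with less than half a decade of decay (e.g. a rigid rod)
  # cannot anchor the exponential fit
  if (slope >= 0 || min(C[usable]) > exp(-0.5)) reliable <- FALSE
  l_p <- if (slope < 0) -sigma / slope else Inf
  list(
    l_p = l_p, se = if (is.na(se) || slope >= 0) NA_real_ else se * l_p / abs(slope),
    reliable = reliable, bond_length = sigma,
    correlation = data.frame(lag = seq_len(max_lag), C = C)
  )
}
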