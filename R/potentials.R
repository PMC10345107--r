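# Closed-form interaction potentials and their radial force laws.
# These are the reference implementations used for documentation, unit
# conversion and testing; the integrator evaluates the same expressions in
# compiled code.

#' Harmonic bond potential
#'
#' `U(r) = k/2 (r - rest)^2`, used for both the chromatin backbone
#' (stiffness `k_chrom`, rest length `sigma`) and the envelope springs
#' (stiffness `k_memb`, rest length `r0`).
#'
#' @param r separation (>= 0).
#' @param k spring stiffness (>= 0), energy/length^2.
#' @param rest rest length.
#' @return energy (or radial force for `harmonic_bond_force`, with the
#'   convention that a positive value pushes the pair apart).
#' @export
#' @examples
#' harmonic_bond_energy(2, k = 15, rest = 1)  # 7.5
harmonic_bond_energy <- function(r, k, rest = 1) {
  if (any(r < 0)) stop("separation r must be non-negative")
  if (any(k < 0)) stop("stiffness k must be non-negative")
  0.5 * k * (r - rest)^2
}

#' @rdname harmonic_bond_energy
#' @export
harmonic_bond_force <- function(r, k, rest = 1) {
  if (any(r < 0)) stop("separation r must be non-negative")
  if (any(k < 0)) stop("stiffness k must be non-negative")
  -k * (r - rest)
}

#' Truncated and shifted Lennard-Jones potential
#'
#' Purely repulsive (WCA-type) excluded-volume interaction with exclusion
#' radius `r_exc` and depth `eps`:
#' `U(r) = 4 eps ((r_exc/r)^12 - (r_exc/r)^6 + 1/4)` for
#' separations below `2^(1/6) r_exc`, zero beyond. Continuous at the
#' cutoff. Used
#' between unconnected envelope vertices (radius `r0`) and between
#' monomer-vertex pairs (radius `Sigma = r0 + sigma`, which makes the
#' triangulated mesh gap-free for the chain).
#'
#' The force diverges at vanishing separation; below `cap_frac * r_exc`
#' the magnitude
#' is capped at its value at `cap_frac * r_exc` for numerical robustness
#' (rare bad initializations), which leaves equilibrium statistics
#' untouched.
#'
#' @param r separation (> 0 for the energy; the capped force tolerates 0).
#' @param r_exc exclusion radius.
#' @param eps depth, energy units.
#' @param cap_frac force-capping fraction of `r_exc`.
#' @return energy, or radial force (positive = repulsive).
#' @export
#' @examples
#' lj_truncated_shifted_energy(1, r_exc = 1)          # = eps
#' lj_truncated_shifted_energy(2^(1/6), r_exc = 1)    # 0 at cutoff
lj_truncated_shifted_energy <- function(r, r_exc = 1, eps = 1,
                                        cap_frac = 0.05) {
  if (any(r <= 0)) stop("separation r must be positive")
  r <- pmax(r, cap_frac * r_exc)
  s6 <- (r_exc / r)^6
  ifelse(r < 2^(1 / 6) * r_exc, 4 * eps * (s6^2 - s6 + 0.25), 0)
}

#' @rdname lj_truncated_shifted_energy
#' @export
lj_truncated_shifted_force <- function(r, r_exc = 1, eps = 1,
                                       cap_frac = 0.05) {
  rr <- pmax(r, cap_frac * r_exc)
  s6 <- (r_exc / rr)^6
  ifelse(r < 2^(1 / 6) * r_exc, 24 * eps * (2 * s6^2 - s6) / rr, 0)
}

#' Soft (finite-barrier) repulsion between non-contiguous monomers
#'
#' `U(r) = eps_chrom (1 + (r/sigma)^12 (6 r^2/sigma^2 - 7))` for
#' separations below `sigma`, zero beyond; finite everywhere with
#' maximum `eps_chrom` at full overlap, and continuously differentiable
#' at the range boundary.
#' The finite barrier permits occasional strand crossing, emulating
#' moderate topoisomerase activity.
#'
#' @param r separation (>= 0).
#' @param sigma interaction range (monomer diameter).
#' @param eps_chrom barrier height, energy units.
#' @return energy, or radial force (positive = repulsive, zero at both
#'   zero separation and at/beyond `sigma`).
#' @export
#' @examples
#' soft_repulsion_energy(0, eps_chrom = 5)    # 5: full-overlap barrier
#' soft_repulsion_energy(1, eps_chrom = 5)    # 0 at the range
soft_repulsion_energy <- function(r, sigma = 1, eps_chrom = 5) {
  if (any(r < 0)) stop("separation r must be non-negative")
  s <- r / sigma
  ifelse(s < 1, eps_chrom * (1 + s^12 * (6 * s^2 - 7)), 0)
}

#' @rdname soft_repulsion_energy
#' @export
soft_repulsion_force <- function(r, sigma = 1, eps_chrom = 5) {
  s <- r / sigma
  ifelse(s < 1, 84 * eps_chrom * s^11 * (1 - s^2) / sigma, 0)
}

#' Angular bending potential
#'
#' `U(theta) = k_bend (1 - cos theta)` where `theta` is the deviation from
#' collinearity of the two bonds of a monomer triplet (`theta = 0` for a
#' straight chain). In the stiff regime this reproduces a worm-like chain
#' of persistence length `k_bend sigma / (kB T)`.
#'
#' @param theta bond angle in radians, in `[0, pi]`.
#' @param k_bend bending stiffness, energy units.
#' @return energy.
#' @export
#' @examples
#' bending_energy(pi / 2, 50)  # 50
bending_energy <- function(theta, k_bend) {
  k_bend * (1 - cos(theta))
}

#' Single-point evaluation of the full force field
#'
#' Evaluates all interaction forces of a system state (chain bonds, soft
#' repulsion, bending, envelope springs, vertex-vertex and monomer-vertex
#' exclusion, external/protocol forces). Mainly a testing and diagnostic
#' surface; the integrator computes the same forces internally.
#'
#' @param state a [system_state()] object.
#' @param method `"cell"` (Verlet/cell lists) or `"brute"` (all pairs).
#' @return list with `forces` ((N_m+N_v) x 3 matrix, monomers first),
#'   `potential` (total potential energy) and `n_capped` (number of
#'   force-cap events).
#' @export
total_forces <- function(state, method = c("cell", "brute")) {
  method <- match.arg(method)
  p <- state$params
  res <- cpp_system_forces(
    state$pos, state$N_m,
    state$chain_id, state$triplet_k, state$envelope$edges,
    state$envelope$edge_rest,
    state$extra_bonds, p$k_chrom, p$eps_chrom, p$k_memb, p$r0,
    p$Sigma_exc, 1.0, external_forces(state), method == "cell"
  )
  if (any(!is.finite(res$forces))) {
    stop("non-finite force encountered; state dumped to attribute 'frame'",
      call. = FALSE
    )
  }
  res
}
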