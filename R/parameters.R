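#' @useDynLib spoolsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov lm coef rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Physical constants (SI)
.kB <- 1.380649e-23 # J/K, exact

#' Simulation parameters for the chromatin/envelope model
#'
#' Container for every model constant, in reduced model units:
#' the unit of length is the fiber diameter `sigma` (30 nm), the unit of
#' energy is `epsilon = kB * T` at the reference temperature (293 K), the
#' monomer mass is 1 and the unit of time is `tau = sigma * sqrt(m/epsilon)`.
#' Defaults encode the full-scale model of cricket spermiogenesis: a single
#' chromatin fiber of `N_m = 10000` monomers (a fraction `f = 0.10` of the
#' genome) confined in an envelope of `N_v = 5560` vertices whose radius
#' `R = R_round * f^(1/3)` preserves the chromatin density of the round
#' spermatid nucleus.
#'
#' @param N_m number of chain monomers (>= 3).
#' @param N_v number of envelope vertices (>= 4).
#' @param sigma_nm fiber diameter in nm; sets the SI length conversion.
#' @param T_K reference temperature in K; sets the SI energy conversion.
#' @param k_chrom chain bond stiffness, `epsilon/sigma^2`.
#' @param eps_chrom soft-repulsion barrier height, `epsilon`. Finite, so
#'   strand crossing is rare but possible (moderate topoisomerase activity).
#' @param k_bend_max terminal bending stiffness, `epsilon`.
#' @param k_memb envelope spring stiffness, `epsilon/sigma^2`.
#' @param R_round round-spermatid nuclear radius, in `sigma`.
#' @param f simulated fraction of the total chromatin content.
#' @param R envelope radius in `sigma`; default `R_round * f^(1/3)`.
#' @param d_nucleation nucleation radius for the nucleated rigidification
#'   protocol, in `sigma` (150 nm at full scale).
#' @param N_spread number of monomers tagged on each side of a completed
#'   domain per spreading iteration.
#' @param F_max maximal polar stretch force, `epsilon/sigma`.
#' @param twist_total total torsional angle applied along the long axis, rad.
#' @param bulk_cut bulk/surface radial threshold, as a fraction of `R`.
#' @param gamma Langevin friction, `1/tau`.
#' @param dt integration timestep, `tau`.
#' @param seed integer RNG seed.
#'
#' @return object of class `sim_params` (a validated named list with the
#'   derived quantities `L = N_m * sigma`, `r0` (envelope spring rest
#'   length) and `Sigma_exc = r0 + sigma`).
#' @export
#' @examples
#' p <- sim_params(N_m = 500, N_v = 320)
#' p$L            # contour length in sigma
#' to_si(p$F_max, "force", p)  # N
sim_params <- function(N_m = 10000L, N_v = 5560L, sigma_nm = 30,
                       T_K = 293, k_chrom = 15, eps_chrom = 5,
                       k_bend_max = 50, k_memb = 2500,
                       R_round = 1500 / sigma_nm, f = 0.10,
                       R = R_round * f^(1 / 3),
                       d_nucleation = 150 / sigma_nm, N_spread = 10L,
                       F_max = 2e5, twist_total = 10 * pi,
                       bulk_cut = 0.85, gamma = 1, dt = 0.005,
                       seed = 1L) {
  p <- list(
    N_m = as.integer(N_m), N_v = as.integer(N_v), sigma = 1,
    sigma_nm = sigma_nm, T_K = T_K, epsilon = .kB * T_K,
    k_chrom = k_chrom, eps_chrom = eps_chrom, k_bend_max = k_bend_max,
    k_memb = k_memb, R_round = R_round, f = f, R = R,
    d_nucleation = d_nucleation, N_spread = as.integer(N_spread),
    F_max = F_max, twist_total = twist_total, bulk_cut = bulk_cut,
    gamma = gamma, dt = dt, seed = as.integer(seed)
  )
  p$L <- p$N_m * p$sigma
  p$r0 <- rest_length_from_geometry(p$R, p$N_v)
  p$Sigma_exc <- p$r0 + p$sigma
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Validate a parameter object
#'
#' Checks every invariant of a [sim_params()] object (positivity,
#' derived-quantity identities, the `(0,1)` range of `bulk_cut`) and
#' errors with a specific message on the first violation.
#'
#' @param p a `sim_params` object.
#' @return `p`, invisibly, when valid.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$sigma <= 0 || p$epsilon <= 0) {
    stop("sigma and epsilon must be positive")
  }
  if (p$N_m < 3) stop("N_m must be at least 3")
  if (p$N_v < 4) stop("N_v must be at least 4 (no closed triangulation)")
  for (k in c("k_chrom", "eps_chrom", "k_bend_max", "k_memb")) {
    if (p[[k]] < 0) stop(k, " must be non-negative")
  }
  if (p$bulk_cut <= 0 || p$bulk_cut >= 1) stop("bulk_cut must lie in (0,1)")
  if (p$T_K <= 0) stop("temperature must be positive")
  if (p$F_max < 0) stop("F_max must be non-negative")
  if (!isTRUE(all.equal(p$L, p$N_m * p$sigma))) stop("L must equal N_m * sigma")
  if (!isTRUE(all.equal(p$Sigma_exc, p$r0 + p$sigma))) {
    stop("Sigma_exc must equal r0 + sigma")
  }
  invisible(p)
}

#' Reduced-size parameter set preserving the model's dimensionless groups
#'
#' Scales the full model down to `n_m` monomers while preserving the
#' dimensionless groups that control the physics: the chain volume fraction
#' (so `R` scales as `(n_m/N_m)^(1/3)`), the stiffness-to-confinement ratio
#' `l_p/R` (so `k_bend_max` scales with `R`), the nucleation geometry `d/R`,
#' and the force-to-shell-elasticity ratio `F/(k_memb R)` (so `F_max`
#' scales with `R`). The vertex count defaults to a proportional mesh
#' (`N_v` scaled by `n_m/N_m`, rounded to a multiple of 10).
#'
#' @param base full-scale [sim_params()] object.
#' @param n_m reduced monomer count.
#' @param n_v optional reduced vertex count.
#' @param ... overrides forwarded to [sim_params()].
#' @return a `sim_params` object.
#' @export
#' @examples
#' scaled_params(sim_params(), n_m = 1000)
scaled_params <- function(base = sim_params(), n_m = 1000L, n_v = NULL, ...) {
  s <- (n_m / base$N_m)^(1 / 3)
  if (is.null(n_v)) n_v <- max(40L, as.integer(round(base$N_v * n_m / base$N_m / 10) * 10))
  sim_params(
    N_m = n_m, N_v = n_v, sigma_nm = base$sigma_nm, T_K = base$T_K,
    k_chrom = base$k_chrom, eps_chrom = base$eps_chrom,
    k_bend_max = base$k_bend_max * s, k_memb = base$k_memb,
    R_round = base$R_round, f = base$f, R = base$R * s,
    d_nucleation = base$d_nucleation * s, N_spread = base$N_spread,
    F_max = base$F_max * s, twist_total = base$twist_total,
    bulk_cut = base$bulk_cut, gamma = base$gamma, dt = base$dt,
    seed = base$seed, ...
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>  (model units: sigma = ", x$sigma_nm, " nm, epsilon = kB * ",
      x$T_K, " K)\n", sep = "")
  cat(sprintf("  chain:    N_m = %d, L = %g sigma, k_chrom = %g, eps_chrom = %g, k_bend_max = %g\n",
              x$N_m, x$L, x$k_chrom, x$eps_chrom, x$k_bend_max))
  cat(sprintf("  envelope: N_v = %d, R = %.3g sigma, r0 = %.3g sigma, k_memb = %g, Sigma = %.3g\n",
              x$N_v, x$R, x$r0, x$k_memb, x$Sigma_exc))
  cat(sprintf("  protocol: d_nucleation = %.3g, N_spread = %d, F_max = %g, twist = %.3g rad\n",
              x$d_nucleation, x$N_spread, x$F_max, x$twist_total))
  cat(sprintf("  dynamics: gamma = %g/tau, dt = %g tau, seed = %d\n",
              x$gamma, x$dt, x$seed))
  invisible(x)
}

#' Convert a model-unit quantity to SI
#'
#' Conversions use `sigma` = 30 nm (configurable), `epsilon = kB T` at
#' 293 K (about 4.045e-21 J), so the force unit `epsilon/sigma` is about
#' 0.135 pN and the stiffness unit `epsilon/sigma^2` about 4.5 uN/m.
#'
#' @param x numeric value(s) in model units.
#' @param kind one of `"length"`, `"energy"`, `"force"`, `"stiffness"`,
#'   `"time"` is not defined (the map to physical time is not part of the
#'   model) and raises an error like any unknown kind.
#' @param params a [sim_params()] object supplying `sigma_nm` and `T_K`.
#' @return value(s) in SI units (m, J, N, N/m).
#' @export
#' @examples
#' to_si(2e5, "force") * 1e9   # ~27 nN
#' to_si(1, "length") * 1e9    # 30 nm
to_si <- function(x, kind = c("length", "energy", "force", "stiffness"),
                  params = NULL) {
  if (length(kind) != 1 || !kind %in% c("length", "energy", "force", "stiffness")) {
    kind <- match.arg(kind)
  }
  sigma_m <- if (is.null(params)) 30e-9 else params$sigma_nm * 1e-9
  eps_J <- if (is.null(params)) .kB * 293 else params$epsilon
  switch(kind,
    length = x * sigma_m,
    energy = x * eps_J,
    force = x * eps_J / sigma_m,
    stiffness = x * eps_J / sigma_m^2
  )
}

#' Nominal persistence length of the discrete worm-like chain
#'
#' In the stiff regime of the angular potential `U = k_bend (1 - cos
#' theta)`, the persistence length is `l_p = k_bend * sigma / (kB T)`.
#' With the terminal stiffness 50 kB T and sigma = 30 nm this gives
#' 1.5 um, the value used for the mature (protamine-bound) fiber.
#'
#' @param k_bend bending stiffness in units of `kB T` (epsilon).
#' @param sigma bond length (default 1 model unit).
#' @param T_K temperature in K (enters only through the energy unit; the
#'   default convention `epsilon = kB T` makes the ratio unitless).
#' @return persistence length in the units of `sigma`.
#' @export
#' @examples
#' nominal_persistence_length(50)       # 50 sigma = 1.5 um
nominal_persistence_length <- function(k_bend, sigma = 1, T_K = 293) {
  if (T_K <= 0) stop("temperature must be positive")
  if (any(k_bend < 0)) stop("k_bend must be non-negative")
  k_bend * sigma # k_bend expressed in kB*T units
}

#' Fiber DNA linear density
#'
#' Back-of-envelope estimate used to calibrate the monomer content: a
#' genome of `genome_bp` base pairs stretched into `n_segments` linear
#' fiber segments of length `segment_um` micrometres each.
#'
#' @param genome_bp genome size in base pairs (cricket: 1.66e9).
#' @param n_segments number of linear fiber segments across the nucleus.
#' @param segment_um segment length in micrometres.
#' @return linear density in bp/nm.
#' @export
#' @examples
#' dna_linear_density()  # ~415 bp/nm
dna_linear_density <- function(genome_bp = 1.66e9, n_segments = 200,
                               segment_um = 20) {
  genome_bp / (n_segments * segment_um * 1e3)
}

#' Read / write parameter files
#'
#' Parameters are stored as a flat `key: value` YAML mapping; every field
#' of [sim_params()] is addressable and unknown keys are rejected.
#'
#' @param path file path.
#' @param params a `sim_params` object.
#' @return `read_params` returns a `sim_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_params))
  allowed <- setdiff(allowed, "...")
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  do.call(sim_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  keep <- intersect(names(formals(sim_params)), names(params))
  yaml::write_yaml(params[keep], path)
  invisible(path)
}
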