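# Langevin integration of a system state.

#' Advance a system state by Langevin dynamics
#'
#' BAOAB-discretized Langevin integration at `kT = 1` (the model energy
#' unit is `kB T`). With `gamma = 0` and `kT = 0` the scheme reduces to
#' velocity Verlet and conserves energy; with `kT = 0` and `gamma > 0` it
#' performs overdamped energy descent. Trajectories are exactly
#' reproducible: the RNG stream is derived from `state$params$seed` and a
#' per-call counter stored in the state.
#'
#' The step is validated against the stiffest spring in the system
#' (`dt < 0.1 * 2/omega_max`, with `omega_max = sqrt(max k)`), and the run
#' aborts with a diagnostic if any particle moves more than
#' `max_step_disp` in one step.
#'
#' @param state a [system_state()].
#' @param n_steps number of MD steps.
#' @param dt timestep (default `params$dt`).
#' @param gamma friction (default `params$gamma`).
#' @param kT thermostat temperature in model units (default 1).
#' @param frame_stride record a position frame every this many steps
#'   (0 = none).
#' @param trace_stride record energies/spring stretch every this many
#'   steps (0 = none).
#' @param max_step_disp instability threshold on per-step displacement.
#' @param max_spring_stretch abort threshold on envelope spring length, in
#'   units of `r0` (`Inf` disables the guard).
#' @param method `"cell"` or `"brute"` force evaluation.
#' @param skin Verlet-list skin width (model units).
#' @param v_clamp speed ceiling (model units): particle speeds are
#'   rescaled down to this value after the force kick. `Inf` (default)
#'   disables it; protocol stages with strong external forces use a
#'   generous ceiling (~20x thermal) purely as a safety valve against
#'   runaway kicks from rare hard overlaps. Clamp events are counted in
#'   `state$last_run$n_vclamp`.
#' @return the updated state; attributes of the run are stored in
#'   `state$last_run` (`frames` as a `3 x N x n_frames` array, `trace`,
#'   `steps_done`, `n_capped`).
#' @export
md_run <- function(state, n_steps, dt = NULL, gamma = NULL, kT = 1,
                   frame_stride = 0L, trace_stride = 0L,
                   max_step_disp = 0.5, max_spring_stretch = Inf,
                   method = c("cell", "brute"), skin = 0.7,
                   v_clamp = Inf) {
  method <- match.arg(method)
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  if (is.null(gamma)) gamma <- p$gamma
  # Verlet stability requires dt < 2/omega_max; keep a 2x safety margin
  kmax <- max(p$k_chrom, p$k_memb, 1)
  if (dt > 1 / sqrt(kmax)) {
    stop(sprintf(
      "dt = %g exceeds the stability bound %.4g set by the stiffest spring",
      dt, 1 / sqrt(kmax)
    ))
  }
  if (n_steps <= 0) {
    return(state)
  }
  seed <- derive_seed(p$seed, state$rng_calls)
  res <- cpp_run_md(
    state$pos, state$vel, state$N_m, state$chain_id, state$triplet_k,
    state$envelope$edges, state$envelope$edge_rest,
    state$extra_bonds, p$k_chrom, p$eps_chrom,
    p$k_memb, p$r0, p$Sigma_exc, 1.0, external_forces(state),
    as.integer(n_steps), dt, gamma, kT, seed,
    as.integer(frame_stride), as.integer(trace_stride),
    max_step_disp, max_spring_stretch, method == "cell", skin, v_clamp
  )
  if (res$aborted) {
    stop(sprintf(
      "dynamics aborted after %d steps: %s", res$steps_done,
      res$abort_reason
    ), call. = FALSE)
  }
  state$pos <- res$pos
  state$vel <- res$vel
  state$time <- state$time + res$steps_done * dt
  state$rng_calls <- state$rng_calls + 1L
  state$last_run <- list(
    frames = if (res$n_frames > 0) res$frames else NULL,
    trace = as.data.frame(res$trace), steps_done = res$steps_done,
    n_capped = res$n_capped, n_vclamp = res$n_vclamp
  )
  state
}

#' Candidate interaction pairs within a cutoff
#'
#' Cell-grid pair search with a brute-force all-pairs oracle, used by the
#' integrator internally and exposed for testing and analysis.
#'
#' @param positions `N x 3` matrix.
#' @param cutoff pair distance cutoff.
#' @param method `"cell"` or `"brute"`.
#' @return `K x 2` integer matrix of 1-based index pairs (`i < j`), in
#'   row-sorted order.
#' @export
neighbor_pairs <- function(positions, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) {
    return(matrix(integer(), 0, 2))
  }
  m <- if (method == "cell") {
    cpp_pairs_cell(positions, cutoff)
  } else {
    cpp_pairs_brute(positions, cutoff)
  }
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
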