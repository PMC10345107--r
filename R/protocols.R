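# Developmental protocols: relaxation, uniform and nucleated
# rigidification, nuclear elongation, twisting and decondensation.
# Each protocol consumes and returns a system_state, appending its
# per-increment observables to state$log.

#' Protocol schedule
#'
#' Step-count schedules are configuration, not physics: the published
#' full-scale runs use O(1e8) steps per increment, which scaled-down
#' systems do not need. Convergence is asserted on observables (density
#' flatness, order parameters), never on step counts.
#'
#' @param kind one of `"relax"`, `"rigidify_uniform"`,
#'   `"rigidify_nucleated"`, `"elongate"`, `"twist"`, `"decondense"`.
#' @param n_increments number of linear parameter increments (>= 1).
#' @param steps_per_increment MD steps after each increment (>= 1).
#' @param post_steps extra equilibration steps after the final increment.
#' @param ... protocol-specific fields (`d_nucleation`, `N_spread`,
#'   `F_max`, `twist_total`, `axis`, `max_spring_stretch`, `frame_stride`).
#' @return object of class `protocol_schedule`.
#' @export
schedule <- function(kind, n_increments = 1L, steps_per_increment = 1L,
                     post_steps = 0L, ...) {
  kinds <- c(
    "relax", "rigidify_uniform", "rigidify_nucleated", "elongate",
    "twist", "decondense"
  )
  if (!kind %in% kinds) stop("unknown schedule kind: ", kind)
  if (n_increments < 1 || steps_per_increment < 1) {
    stop("n_increments and steps_per_increment must be at least 1")
  }
  s <- c(
    list(
      kind = kind, n_increments = as.integer(n_increments),
      steps_per_increment = as.integer(steps_per_increment),
      post_steps = as.integer(post_steps)
    ),
    list(...)
  )
  class(s) <- "protocol_schedule"
  s
}

append_log <- function(state, name, value) {
  state$log[[name]] <- value
  state
}

#' Relax the flexible chain to a homogeneous density
#'
#' Runs plain Langevin dynamics of the untagged (zero-stiffness) chain in
#' the envelope. The radial density profile of the final configuration is
#' checked for flatness (every interior bin within 3 standard errors of
#' the mean) and the result is logged; non-convergence produces a warning
#' with diagnostics, not an error.
#'
#' @param state a [system_state()] with all bending stiffness zero.
#' @param sched a `"relax"` [schedule()]; total steps =
#'   `n_increments * steps_per_increment + post_steps`.
#' @return the relaxed state (`state$log$relaxation` holds the check).
#' @export
run_relaxation <- function(state, sched) {
  stopifnot(inherits(sched, "protocol_schedule"), sched$kind == "relax")
  if (any(state$triplet_k > 0)) {
    stop("relaxation expects a fully flexible chain (all stiffness zero)")
  }
  total <- sched$n_increments * sched$steps_per_increment + sched$post_steps
  if (total <= 0) {
    return(state)
  }
  state <- md_run(state, total)
  # flatness is judged over the volume accessible to monomer centers
  # (the monomer-vertex exclusion empties a shell of thickness ~r0+sigma)
  prof <- radial_density(
    monomer_positions(state), accessible_radius(state),
    n_shells = 6, center = nucleus_center(state)
  )
  inner <- prof$rho_r[seq_len(nrow(prof) - 1)] # outermost bin feels the wall
  se <- sd(inner) / sqrt(length(inner))
  flat <- max(abs(inner - mean(inner))) < 3 * max(se, 0.05)
  if (!flat) {
    warning(
      "relaxation may not have converged: radial density deviates by ",
      sprintf("%.2f", max(abs(inner - 1))), " from uniformity"
    )
  }
  append_log(state, "relaxation", list(profile = prof, flat = flat))
}

# per-triplet bending stiffness from the tag vector:
# rigid triplets carry k_max, triplets fully inside the ramping+rigid set
# carry the current ramp level, any triplet touching an untagged monomer
# stays exactly 0
triplet_stiffness <- function(tag, k_max, ramp_level) {
  n <- length(tag)
  k <- rep(0, n)
  if (n < 3) {
    return(k)
  }
  i <- 2:(n - 1)
  all_rigid <- tag[i - 1] == 2L & tag[i] == 2L & tag[i + 1] == 2L
  all_tagged <- tag[i - 1] > 0L & tag[i] > 0L & tag[i + 1] > 0L
  k[i][all_tagged] <- k_max * ramp_level
  k[i][all_rigid] <- k_max
  k
}

#' Uniform rigidification ramp
#'
#' Raises the bending stiffness of every triplet linearly from 0 to
#' `k_bend_max` in `n_increments` steps, equilibrating after each
#' increment. Models the genome-wide histone-to-protamine transition as a
#' spatially uniform stiffening.
#'
#' @param state a relaxed [system_state()].
#' @param sched a `"rigidify_uniform"` [schedule()].
#' @return state with all monomers rigid and every triplet at
#'   `k_bend_max`; `state$log$rigidify_uniform` holds the ramp trace.
#' @export
rigidify_uniform <- function(state, sched) {
  stopifnot(sched$kind == "rigidify_uniform")
  k_max <- state$params$k_bend_max
  n <- sched$n_increments
  trace <- data.frame(increment = seq_len(n), k_bend = NA_real_)
  for (i in seq_len(n)) {
    state$triplet_k <- rep(k_max * i / n, state$N_m)
    state$triplet_k[c(1, state$N_m)] <- 0 # chain ends carry no triplet
    state <- md_run(state, sched$steps_per_increment)
    trace$k_bend[i] <- k_max * i / n
  }
  state$tag <- rep(2L, state$N_m)
  if (sched$post_steps > 0) state <- md_run(state, sched$post_steps)
  append_log(state, "rigidify_uniform", trace)
}

# contiguous runs of rigid/tagged monomers as [start, end] intervals
tag_domains <- function(tagged) {
  r <- rle(tagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Nucleated rigidification with cis-spreading
#'
#' Emulates the nucleation-and-spreading pattern of histone H4
#' acetylation: monomers within `d_nucleation` of the nucleus center are
#' tagged first (the "acetylation factory"), their triplets ramp from 0
#' to `k_bend_max`, and on completion every rigid domain grows by
#' `N_spread` monomers on each side (domains that collide merge). The
#' cycle repeats until the whole chain is rigid. Untagged triplets stay
#' at exactly zero stiffness throughout.
#'
#' @param state a relaxed [system_state()].
#' @param sched a `"rigidify_nucleated"` [schedule()]; `n_increments` and
#'   `steps_per_increment` apply to each ramp cycle. Optional fields
#'   `d_nucleation` and `N_spread` override the parameter defaults.
#' @return fully rigid state; `state$log$rigidify_nucleated` holds the
#'   per-iteration tagged fraction trace.
#' @export
rigidify_nucleated <- function(state, sched) {
  stopifnot(sched$kind == "rigidify_nucleated")
  p <- state$params
  d <- if (!is.null(sched$d_nucleation)) sched$d_nucleation else p$d_nucleation
  n_spread <- if (!is.null(sched$N_spread)) sched$N_spread else p$N_spread
  k_max <- p$k_bend_max

  cen <- nucleus_center(state)
  r <- sqrt(rowSums(sweep(monomer_positions(state), 2, cen)^2))
  seed_tag <- r < d
  if (!any(seed_tag)) {
    stop("no monomer lies within d_nucleation of the nucleus center")
  }
  state$tag <- ifelse(seed_tag, 1L, 0L)
  trace <- data.frame(
    iteration = 0L, tagged_fraction = mean(state$tag > 0L),
    rigid_fraction = 0
  )

  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(sched$n_increments)) {
      state$triplet_k <- triplet_stiffness(state$tag, k_max,
                                           i / sched$n_increments)
      state <- md_run(state, sched$steps_per_increment)
    }
    state$tag[state$tag == 1L] <- 2L
    state$triplet_k <- triplet_stiffness(state$tag, k_max, 1)
    trace <- rbind(trace, data.frame(
      iteration = iter, tagged_fraction = mean(state$tag > 0L),
      rigid_fraction = mean(state$tag == 2L)
    ))
    if (all(state$tag == 2L)) break
    dom <- tag_domains(state$tag == 2L)
    for (k in seq_len(nrow(dom))) {
      lo <- max(1L, dom[k, 1] - n_spread)
      hi <- min(state$N_m, dom[k, 2] + n_spread)
      idx <- lo:hi
      state$tag[idx][state$tag[idx] == 0L] <- 1L # merging handled implicitly
    }
  }
  if (sched$post_steps > 0) state <- md_run(state, sched$post_steps)
  append_log(state, "rigidify_nucleated", trace)
}

#' Nuclear elongation under an antipodal force gradient
#'
#' Identifies the two pole vertices along the stretch axis, then ramps
#' the polar force magnitude linearly from 0 to `F_max` in
#' `n_increments`, equilibrating after each increment. The force pattern
#' (`F` on each pole, `F/2` on each pole neighbor, antisymmetric between
#' the two poles) is re-evaluated every increment; it stays attached to
#' the same vertices (fixed topology). The final state retains its forces
#' so that twisting can follow.
#'
#' @param state a rigidified [system_state()].
#' @param sched an `"elongate"` [schedule()]; optional fields `F_max`,
#'   `axis`, `max_spring_stretch` (abort guard on envelope springs, in
#'   units of `r0`; default `Inf`) and `trace_stride`.
#' @return elongated state; `state$log$elongation` holds per-increment
#'   force, envelope aspect ratio and bulk alignment.
#' @export
run_elongation <- function(state, sched) {
  stopifnot(sched$kind == "elongate")
  p <- state$params
  f_max <- if (!is.null(sched$F_max)) sched$F_max else p$F_max
  axis <- if (!is.null(sched$axis)) sched$axis else c(0, 0, 1)
  guard <- if (!is.null(sched$max_spring_stretch)) {
    sched$max_spring_stretch
  } else {
    Inf
  }
  vc <- if (!is.null(sched$v_clamp)) sched$v_clamp else 30

  ev <- list(vertices = vertex_positions(state), edges = state$envelope$edges)
  class(ev) <- "envelope_state"
  ev <- select_poles(ev, axis)
  state$envelope$stretch_axis <- ev$stretch_axis
  state$envelope$poles <- ev$poles

  n <- sched$n_increments
  trace <- data.frame(
    increment = seq_len(n), F = NA_real_, aspect_ratio = NA_real_,
    alpha_bulk = NA_real_
  )
  for (i in seq_len(n)) {
    state$envelope$stretch_F <- f_max * i / n
    state <- md_run(state, sched$steps_per_increment,
      trace_stride = max(1L, sched$steps_per_increment %/% 4L),
      max_spring_stretch = guard, v_clamp = vc
    )
    trace$F[i] <- state$envelope$stretch_F
    trace$aspect_ratio[i] <-
      envelope_shape_metrics(vertex_positions(state))$aspect_ratio
    ba <- bulk_surface_alignment(state)
    trace$alpha_bulk[i] <- ba$alpha_bulk
  }
  if (sched$post_steps > 0) {
    state <- md_run(state, sched$post_steps, max_spring_stretch = guard,
                    v_clamp = vc)
  }
  append_log(state, "elongation", trace)
}

#' Apply a uniform torsional field about the long axis
#'
#' Rotates every particle (monomers and vertices) about the stretch axis
#' by an angle growing linearly with its axial coordinate, from 0 at
#' `z_min` to `twist_total` at `z_max`; axial coordinates are unchanged.
#' The twist is a single instantaneous geometric transformation, after
#' which the caller typically relaxes the system (see
#' `steps_per_increment` on a `"twist"` schedule or [md_run()]).
#'
#' @param state an elongated [system_state()].
#' @param axis twist axis; defaults to the stored stretch axis.
#' @param twist_total total twist angle in radians (default
#'   `params$twist_total`, 10*pi).
#' @param particles `"all"` (default): monomers and vertices, the
#'   literal torsional field; `"chain"`: monomers only — since the
#'   envelope is axisymmetric about the twist axis, rotating its
#'   material points leaves the confinement unchanged while loading the
#'   coarse spring mesh with shear it cannot absorb at reduced scale,
#'   so reduced-scale protocols twist the chromatin alone.
#' @return twisted state.
#' @export
apply_twist <- function(state, axis = NULL, twist_total = NULL,
                        particles = c("all", "chain")) {
  particles <- match.arg(particles)
  if (is.null(axis)) axis <- state$envelope$stretch_axis
  if (is.null(twist_total)) twist_total <- state$params$twist_total
  u <- axis / sqrt(sum(axis^2))
  cen <- nucleus_center(state)
  idx <- if (particles == "chain") seq_len(state$N_m) else
    seq_len(nrow(state$pos))
  rel <- sweep(state$pos[idx, , drop = FALSE], 2, cen)
  zc <- as.vector(rel %*% u)
  zmin <- min(zc)
  zmax <- max(zc)
  if (zmax - zmin < .Machine$double.eps) {
    stop("degenerate axial extent: z_max equals z_min")
  }
  phi <- twist_total * (zc - zmin) / (zmax - zmin)
  # rotate the transverse component of each particle by phi about u
  axial <- outer(zc, u)
  trans <- rel - axial
  cross_u <- cbind(
    u[2] * trans[, 3] - u[3] * trans[, 2],
    u[3] * trans[, 1] - u[1] * trans[, 3],
    u[1] * trans[, 2] - u[2] * trans[, 1]
  )
  rot <- trans * cos(phi) + cross_u * sin(phi)
  state$pos[idx, ] <- sweep(axial + rot, 2, cen, `+`)
  state
}

#' Force release and recovery towards the spherical reference shape
#'
#' Sets all protocol forces to zero and follows the elastic recovery of
#' the envelope, recording the aspect-ratio trace. The envelope relaxes
#' towards its spherical rest state; the encapsulated rigid fiber can
#' transiently curl, which shows up as non-monotonic centerline
#' curvature in the recorded frames.
#'
#' @param state a twisted and/or elongated [system_state()].
#' @param sched a `"decondense"` [schedule()]; total steps =
#'   `n_increments * steps_per_increment`, traced every
#'   `steps_per_increment`.
#' @return recovered state; `state$log$decondensation` holds the
#'   aspect-ratio trace, `state$last_run$frames` the frames.
#' @export
run_decondensation <- function(state, sched) {
  stopifnot(sched$kind == "decondense")
  state$envelope$stretch_F <- 0
  vc <- if (!is.null(sched$v_clamp)) sched$v_clamp else 30
  n <- sched$n_increments
  trace <- data.frame(step = integer(n + 1), aspect_ratio = NA_real_)
  trace$aspect_ratio[1] <-
    envelope_shape_metrics(vertex_positions(state))$aspect_ratio
  for (i in seq_len(n)) {
    state <- md_run(state, sched$steps_per_increment, v_clamp = vc)
    trace$step[i + 1] <- i * sched$steps_per_increment
    trace$aspect_ratio[i + 1] <-
      envelope_shape_metrics(vertex_positions(state))$aspect_ratio
  }
  append_log(state, "decondensation", trace)
}
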