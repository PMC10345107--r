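# System state assembly: confined chain + envelope, with rigidification
# tags and protocol force bookkeeping.

# evaluate expr under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic per-call seed stream, kept below 2^31
derive_seed <- function(base, counter) {
  ((as.numeric(base) %% 2147483647) * 48271 +
     as.numeric(counter) * 16807) %% 2147483647 + 1
}

#' Initialize the chain as a dense self-avoiding walk in a sphere
#'
#' Monomers are grown as a random walk with unit (= `sigma`) steps,
#' rejecting placements that leave the ball of radius `R - sigma` or come
#' closer than `min_sep` to any earlier monomer, with bounded backtracking
#' in dense regions. By construction bond lengths are exactly `sigma`, no
#' pair is closer than `min_sep`, and every monomer lies strictly inside
#' `R - sigma`, so the walk needs no separate push-off relaxation.
#'
#' @param N_m number of monomers.
#' @param R confining radius (the envelope radius), model units.
#' @param seed RNG seed.
#' @param min_sep minimal pairwise clearance, model units.
#' @return `N_m x 3` matrix of monomer positions.
#' @export
initialize_chain <- function(N_m, R, seed = 1L, min_sep = 0.8) {
  if (N_m * pi / 6 >= 4 / 3 * pi * (R - 1)^3) {
    stop("chain volume exceeds the confining sphere; increase R or reduce N_m")
  }
  cpp_saw_chain(as.integer(N_m), R - 1, min_sep, seed, 200L)
}

#' Assemble a full system state
#'
#' Builds the envelope (vertex lattice + fixed topology) and the initial
#' chain conformation, and sets up the rigidification bookkeeping: all
#' monomers untagged, all triplet bending stiffnesses zero (the compliant
#' nucleosomal fiber).
#'
#' @param params a [sim_params()] object.
#' @param envelope_mode vertex placement, see [make_sphere_vertices()].
#' @param envelope_rest `"geometric"` (default): each envelope spring
#'   rests at its initial-state length, so the shell starts unstressed
#'   (the mean rest length equals the nominal `r0`); `"uniform"`: every
#'   spring rests at exactly `r0`, which leaves residual frustration from
#'   the lattice's spacing spread.
#' @return object of class `system_state` with fields `pos` (monomers
#'   first, then vertices), `vel`, `N_m`, `chain_id`, `tag` (0 =
#'   untagged, 1 = ramping, 2 = rigid), `triplet_k`, `extra_bonds`,
#'   `envelope` (topology and protocol forces), `time`, `rng_calls`.
#' @export
system_state <- function(params, envelope_mode = "deterministic",
                         envelope_rest = c("geometric", "uniform")) {
  envelope_rest <- match.arg(envelope_rest)
  env <- make_envelope(params, mode = envelope_mode)
  if (envelope_rest == "uniform") {
    env$edge_rest <- rep(params$r0, nrow(env$edges))
  }
  # grow the walk clear of the monomer-vertex exclusion shell (radius
  # Sigma = r0 + sigma around each vertex), not just of the wall itself
  chain <- initialize_chain(params$N_m, params$R - params$r0,
                            seed = params$seed)
  st <- list(
    params = params,
    pos = rbind(chain, env$vertices),
    vel = matrix(0, params$N_m + params$N_v, 3),
    N_m = params$N_m,
    chain_id = rep(1L, params$N_m),
    tag = rep(0L, params$N_m),
    triplet_k = rep(0, params$N_m),
    extra_bonds = matrix(integer(), 0, 2),
    envelope = list(
      edges = env$edges, faces = env$faces, r0 = env$r0, R = env$R,
      edge_rest = env$edge_rest, N_v = params$N_v,
      stretch_axis = c(0, 0, 1), stretch_F = 0, poles = NULL
    ),
    time = 0, rng_calls = 0L
  )
  class(st) <- "system_state"
  st
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "<system_state> N_m = %d, N_v = %d, t = %g tau, rigid %.1f%%, F = %g\n",
    x$N_m, x$envelope$N_v, x$time, 100 * mean(x$tag == 2L),
    x$envelope$stretch_F
  ))
  invisible(x)
}

#' Monomer / vertex coordinate views of a state
#'
#' @param state a `system_state`.
#' @return coordinate matrix (monomers or envelope vertices), or the
#'   envelope centroid for `nucleus_center`.
#' @export
monomer_positions <- function(state) state$pos[seq_len(state$N_m), , drop = FALSE]

#' @rdname monomer_positions
#' @export
vertex_positions <- function(state) {
  state$pos[-seq_len(state$N_m), , drop = FALSE]
}

#' @rdname monomer_positions
#' @export
nucleus_center <- function(state) colMeans(vertex_positions(state))

#' Chain bond vectors of a state
#'
#' @param state a `system_state`.
#' @param normalize return unit vectors?
#' @return list with `bonds` (matrix of bond vectors) and `mid`
#'   (bond midpoint positions), consecutive same-chain monomer pairs only.
#' @export
chain_bonds <- function(state, normalize = TRUE) {
  m <- monomer_positions(state)
  i <- seq_len(state$N_m - 1)
  keep <- state$chain_id[i] == state$chain_id[i + 1]
  b <- m[i + 1, , drop = FALSE] - m[i, , drop = FALSE]
  mid <- (m[i + 1, , drop = FALSE] + m[i, , drop = FALSE]) / 2
  b <- b[keep, , drop = FALSE]
  mid <- mid[keep, , drop = FALSE]
  if (normalize) {
    n <- sqrt(rowSums(b^2))
    ok <- n > 0
    b <- b[ok, , drop = FALSE] / n[ok]
    mid <- mid[ok, , drop = FALSE]
  }
  list(bonds = b, mid = mid)
}

# full per-particle external force matrix (protocol stretch forces).
# When the two poles have unequal neighbor counts the prescribed pattern
# has a net resultant ~F, which would drive a large center-of-mass drift;
# the residual is spread uniformly over all vertices (a ~F/N_v correction
# per vertex) so that the total applied force is exactly zero.
external_forces <- function(state) {
  out <- matrix(0, nrow(state$pos), 3)
  env <- state$envelope
  if (env$stretch_F > 0 && !is.null(env$poles)) {
    ev <- list(
      vertices = vertex_positions(state), edges = env$edges,
      stretch_axis = env$stretch_axis, poles = env$poles
    )
    class(ev) <- "envelope_state"
    fv <- stretch_forces(ev, env$stretch_F)
    fv <- sweep(fv, 2, colSums(fv) / nrow(fv))
    out[-seq_len(state$N_m), ] <- fv
  }
  out
}
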