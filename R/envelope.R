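# Construction and mechanics of the polymerized elastic shell that
# represents the nuclear envelope.

#' Distribute vertices on a sphere
#'
#' Deterministic mode uses a generalized Fibonacci spiral lattice, which
#' gives a seed-independent, quasi-uniform covering (and hence a
#' reproducible Delaunay topology); random mode samples the sphere
#' uniformly.
#'
#' @param N_v number of vertices (>= 4).
#' @param R sphere radius.
#' @param mode `"deterministic"` (Fibonacci lattice) or `"random"`.
#' @param seed RNG seed for random mode.
#' @return `N_v x 3` matrix of positions at distance `R` from the origin.
#' @export
#' @examples
#' v <- make_sphere_vertices(100, R = 10)
#' range(sqrt(rowSums(v^2)))  # all = 10
make_sphere_vertices <- function(N_v, R, mode = c("deterministic", "random"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (N_v < 4) stop("N_v must be at least 4 (no closed triangulation)")
  if (R <= 0) stop("R must be positive")
  if (mode == "deterministic") {
    i <- seq_len(N_v) - 0.5
    phi <- pi * (1 + sqrt(5)) * i       # golden-angle longitude
    cost <- 1 - 2 * i / N_v             # uniform in cos(theta)
    sint <- sqrt(pmax(0, 1 - cost^2))
    v <- cbind(sint * cos(phi), sint * sin(phi), cost)
  } else {
    v <- with_seed(seed, {
      g <- matrix(rnorm(3 * N_v), ncol = 3)
      g / sqrt(rowSums(g^2))
    })
  }
  v * R
}

#' Delaunay topology of a spherical vertex set
#'
#' For points in convex position on a sphere the Delaunay triangulation of
#' the surface equals the convex hull, computed here by an incremental
#' quickhull-style algorithm. The edge set satisfies Euler's relation
#' `|E| = 3 N_v - 6` for a closed triangulated sphere, which is asserted.
#'
#' @param vertices `N_v x 3` matrix of positions in convex position.
#' @return list with `faces` (`F x 3` integer matrix, 1-based) and
#'   `edges` (`E x 2` integer matrix, 1-based, each pair once with
#'   `edges[,1] < edges[,2]`).
#' @export
triangulate <- function(vertices) {
  faces <- cpp_convex_hull_faces(as.matrix(vertices))
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  n <- nrow(vertices)
  if (nrow(e) != 3 * n - 6) {
    stop(sprintf(
      "triangulation is not a closed sphere: %d edges for %d vertices (expected %d)",
      nrow(e), n, 3 * n - 6
    ))
  }
  deg <- tabulate(e, nbins = n)
  if (any(deg < 3)) stop("triangulation produced a vertex of degree < 3")
  list(faces = faces, edges = e)
}

#' Envelope spring rest length from mesh geometry
#'
#' The mean inter-vertex spacing of a uniform covering of a sphere of
#' radius `R` by `N_v` points: `r0 = sqrt(8 pi R^2 / (sqrt(3) N_v))`.
#'
#' @param R sphere radius.
#' @param N_v vertex count.
#' @return rest length in the units of `R`.
#' @export
#' @examples
#' rest_length_from_geometry(0.7e-6, 5560) * 1e9  # ~35.8 nm
rest_length_from_geometry <- function(R, N_v) {
  if (R <= 0) stop("R must be positive")
  if (N_v < 4) stop("N_v must be at least 4")
  sqrt(8 * pi * R^2 / (sqrt(3) * N_v))
}

#' Even out a spherical point lattice by tangential repulsion
#'
#' Deterministic steepest-descent relaxation of points on a sphere under
#' a short-range pairwise repulsion (the points stay on the sphere).
#' Evens out the inter-point spacing so that the edge lengths of the
#' subsequent triangulation cluster tightly around the nominal rest
#' length, which keeps the spring network nearly unstressed in the
#' initial state.
#'
#' @param vertices `N x 3` matrix of points on a sphere.
#' @param R sphere radius.
#' @param n_iter descent iterations.
#' @param step descent step size, in units of `r0^2`.
#' @return relaxed `N x 3` matrix, all points at radius `R`.
#' @export
relax_sphere_lattice <- function(vertices, R, n_iter = 100, step = 0.5) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  rounds <- max(1L, ceiling(n_iter / 50))
  good <- v
  for (r in seq_len(rounds)) {
    # Laplacian smoothing against the current Delaunay neighbors; if the
    # mesh ever degenerates (tiny lattices over-smooth), keep the last
    # triangulable configuration
    topo <- tryCatch(triangulate(v), error = function(e) NULL)
    if (is.null(topo)) {
      return(good)
    }
    good <- v
    e <- topo$edges
    both <- rbind(e, e[, 2:1])
    deg <- tabulate(both[, 1], nbins = n)
    for (it in seq_len(min(50L, n_iter))) {
      cent <- rowsum(v[both[, 2], , drop = FALSE], group = both[, 1]) / deg
      v_new <- (1 - step) * v + step * cent
      v_new <- v_new * (R / sqrt(rowSums(v_new^2)))
      moved <- max(abs(v_new - v))
      v <- v_new
      if (moved < 1e-5 * R) break
    }
    if (moved < 1e-5 * R) break
  }
  if (is.null(tryCatch(triangulate(v), error = function(e) NULL))) {
    return(good)
  }
  v
}

#' Construct an envelope state
#'
#' Builds the vertex lattice, its fixed Delaunay topology and the spring
#' rest length (from the mesh geometry unless overridden by
#' `params$r0`). The lattice is evened out by a short deterministic
#' on-sphere repulsive relaxation (see [relax_sphere_lattice()]) so that
#' the uniform spring rest length `r0` matches the realized edge lengths
#' closely and the shell starts essentially unstressed.
#'
#' @param params a [sim_params()] object.
#' @param mode vertex placement mode, see [make_sphere_vertices()].
#' @param lattice_iter relaxation iterations (0 disables).
#' @return list of class `envelope_state`: `vertices`, `edges`, `faces`,
#'   `r0`, `R`, `stretch_axis` (default +z), `stretch_F` (default 0),
#'   `poles` (NULL until [select_poles()] is applied).
#' @export
make_envelope <- function(params, mode = "deterministic",
                          lattice_iter = 400) {
  v <- make_sphere_vertices(params$N_v, params$R, mode = mode,
                            seed = params$seed)
  if (lattice_iter > 0) v <- relax_sphere_lattice(v, params$R, lattice_iter)
  topo <- triangulate(v)
  env <- list(
    vertices = v, edges = topo$edges, faces = topo$faces,
    r0 = params$r0, R = params$R,
    edge_rest = sqrt(rowSums((v[topo$edges[, 1], ] -
                                v[topo$edges[, 2], ])^2)),
    stretch_axis = c(0, 0, 1), stretch_F = 0, poles = NULL
  )
  class(env) <- "envelope_state"
  env
}

#' Select the antipodal pole vertices along a stretching axis
#'
#' The pole maximizing (resp. minimizing) the projection on the axis and
#' its topological neighbors receive the stretch force gradient. Ties are
#' broken by the lowest vertex index.
#'
#' @param envelope an `envelope_state`.
#' @param axis stretching axis (normalized internally).
#' @return the envelope with `poles = list(a, b, nbr_a, nbr_b)` and
#'   `stretch_axis` set.
#' @export
select_poles <- function(envelope, axis = c(0, 0, 1)) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be non-zero")
  axis <- axis / nrm
  proj <- as.vector(envelope$vertices %*% axis)
  a <- which(proj == max(proj))[1]
  b <- which(proj == min(proj))[1]
  nbrs <- function(i) {
    e <- envelope$edges
    sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])))
  }
  envelope$stretch_axis <- axis
  envelope$poles <- list(a = a, b = b, nbr_a = nbrs(a), nbr_b = nbrs(b))
  envelope
}

#' Per-vertex stretch force array
#'
#' Outward force `+F u` on the pole with the largest axis projection and
#' `+F/2 u` on each of its connected neighbors; the antipodal pole and its
#' neighbors receive the opposite forces. The total applied force vanishes
#' when the two poles have equal neighbor counts.
#'
#' @param envelope an `envelope_state` with poles selected.
#' @param F force magnitude (>= 0), `epsilon/sigma`.
#' @return `N_v x 3` matrix of per-vertex forces.
#' @export
stretch_forces <- function(envelope, F) {
  if (F < 0) stop("stretch force magnitude must be non-negative")
  if (is.null(envelope$poles)) stop("select_poles() must be applied first")
  out <- matrix(0, nrow(envelope$vertices), 3)
  u <- envelope$stretch_axis
  p <- envelope$poles
  out[p$a, ] <- F * u
  out[p$nbr_a, ] <- matrix(F / 2 * u, length(p$nbr_a), 3, byrow = TRUE)
  out[p$b, ] <- -F * u
  out[p$nbr_b, ] <- matrix(-F / 2 * u, length(p$nbr_b), 3, byrow = TRUE)
  out
}

#' Shape metrics of a vertex cloud
#'
#' Eigen-decomposition of the gyration tensor about the centroid.
#' `aspect_ratio = sqrt(lmax/lmin)` is 1 for a uniform spherical shell and
#' grows with elongation; `asphericity` is the normalized deviation
#' `(l1 - (l2+l3)/2) / (l1+l2+l3)`.
#'
#' @param vertices `N x 3` position matrix (>= 4 rows).
#' @return list: `aspect_ratio`, `asphericity`, `extents` (principal
#'   standard extents, descending), `centroid`.
#' @export
envelope_shape_metrics <- function(vertices) {
  if (nrow(vertices) < 4) stop("need at least 4 vertices")
  cen <- colMeans(vertices)
  d <- sweep(vertices, 2, cen)
  g <- crossprod(d) / nrow(d)
  ev <- sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(
    aspect_ratio = sqrt(ev[1] / max(ev[3], .Machine$double.eps)),
    asphericity = (ev[1] - 0.5 * (ev[2] + ev[3])) / max(sum(ev), .Machine$double.eps),
    extents = sqrt(ev),
    centroid = cen
  )
}

#' Export a triangle mesh as an OFF text file
#'
#' @param vertices `N x 3` matrix.
#' @param faces `F x 3` integer matrix (1-based).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_off_mesh <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(vertices), nrow(faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}
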