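# End-to-end orchestration of the developmental narrative:
# init -> relax -> rigidify (uniform | nucleated) -> elongate -> twist ->
# decondense, with per-stage checkpoints and metrics.

#' Default protocol schedules for a parameter set
#'
#' Step counts are sized for reduced systems (N_m ~ 500-2000); they are
#' plain configuration and can be scaled globally with `steps_scale`.
#' Increment counts follow the published protocol structure (tens of
#' linear increments per ramp).
#'
#' @param params a [sim_params()] object.
#' @param steps_scale global multiplier on steps-per-increment.
#' @return named list of [schedule()] objects.
#' @export
default_schedules <- function(params, steps_scale = 1) {
  s <- function(n) max(50L, as.integer(round(n * steps_scale)))
  list(
    relax = schedule("relax",
      n_increments = 1L,
      steps_per_increment = s(150000)
    ),
    rigidify_uniform = schedule("rigidify_uniform",
      n_increments = 20L, steps_per_increment = s(5000),
      post_steps = s(40000)
    ),
    rigidify_nucleated = schedule("rigidify_nucleated",
      n_increments = 6L, steps_per_increment = s(2000),
      post_steps = s(40000)
    ),
    elongate = schedule("elongate",
      n_increments = 40L, steps_per_increment = s(6000),
      post_steps = s(60000)
    ),
    twist = schedule("twist",
      n_increments = 1L, steps_per_increment = s(60000)
    ),
    decondense = schedule("decondense",
      n_increments = 20L, steps_per_increment = s(6000)
    )
  )
}

#' Run the full developmental pipeline
#'
#' Chains the simulation stages in their physiological order and returns
#' the per-stage states. Stages can be truncated with `through`; when
#' `out_dir` is given, each completed stage is checkpointed and its
#' metrics are written as CSV.
#'
#' @param params a [sim_params()] object (typically [scaled_params()]).
#' @param mode rigidification mode, `"nucleated"` (default) or
#'   `"uniform"`.
#' @param schedules named schedule list, see [default_schedules()].
#' @param through last stage to execute: one of `"relax"`, `"rigidify"`,
#'   `"elongate"`, `"twist"`, `"decondense"` (default).
#' @param out_dir optional output directory for checkpoints and metrics.
#' @param quiet suppress progress messages.
#' @return named list of stage states (`init`, `relax`, `rigidify`,
#'   `elongate`, `twist`, `decondense`, as far as requested).
#' @export
run_pipeline <- function(params, mode = c("nucleated", "uniform"),
                         schedules = default_schedules(params),
                         through = "decondense", out_dir = NULL,
                         quiet = FALSE) {
  mode <- match.arg(mode)
  stages <- c("relax", "rigidify", "elongate", "twist", "decondense")
  if (!through %in% stages) stop("unknown stage: ", through)
  n_through <- match(through, stages)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(state, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(state, file.path(out_dir, paste0(name, ".rds")))
      for (lg in names(state$log)) {
        if (is.data.frame(state$log[[lg]])) {
          write_metrics(state$log[[lg]],
            file.path(out_dir, paste0(name, "_", lg, ".csv")),
            meta = list(
              stage = name, seed = params$seed, N_m = params$N_m,
              N_v = params$N_v
            )
          )
        }
      }
    }
    state
  }

  out <- list()
  say("init: N_m = %d, N_v = %d, R = %.2f sigma", params$N_m, params$N_v,
      params$R)
  st <- system_state(params)
  out$init <- emit(st, "init")

  say("relax: %d steps", schedules$relax$n_increments *
        schedules$relax$steps_per_increment)
  st <- run_relaxation(st, schedules$relax)
  out$relax <- emit(st, "relax")
  if (n_through < 2) {
    return(out)
  }

  say("rigidify (%s)", mode)
  st <- if (mode == "nucleated") {
    rigidify_nucleated(st, schedules$rigidify_nucleated)
  } else {
    rigidify_uniform(st, schedules$rigidify_uniform)
  }
  out$rigidify <- emit(st, "rigidify")
  if (n_through < 3) {
    return(out)
  }

  say("elongate: ramp to F = %g over %d increments", params$F_max,
      schedules$elongate$n_increments)
  st <- run_elongation(st, schedules$elongate)
  out$elongate <- emit(st, "elongate")
  if (n_through < 4) {
    return(out)
  }

  say("twist: %.3g rad + %d relaxation steps", params$twist_total,
      schedules$twist$steps_per_increment)
  st <- apply_twist(st, particles = "chain")
  # settle the torsional shock at reduced dt before the normal relaxation
  st <- md_run(st, 10000, dt = 0.002, v_clamp = 10)
  st <- md_run(st, schedules$twist$n_increments *
                 schedules$twist$steps_per_increment, v_clamp = 30)
  out$twist <- emit(st, "twist")
  if (n_through < 5) {
    return(out)
  }

  say("decondense")
  st <- run_decondensation(st, schedules$decondense)
  out$decondense <- emit(st, "decondense")
  out
}
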