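# Trajectory, checkpoint and metrics serialization.

#' Write / read multi-frame trajectories (extended-XYZ-style text)
#'
#' Each frame is stored as: a particle-count line, a comment line of
#' `key=value` metadata, then one `species x y z tag` row per particle
#' (species `M` for monomers, `V` for envelope vertices). Coordinates are
#' written with 17 significant digits so that a read/write round trip is
#' exact in double precision.
#'
#' @param frames list of frames; each frame is a list with `pos`
#'   (`N x 3`), optional `species` (character) and `tag` (integer), and
#'   optional `meta` (named character/numeric for the comment line).
#'   A `3 x N x n_frames` array (as produced by [md_run()]) is also
#'   accepted.
#' @param path output file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a list of frames (`pos`, `species`, `tag`, `meta`).
#' @export
write_trajectory <- function(frames, path) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) {
      list(pos = t(frames[, , k]))
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    pos <- as.matrix(fr$pos)
    n <- nrow(pos)
    species <- if (!is.null(fr$species)) fr$species else rep("M", n)
    tag <- if (!is.null(fr$tag)) fr$tag else rep(0L, n)
    meta <- if (!is.null(fr$meta)) fr$meta else c()
    meta_str <- if (length(meta) > 0) {
      paste(sprintf("%s=%s", names(meta), vapply(meta, format, "")),
            collapse = " ")
    } else {
      "frame"
    }
    writeLines(as.character(n), con)
    writeLines(meta_str, con)
    if (n > 0) {
      writeLines(sprintf(
        "%s %.17g %.17g %.17g %d", species, pos[, 1], pos[, 2], pos[, 3],
        as.integer(tag)
      ), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  k <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    k <- k + 1
    if (is.na(n) || i + 1 + n > length(lines) + 1) {
      stop("corrupt trajectory at frame ", k, " (line ", i, ")")
    }
    meta_line <- lines[i + 1]
    rows <- lines[i + 1 + seq_len(n)]
    parts <- strsplit(rows, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 5)
    if (length(bad) > 0) {
      stop("corrupt trajectory at frame ", k, ", particle ", bad[1])
    }
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    frames[[k]] <- list(
      pos = m,
      species = vapply(parts, `[`, "", 1),
      tag = as.integer(vapply(parts, `[`, "", 5)),
      meta = meta_line
    )
    i <- i + 2 + n
  }
  frames
}

#' Checkpoint a full system state
#'
#' Binary container (RDS) carrying the complete [system_state()]
#' including protocol bookkeeping and the RNG call counter, so that
#' re-running a stage from a checkpoint reproduces it exactly.
#'
#' @param state a `system_state`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the state.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path)
  st <- readRDS(path)
  if (!inherits(st, "system_state")) stop("not a system_state checkpoint")
  st
}

#' Write a metrics table as CSV with commented header metadata
#'
#' @param df data.frame of observables.
#' @param path output path.
#' @param meta named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  read.csv(path, comment.char = "#")
}
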