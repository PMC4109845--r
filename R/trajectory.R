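#' Swarm trajectory container
#'
#' A `swarm_trajectory` holds the time-ordered 3D positions of N identified
#' individuals together with the acquisition metadata needed to put the
#' analysis in physical units: the frame rate (`fps`, 1/s) and the insect
#' body length (`body_length`, metres). Positions are in metres. Velocities
#' are attached per frame by [compute_velocities()].
#'
#' @param frames list of `swarm_frame` objects, ordered by `time_index`.
#' @param fps frames per second; must be > 0.
#' @param body_length body length in metres; must be > 0.
#' @param species_label free-text species annotation.
#' @param event_id free-text identifier of the swarming event.
#' @return An object of class `swarm_trajectory`.
#' @seealso [load_trajectory()], [compute_velocities()]
#' @export
swarm_trajectory <- function(frames, fps, body_length,
                             species_label = "", event_id = "") {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    swarm_stop("fps must be a single positive number", "swarm_integrity_error")
  if (!is.numeric(body_length) || length(body_length) != 1L || body_length <= 0)
    swarm_stop("body_length must be a single positive number",
               "swarm_integrity_error")
  idx <- vapply(frames, function(f) f$time_index, numeric(1))
  if (is.unsorted(idx, strictly = TRUE))
    swarm_stop("frame time indices must be strictly increasing",
               "swarm_integrity_error")
  structure(list(frames = frames, fps = fps, body_length = body_length,
                 species_label = species_label, event_id = event_id),
            class = "swarm_trajectory")
}

#' Single frame of a swarm trajectory
#'
#' @param time_index integer frame index (0-based physical time =
#'   `time_index / fps`).
#' @param positions N x 3 numeric matrix (metres), rownames are individual ids.
#' @param velocities optional N x 3 numeric matrix (m/s), row-aligned with
#'   `positions`; rows may be `NA` for individuals absent at the next frame.
#' @return An object of class `swarm_frame`.
#' @export
swarm_frame <- function(time_index, positions, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || nrow(positions) < 1L)
    swarm_stop("positions must be an N x 3 matrix with N >= 1",
               "swarm_integrity_error")
  if (!all(is.finite(positions)))
    swarm_stop("positions must be finite", "swarm_integrity_error")
  if (is.null(rownames(positions)))
    rownames(positions) <- as.character(seq_len(nrow(positions)))
  colnames(positions) <- NULL
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!identical(dim(velocities), dim(positions)))
      swarm_stop("velocities must align with positions", "swarm_integrity_error")
    rownames(velocities) <- rownames(positions)
  }
  structure(list(time_index = as.integer(time_index), positions = positions,
                 velocities = velocities),
            class = "swarm_frame")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  ns <- vapply(x$frames, function(f) nrow(f$positions), integer(1))
  cat(sprintf(
    "swarm_trajectory: %d frames, N = %s, fps = %g, body length = %g m\n",
    length(x$frames),
    if (length(unique(ns)) == 1L) as.character(ns[1]) else
      sprintf("%d-%d", min(ns), max(ns)),
    x$fps, x$body_length))
  if (nzchar(x$event_id)) cat("event:", x$event_id, "\n")
  if (nzchar(x$species_label)) cat("species:", x$species_label, "\n")
  invisible(x)
}

#' Read a trajectory table
#'
#' Reads a delimited text table with header columns `frame,id,x,y,z`
#' (coordinates in metres) and groups the rows into per-frame position
#' matrices sorted by frame index.
#'
#' @param path path to the delimited file (comma- or whitespace-separated).
#' @inheritParams swarm_trajectory
#' @return A [swarm_trajectory()].
#' @export
load_trajectory <- function(path, fps, body_length,
                            species_label = "", event_id = "") {
  raw <- tryCatch(
    utils::read.csv(path, header = TRUE, strip.white = TRUE),
    error = function(e) swarm_stop(
      sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
      "swarm_parse_error"))
  need <- c("frame", "id", "x", "y", "z")
  if (!all(need %in% names(raw)))
    swarm_stop(sprintf("missing columns: %s",
                       paste(setdiff(need, names(raw)), collapse = ", ")),
               "swarm_parse_error")
  for (cc in c("frame", "x", "y", "z")) {
    vals <- raw[[cc]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(vals))))
    if (length(bad))
      swarm_stop(sprintf("non-numeric value in column '%s' at data line %d",
                         cc, bad[1]), "swarm_parse_error")
    raw[[cc]] <- as.numeric(vals)
  }
  key <- paste(raw$frame, raw$id)
  if (anyDuplicated(key))
    swarm_stop(sprintf("duplicate (frame,id) row: (%s)",
                       key[anyDuplicated(key)]), "swarm_integrity_error")
  frames <- lapply(split(raw, raw$frame), function(d) {
    d <- d[order(d$id), ]
    pos <- as.matrix(d[, c("x", "y", "z")])
    rownames(pos) <- as.character(d$id)
    swarm_frame(d$frame[1], pos)
  })
  frames <- frames[order(as.numeric(names(frames)))]
  swarm_trajectory(unname(frames), fps = fps, body_length = body_length,
                   species_label = species_label, event_id = event_id)
}

#' Write a trajectory table
#'
#' Emits the same `frame,id,x,y,z` dialect that [load_trajectory()] reads,
#' so round-trips are lossless.
#'
#' @param traj a [swarm_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  tabs <- lapply(traj$frames, function(f)
    data.frame(frame = f$time_index, id = rownames(f$positions),
               x = f$positions[, 1], y = f$positions[, 2],
               z = f$positions[, 3]))
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach forward-difference velocities
#'
#' The velocity of individual i at frame t is the forward difference
#' `v_i(t) = (x_i(t+1) - x_i(t)) * fps`. The final frame carries no velocity
#' and is excluded from downstream per-frame statistics. Individuals absent
#' at t+1 get `NA` velocity rows for frame t (tracking gaps are excluded,
#' not interpolated).
#'
#' @param traj a [swarm_trajectory()] with at least 2 frames.
#' @return The trajectory with `velocities` filled on frames 1..T-1.
#' @export
compute_velocities <- function(traj) {
  nf <- length(traj$frames)
  if (nf < 2L)
    swarm_stop("need at least 2 frames to compute velocities",
               "swarm_degenerate_error")
  dts <- diff(vapply(traj$frames, function(f) f$time_index, numeric(1)))
  if (length(unique(dts)) != 1L)
    swarm_stop("frame spacing must be constant", "swarm_integrity_error")
  dt <- dts[1] / traj$fps
  for (t in seq_len(nf - 1L)) {
    f0 <- traj$frames[[t]]; f1 <- traj$frames[[t + 1L]]
    v <- matrix(NA_real_, nrow(f0$positions), 3L,
                dimnames = list(rownames(f0$positions), NULL))
    common <- intersect(rownames(f0$positions), rownames(f1$positions))
    v[common, ] <- (f1$positions[common, , drop = FALSE] -
                      f0$positions[common, , drop = FALSE]) / dt
    traj$frames[[t]]$velocities <- v
  }
  traj
}

#' Mean nearest-neighbour distance r1
#'
#' Average over individuals of the distance to their nearest neighbour;
#' the standard inverse proxy for swarm density.
#'
#' @param x a `swarm_frame` or an N x 3 position matrix, N >= 2.
#' @return r1 in the units of the positions (metres for field data).
#' @export
nearest_neighbour_distance <- function(x) {
  pos <- if (inherits(x, "swarm_frame")) x$positions else as.matrix(x)
  n <- nrow(pos)
  if (is.null(n) || n < 2L)
    swarm_stop("nearest-neighbour distance needs N >= 2",
               "swarm_degenerate_error")
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  mean(apply(dm, 1L, min))
}

#' Read a pairwise correlation sample file
#'
#' Parses the two-column numeric format used for published per-pair data:
#' pair distance in metres in the first column, the dimensionless scalar
#' product of the two velocity-fluctuation vectors in the second.
#'
#' @param path path to a whitespace- or comma-delimited two-column file.
#' @return A data.frame with columns `distance`, `dot` (possibly 0 rows).
#' @export
read_pairwise <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(distance = numeric(0), dot = numeric(0)))
  parse_line <- function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      swarm_stop(sprintf("non-numeric pairwise row at line %d", i),
                 "swarm_parse_error")
    vals[1:2]
  }
  m <- t(vapply(seq_along(lines), parse_line, numeric(2)))
  if (any(m[, 1] < 0))
    swarm_stop("pair distances must be non-negative", "swarm_integrity_error")
  data.frame(distance = m[, 1], dot = m[, 2])
}

#' Read an event metadata file
#'
#' YAML key-value file carrying the acquisition metadata of one swarming
#' event (`fps`, `body_length`, optional `species_label`, `event_id`), so
#' trajectory tables can be loaded with their physical units attached.
#'
#' @param path YAML file path.
#' @return named list with at least `fps` and `body_length`.
#' @export
read_event_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (need in c("fps", "body_length"))
    if (is.null(cfg[[need]]))
      swarm_stop(sprintf("event config misses '%s'", need),
                 "swarm_parse_error")
  cfg
}

#' Write pairwise samples in the two-column format
#'
#' @param samples data.frame with columns `distance`, `dot`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairwise <- function(samples, path) {
  writeLines(sprintf("%.10g %.10g", samples$distance, samples$dot), path)
  invisible(path)
}

# Internal: list of usable (x0, x1) position-matrix pairs over common ids.
# A pair is usable when both frames share >= 2 ids with finite positions.
traj_frame_pairs <- function(traj) {
  nf <- length(traj$frames)
  if (nf < 2L) return(list())
  out <- vector("list", nf - 1L)
  for (t in seq_len(nf - 1L)) {
    f0 <- traj$frames[[t]]; f1 <- traj$frames[[t + 1L]]
    common <- intersect(rownames(f0$positions), rownames(f1$positions))
    out[[t]] <- list(x0 = f0$positions[common, , drop = FALSE],
                     x1 = f1$positions[common, , drop = FALSE],
                     fps = traj$fps, time_index = f0$time_index)
  }
  out
}
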