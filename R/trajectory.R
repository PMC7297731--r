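#' Multi-frame trajectory of configurations
#'
#' An ordered collection of [mol_config()] frames with consistent point
#' counts and type labels, standing in for frames sampled at equal
#' intervals from a molecular dynamics run.
#'
#' @param frames list of `mol_config` objects.
#' @param metadata optional named list (concentration label, cutoff, ...).
#' @return A `mol_trajectory` object.
#' @export
mol_trajectory <- function(frames, metadata = list()) {
  if (length(frames) < 1L) abort("a trajectory needs at least one frame")
  ok <- vapply(frames, inherits, logical(1), "mol_config")
  if (!all(ok)) abort("all frames must be mol_config objects")
  types0 <- frames[[1L]]$type
  for (i in seq_along(frames)) {
    if (!identical(frames[[i]]$type, types0)) {
      abort(sprintf("frame %d has inconsistent type labels", i))
    }
  }
  structure(list(frames = frames, metadata = metadata),
            class = "mol_trajectory")
}

#' @rdname mol_trajectory
#' @param traj a `mol_trajectory`.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "mol_trajectory"))
  length(traj$frames)
}

#' Select equally spaced frames
#'
#' Picks `f` frames at (approximately) equal intervals, always including
#' the first and last frame; the default of 101 frames mirrors standard
#' trajectory subsampling practice for these descriptors.
#'
#' @param traj a [mol_trajectory()].
#' @param f number of frames to keep; if the trajectory is shorter than
#'   `f`, all frames are kept.
#' @return A `mol_trajectory`.
#' @export
subsample_frames <- function(traj, f = 101L) {
  stopifnot(inherits(traj, "mol_trajectory"), f >= 1L)
  n <- n_frames(traj)
  idx <- unique(round(seq(1L, n, length.out = min(f, n))))
  mol_trajectory(traj$frames[idx], traj$metadata)
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("# mol_trajectory: %d frames of %d points\n",
              n_frames(x), nrow(x$frames[[1L]])))
  invisible(x)
}
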