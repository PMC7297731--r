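with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

runif_box <- function(n, box) {
  cbind(runif(n, 0, box[1L]), runif(n, 0, box[2L]), runif(n, 0, box[3L]))
}

as_box3 <- function(box) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(box) == 3L, all(box > 0))
  box
}

#' Uniformly random configuration
#'
#' `n` independent uniform points in the periodic box: the fully
#' disordered reference against which structured generators are compared.
#'
#' @param n number of points.
#' @param box box lengths (angstrom, scalar or 3-vector).
#' @param seed optional integer seed; the same seed reproduces the same
#'   configuration exactly.
#' @param type point type label.
#' @return A [mol_config()].
#' @export
gen_uniform <- function(n, box, seed = NULL, type = "WATER") {
  box <- as_box3(box)
  stopifnot(n >= 1L)
  with_seed_maybe(seed, mol_config(runif_box(n, box), box, types = type))
}

#' Hard-core (evenly spread) configuration
#'
#' Dart-throwing with minimum-image rejection: points are proposed
#' uniformly and accepted only if at least `min_dist` from every accepted
#' point. Emulates an evenly distributed, network-like species whose
#' nearest-neighbor distances are bounded below.
#'
#' @inheritParams gen_uniform
#' @param min_dist minimum allowed pairwise min-image distance (angstrom).
#' @param max_attempts proposal budget; exceeding it raises an error
#'   suggesting a smaller `n` or `min_dist`.
#' @return A [mol_config()] whose pairwise min-image distances are all
#'   `>= min_dist`.
#' @export
gen_hardcore <- function(n, box, min_dist, seed = NULL, type = "OSMOLYTE",
                         max_attempts = 200L * n) {
  box <- as_box3(box)
  stopifnot(n >= 1L, min_dist >= 0)
  with_seed_maybe(seed, {
    acc <- matrix(numeric(0), ncol = 3L)
    attempts <- 0L
    while (nrow(acc) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(paste0("hard-core packing failed after ", max_attempts,
                     " attempts; reduce `n` or `min_dist`"))
      }
      p <- runif_box(1L, box)
      if (nrow(acc) == 0L ||
          min(cross_distance_matrix(acc, p, box)) >= min_dist) {
        acc <- rbind(acc, p)
      }
    }
    mol_config(acc, box, types = type)
  })
}

#' Clustered (Thomas-process) configuration
#'
#' Uniform parent centers, Poisson-distributed offspring counts around
#' `offspring_mean`, offspring displaced from their parent by an isotropic
#' Gaussian of scale `sigma` and wrapped into the box. Emulates a species
#' that concentrates into clusters.
#'
#' @inheritParams gen_uniform
#' @param n_parents number of cluster centers.
#' @param offspring_mean mean points per cluster.
#' @param sigma cluster spread (angstrom); `sigma = 0` stacks offspring on
#'   their parents.
#' @return A [mol_config()] (total count is random, Poisson around
#'   `n_parents * offspring_mean`, resampled if zero).
#' @export
gen_clustered <- function(n_parents, offspring_mean, sigma, box, seed = NULL,
                          type = "OSMOLYTE") {
  box <- as_box3(box)
  stopifnot(n_parents >= 1L, offspring_mean > 0, sigma >= 0)
  with_seed_maybe(seed, {
    repeat {
      parents <- runif_box(n_parents, box)
      counts <- rpois(n_parents, offspring_mean)
      if (sum(counts) >= 1L) break
    }
    pts <- parents[rep(seq_len(n_parents), counts), , drop = FALSE]
    pts <- pts + matrix(rnorm(3L * nrow(pts), sd = sigma), ncol = 3L)
    pts <- cbind(pts[, 1L] %% box[1L], pts[, 2L] %% box[2L], pts[, 3L] %% box[3L])
    mol_config(pts, box, types = type)
  })
}

#' Solvated two-type configuration
#'
#' Adds `n_water` waters around an osmolyte configuration: a fraction
#' `shell_fraction` is placed on spheres of radius `shell_radius` (with
#' Gaussian radial jitter) around randomly chosen osmolytes -- a synthetic
#' first hydration shell -- and the remainder uniformly in the box, with
#' bulk waters rejected inside `exclusion_radius` of any osmolyte
#' (excluded volume; without it the `1/(4 pi r^2)` normalization makes the
#' smallest radial bins unboundedly noisy).
#'
#' @inheritParams gen_uniform
#' @param osmolyte_config a [mol_config()] of osmolytes.
#' @param n_water number of waters to add.
#' @param shell_radius hydration-shell radius (angstrom, default 4).
#' @param shell_fraction fraction of waters in the shell, in `[0, 1]`.
#' @param jitter Gaussian sd of the shell radius (angstrom).
#' @param exclusion_radius closest allowed bulk-water-to-osmolyte approach
#'   (angstrom, default 2.5, about a heavy-atom contact distance).
#' @return A [mol_config()] with the osmolytes first, then the waters.
#' @export
gen_solvated <- function(osmolyte_config, n_water, shell_radius = 4,
                         shell_fraction = 0.3, jitter = 0.3, seed = NULL,
                         exclusion_radius = 2.5) {
  stopifnot(inherits(osmolyte_config, "mol_config"), n_water >= 1L,
            shell_fraction >= 0, shell_fraction <= 1, jitter >= 0,
            shell_radius > 0)
  box <- box_lengths(osmolyte_config)
  osm <- coords_matrix(osmolyte_config)
  with_seed_maybe(seed, {
    n_shell <- round(shell_fraction * n_water)
    shell <- NULL
    if (n_shell > 0L) {
      parent <- sample.int(nrow(osm), n_shell, replace = TRUE)
      u <- matrix(rnorm(3L * n_shell), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      r <- pmax(shell_radius + rnorm(n_shell, sd = jitter),
                exclusion_radius)
      shell <- osm[parent, , drop = FALSE] + u * r
    }
    n_bulk <- n_water - n_shell
    bulk <- matrix(numeric(0), ncol = 3L)
    guard <- 0L
    while (nrow(bulk) < n_bulk) {
      guard <- guard + 1L
      if (guard > 200L * n_bulk + 100L) {
        abort("bulk water placement failed; shrink `exclusion_radius`")
      }
      p <- runif_box(1L, box)
      if (exclusion_radius <= 0 ||
          min(cross_distance_matrix(osm, p, box)) >= exclusion_radius) {
        bulk <- rbind(bulk, p)
      }
    }
    waters <- rbind(shell, bulk)
    waters <- cbind(waters[, 1L] %% box[1L], waters[, 2L] %% box[2L],
                    waters[, 3L] %% box[3L])
    mol_config(rbind(osm, waters), box,
               types = c(osmolyte_config$type, rep("WATER", n_water)),
               frame_index = attr(osmolyte_config, "frame_index"))
  })
}

#' Generator specification
#'
#' Bundles a generator kind with its parameters so trajectories and the
#' command line can be driven by one object.
#'
#' @param kind one of `"UNIFORM"`, `"HARDCORE"`, `"CLUSTERED"`,
#'   `"SOLVATED"`.
#' @param ... parameters passed to the matching `gen_*` function (for
#'   `"SOLVATED"`: the osmolyte parameters `n_osmolyte`, `min_dist` plus
#'   the [gen_solvated()] parameters).
#' @param box box lengths (angstrom).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(kind = c("UNIFORM", "HARDCORE", "CLUSTERED",
                                    "SOLVATED"), box, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, box = as_box3(box), params = list(...)),
            class = "generator_spec")
}

#' Generate one configuration from a specification
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer seed.
#' @return A [mol_config()].
#' @export
gen_configuration <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  p <- spec$params
  with_seed_maybe(seed, switch(spec$kind,
    UNIFORM = gen_uniform(p$n, spec$box,
                          type = p$type %||% "WATER"),
    HARDCORE = gen_hardcore(p$n, spec$box, p$min_dist %||% 0,
                            type = p$type %||% "OSMOLYTE"),
    CLUSTERED = gen_clustered(p$n_parents, p$offspring_mean, p$sigma,
                              spec$box, type = p$type %||% "OSMOLYTE"),
    SOLVATED = {
      osm <- gen_hardcore(p$n_osmolyte, spec$box, p$min_dist %||% 0,
                          type = "OSMOLYTE")
      gen_solvated(osm, p$n_water,
                   shell_radius = p$shell_radius %||% 4,
                   shell_fraction = p$shell_fraction %||% 0.3,
                   jitter = p$jitter %||% 0.3,
                   exclusion_radius = p$exclusion_radius %||% 2.5)
    }))
}

#' Generate a stationary synthetic trajectory
#'
#' A base configuration from the specification plus independent Gaussian
#' coordinate jitter per frame (wrapped into the box), giving statistically
#' stationary frames that stand in for equally spaced samples of an
#' equilibrated simulation.
#'
#' @param spec a [generator_spec()].
#' @param n_frames number of frames (default 101).
#' @param frame_jitter per-coordinate Gaussian sd (angstrom); 0 gives
#'   identical frames.
#' @param seed optional integer seed fixing base configuration and jitter.
#' @return A [mol_trajectory()].
#' @export
gen_trajectory <- function(spec, n_frames = 101L, frame_jitter = 0.5,
                           seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"), n_frames >= 1L,
            frame_jitter >= 0)
  with_seed_maybe(seed, {
    base <- gen_configuration(spec)
    box <- box_lengths(base)
    cm <- coords_matrix(base)
    frames <- lapply(seq_len(n_frames), function(i) {
      pts <- cm + matrix(rnorm(length(cm), sd = frame_jitter),
                         ncol = 3L)
      pts <- cbind(pts[, 1L] %% box[1L], pts[, 2L] %% box[2L],
                   pts[, 3L] %% box[3L])
      mol_config(pts, box, types = base$type, frame_index = i - 1L)
    })
    mol_trajectory(frames, metadata = list(spec = spec,
                                           frame_jitter = frame_jitter))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
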