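new_iph_matrix <- function(m, types, scale) {
  structure(m, types = types, scale = scale,
            class = c("iph_matrix", "matrix", "array"))
}

#' Global-scale interactive dissimilarity matrix
#'
#' For one chosen osmolyte and all `N_w` waters of a frame, builds the
#' `(N_w + 1) x (N_w + 1)` matrix whose entries are minimum-image distances
#' when the two molecules differ in type and `Inf` when they agree (zero on
#' the diagonal, so every vertex is born at filtration 0). Only
#' osmolyte-water edges can ever form, so the filtration encodes purely the
#' solvation structure of that osmolyte.
#'
#' @param config a [mol_config()] containing both types.
#' @param osmolyte_index index (into `config`) of an `OSMOLYTE` point.
#' @return An `iph_matrix` (attributes `types`, `scale = "GLOBAL"`); the
#'   osmolyte is row 1, the waters follow in index order.
#' @export
build_global_iph_matrix <- function(config, osmolyte_index) {
  stopifnot(inherits(config, "mol_config"))
  osmolyte_index <- as.integer(osmolyte_index)
  if (config$type[osmolyte_index] != "OSMOLYTE") {
    abort("`osmolyte_index` must refer to an OSMOLYTE point")
  }
  waters <- which(config$type == "WATER")
  if (length(waters) == 0L) abort("no WATER points in the frame")
  idx <- c(osmolyte_index, waters)
  m <- pairwise_distance_matrix(config, idx)
  same <- outer(config$type[idx], config$type[idx], "==")
  m[same] <- Inf
  diag(m) <- 0
  new_iph_matrix(m, config$type[idx], "GLOBAL")
}

#' Local-scale interactive dissimilarity matrix
#'
#' The `(N_w + N_s) x (N_w + N_s)` matrix over every molecule of a frame
#' with the same rule: finite minimum-image distances across types,
#' `Inf` within a type, zero diagonal. Under the resulting filtration
#' waters first attach to their nearest osmolytes (a Voronoi-like cell
#' structure emerges) and cells later merge through shared waters.
#'
#' @param config a [mol_config()] containing both types.
#' @return An `iph_matrix` with `scale = "LOCAL"`, rows in `config` order.
#' @export
build_local_iph_matrix <- function(config) {
  stopifnot(inherits(config, "mol_config"))
  if (!all(c("OSMOLYTE", "WATER") %in% config$type)) {
    abort("local-scale matrix needs at least one point of each type")
  }
  m <- pairwise_distance_matrix(config)
  same <- outer(config$type, config$type, "==")
  m[same] <- Inf
  diag(m) <- 0
  new_iph_matrix(m, config$type, "LOCAL")
}

#' Dimension-0 barcode of an interactive matrix
#'
#' Sorted-edge union-find over the finite (cross-type) edges. For a
#' global-scale matrix this takes the fast path: every water merges into
#' the osmolyte's component exactly at its distance, so the finite deaths
#' are the multiset of osmolyte-water distances; the generic union-find
#' gives the identical barcode. For a local-scale matrix the finite deaths
#' are the edge weights of the bipartite minimum spanning forest.
#'
#' @param matrix an `iph_matrix` (or any symmetric dissimilarity matrix
#'   with `Inf` entries).
#' @return A `ph_barcode` tibble with dimension-0 bars only.
#' @export
iph_betti0 <- function(matrix) {
  if (identical(attr(matrix, "scale"), "GLOBAL")) {
    deaths <- matrix[1L, -1L]
    deaths <- deaths[is.finite(deaths) & deaths > 0]
    n_zero <- sum(matrix[1L, -1L] == 0)       # coincident points merge at 0
    n_inf <- nrow(matrix) - length(deaths) - n_zero
    return(new_barcode(rep(0L, length(deaths) + n_inf),
                       rep(0, length(deaths) + n_inf),
                       c(sort(deaths), rep(Inf, n_inf))))
  }
  betti0_union_find(unclass_matrix(matrix))
}

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Verify that interactive dimension-1 features persist forever
#'
#' Any three vertices of a two-type system contain a same-type pair, whose
#' entry is infinite, so no 2-simplex can ever form and no dimension-1
#' cycle can be filled: every dimension-1 bar has infinite death. This
#' reports the analytic argument and, on small matrices, confirms it by
#' running the full Rips reduction.
#'
#' @param matrix an `iph_matrix`.
#' @param verify_rips also compute the Rips barcode and count triangles
#'   (default: only for matrices up to 60 points).
#' @return A list: `bipartite_infinite` (all same-type off-diagonal entries
#'   infinite), `n_triangles` (0), `n_dim1_bars`, `n_finite_dim1_deaths`
#'   (0), `verified_by_reduction`.
#' @export
iph_betti1_check <- function(matrix, verify_rips = nrow(matrix) <= 60L) {
  types <- attr(matrix, "types")
  stopifnot(!is.null(types))
  same <- outer(types, types, "==")
  diag(same) <- FALSE
  bip <- all(is.infinite(matrix[same]))
  out <- list(bipartite_infinite = bip, n_triangles = 0L,
              n_dim1_bars = NA_integer_, n_finite_dim1_deaths = 0L,
              verified_by_reduction = FALSE)
  if (verify_rips) {
    fin <- matrix[is.finite(matrix)]
    mf <- max(c(0, fin))
    bc <- rips_persistence(unclass_matrix(matrix), max_dim = 1L, max_filt = mf)
    d1 <- bars_of_dim(bc, 1L)
    filt <- build_rips_filtration(unclass_matrix(matrix), max_dim = 2L,
                                  max_filt = mf)
    out$n_triangles <- sum(filt$dim == 2L)
    out$n_dim1_bars <- nrow(d1)
    out$n_finite_dim1_deaths <- sum(is.finite(d1$death))
    out$verified_by_reduction <- TRUE
  }
  out
}

# Per-frame cross-distance matrix (osmolytes x waters) with indices.
frame_cross_distances <- function(config) {
  osm <- which(config$type == "OSMOLYTE")
  wat <- which(config$type == "WATER")
  if (length(osm) == 0L || length(wat) == 0L) {
    abort("frame must contain both OSMOLYTE and WATER points")
  }
  cm <- coords_matrix(config)
  list(osm = osm, wat = wat,
       d = cross_distance_matrix(cm[osm, , drop = FALSE],
                                 cm[wat, , drop = FALSE],
                                 box_lengths(config)))
}

#' Average global-scale persistent radial distribution function
#'
#' For every osmolyte of every frame, takes the dimension-0 deaths of its
#' global-scale interactive matrix (equal to its distances to all waters),
#' bins them to `r_max = min(box) / 2`, normalizes conventionally, and
#' averages with uniform weight per (molecule, frame) pair. The number
#' density is the sphere-averaged rule: mean water count within `r_max` of
#' an osmolyte divided by the `r_max`-sphere volume. For uniform waters the
#' tail of the curve tends to 1, as for a conventional radial distribution
#' function.
#'
#' @param traj a [mol_trajectory()] whose frames contain both types.
#' @param bin_width histogram bin width in angstrom (default 0.1,
#'   resolving hydration-shell peaks near 4 angstrom).
#' @param mode normalization mode, see [prdf_from_barcode()].
#' @return A `prdf_curve` tibble (attributes include the density `rho`
#'   and `r_max`).
#' @export
global_prdf_pipeline <- function(traj, bin_width = 0.1,
                                 mode = c("conventional", "literal_eq4")) {
  stopifnot(inherits(traj, "mol_trajectory"))
  mode <- match.arg(mode)
  r_max <- min(vapply(traj$frames, function(f) min(box_lengths(f)), numeric(1))) / 2
  n_bins <- max(1L, ceiling(r_max / bin_width - 0.5))
  breaks <- (seq_len(n_bins + 1L) - 0.5) * bin_width
  centers <- bin_width * seq_len(n_bins)
  count_acc <- numeric(n_bins)
  n_curves <- 0L
  n_in_sphere <- 0
  x_t <- 0
  n0 <- 0L
  for (config in traj$frames) {
    cr <- frame_cross_distances(config)
    for (i in seq_along(cr$osm)) {
      deaths <- cr$d[i, ]
      count_acc <- count_acc + hist_counts(deaths, breaks)
      n_in_sphere <- n_in_sphere + sum(deaths <= r_max)
      n_curves <- n_curves + 1L
      x_t <- max(x_t, max(deaths))
      n0 <- n0 + length(deaths) + 1L
    }
  }
  rho <- (n_in_sphere / n_curves) / ((4 / 3) * pi * r_max^3)
  mean_counts <- count_acc / n_curves
  value <- switch(mode,
    conventional = mean_counts / (4 * pi * centers^2 * bin_width * rho),
    literal_eq4 = (x_t / (n0 / n_curves)) * mean_counts /
      (4 * pi * centers^2 * bin_width))
  structure(tibble(r = centers, value = value),
            x_t = x_t, n0 = n0 / n_curves, rho = rho,
            bin_width = bin_width, mode = mode, r_max = r_max,
            n_curves = n_curves,
            class = c("prdf_curve", "tbl_df", "tbl", "data.frame"))
}

#' Average local-scale persistent radial distribution function
#'
#' Per frame, the dimension-0 deaths of the local-scale interactive matrix
#' (bipartite minimum-spanning-forest edge weights) are binned and
#' normalized by the box number density of water, `N_w / V`; frames are
#' averaged with equal weight. Unlike the global-scale curve this one
#' drops to zero once the filtration exceeds the largest death.
#'
#' @inheritParams global_prdf_pipeline
#' @return A `prdf_curve` tibble.
#' @export
local_prdf_pipeline <- function(traj, bin_width = 0.1) {
  stopifnot(inherits(traj, "mol_trajectory"))
  deaths_by_frame <- lapply(traj$frames, function(config) {
    bc <- iph_betti0(build_local_iph_matrix(config))
    bc$death[is.finite(bc$death)]
  })
  cfg1 <- traj$frames[[1L]]
  rho <- sum(cfg1$type == "WATER") / prod(box_lengths(cfg1))
  r_top <- max(unlist(deaths_by_frame))
  n_bins <- max(1L, ceiling(r_top / bin_width - 0.5) + 1L)
  breaks <- (seq_len(n_bins + 1L) - 0.5) * bin_width
  centers <- bin_width * seq_len(n_bins)
  counts <- Reduce(`+`, lapply(deaths_by_frame, hist_counts, breaks = breaks))
  mean_counts <- counts / length(deaths_by_frame)
  structure(tibble(r = centers,
                   value = mean_counts / (4 * pi * centers^2 * bin_width * rho)),
            x_t = r_top, n0 = mean(lengths(deaths_by_frame)) + 1,
            rho = rho, bin_width = bin_width, mode = "conventional",
            class = c("prdf_curve", "tbl_df", "tbl", "data.frame"))
}

#' Local-scale interactive PBN curve and per-frame BPE series
#'
#' Averages the dimension-0 persistent Betti number of the local-scale
#' interactive matrix over frames (on a common grid) and computes one
#' dimension-0 Boltzmann persistent entropy per frame.
#'
#' @inheritParams global_prdf_pipeline
#' @param params an [entropy_params()].
#' @param grid common PBN grid; default `seq(0, max death, by = 0.1)`.
#' @return A list with elements `pbn` (a `pbn_curve`) and `bpe` (a tibble
#'   with columns `frame`, `bpe`).
#' @export
iph_pbn_bpe_pipeline <- function(traj, params = entropy_params(), grid = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"))
  barcodes <- lapply(traj$frames, function(config) {
    iph_betti0(build_local_iph_matrix(config))
  })
  if (is.null(grid)) {
    top <- max(vapply(barcodes, function(b) {
      d <- b$death[is.finite(b$death)]
      if (length(d)) max(d) else 0
    }, numeric(1)))
    grid <- seq(0, ceiling(top * 10) / 10, by = 0.1)
  }
  acc <- numeric(length(grid))
  for (bc in barcodes) acc <- acc + persistent_betti_number(bc, 0L, grid)$value
  pbn <- structure(tibble(x = grid, value = acc / length(barcodes)),
                   dimension = 0L,
                   class = c("pbn_curve", "tbl_df", "tbl", "data.frame"))
  bpe <- tibble(frame = seq_along(barcodes),
                bpe = vapply(barcodes, boltzmann_persistent_entropy,
                             numeric(1), k = 0L, params = params))
  list(pbn = pbn, bpe = bpe)
}
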