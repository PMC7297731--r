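#' Localized persistent homology barcode of one molecule
#'
#' Extracts the spherical local region of radius `r_c` around the chosen
#' center (minimum-image distances, optionally restricted to one species)
#' and computes the Vietoris-Rips barcode of its distance matrix up to
#' homology dimension `max_dim`. The filtration runs to `2 * r_c`, the
#' largest pairwise distance possible inside the sphere, so loops larger
#' than the cutoff radius itself are still resolved.
#'
#' @inheritParams extract_local_region
#' @param max_dim highest homology dimension (default 1: components and
#'   loops).
#' @return A `ph_barcode` tibble.
#' @export
lph_barcode <- function(config, center, r_c, max_dim = 1L, species = NULL) {
  region <- extract_local_region(config, center, r_c, species = species)
  rips_persistence(region$dist, max_dim = max_dim, max_filt = 2 * r_c)
}

lph_frame_barcodes <- function(config, species, r_c, max_dim) {
  centers <- which(config$type == species)
  if (length(centers) == 0L) {
    abort(sprintf("no points of species %s in frame", species))
  }
  lapply(centers, function(ci) {
    lph_barcode(config, ci, r_c, max_dim = max_dim, species = species)
  })
}

#' Ensemble-averaged localized PBN curve
#'
#' Computes the per-molecule local barcode for every molecule of the given
#' species in every frame, evaluates each dimension-`k` persistent Betti
#' number on a common grid, and returns the arithmetic mean over all
#' (molecule, frame) pairs.
#'
#' @param traj a [mol_trajectory()].
#' @param species `"OSMOLYTE"` or `"WATER"`.
#' @param r_c cutoff radius in angstrom (typical choices: 9, 12 or 15 for
#'   osmolytes; 7 or 9 for water).
#' @param k homology dimension of the curve (default 1: loop structures).
#' @param grid common evaluation grid; default `seq(0, 2 * r_c, by = 0.1)`.
#' @return A `pbn_curve` tibble (columns `x`, `value`) with attribute
#'   `n_curves`, the number of per-molecule curves averaged.
#' @export
lph_average_pbn <- function(traj, species, r_c, k = 1L, grid = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"))
  if (is.null(grid)) grid <- seq(0, 2 * r_c, by = 0.1)
  max_dim <- max(1L, as.integer(k))
  acc <- numeric(length(grid))
  n_curves <- 0L
  for (config in traj$frames) {
    for (bc in lph_frame_barcodes(config, species, r_c, max_dim)) {
      acc <- acc + persistent_betti_number(bc, k, grid)$value
      n_curves <- n_curves + 1L
    }
  }
  structure(tibble(x = grid, value = acc / n_curves),
            dimension = as.integer(k), n_curves = n_curves,
            class = c("pbn_curve", "tbl_df", "tbl", "data.frame"))
}

#' Per-frame Boltzmann persistent entropy series from LPH
#'
#' For each frame, averages the dimension-`k` BPE of the local barcodes of
#' all molecules of the species, giving one value per frame (e.g. 101
#' values from a 101-frame trajectory). Local regions without finite
#' dimension-`k` bars contribute a BPE of 0.
#'
#' @inheritParams lph_average_pbn
#' @param params an [entropy_params()].
#' @return A tibble with columns `frame`, `bpe`, `n_molecules`.
#' @export
lph_bpe_series <- function(traj, species, r_c, k = 1L,
                           params = entropy_params()) {
  stopifnot(inherits(traj, "mol_trajectory"))
  max_dim <- max(1L, as.integer(k))
  rows <- purrr::imap(traj$frames, function(config, i) {
    bcs <- lph_frame_barcodes(config, species, r_c, max_dim)
    vals <- vapply(bcs, boltzmann_persistent_entropy, numeric(1),
                   k = k, params = params)
    tibble(frame = i, bpe = mean(vals), n_molecules = length(vals))
  })
  dplyr::bind_rows(rows)
}

#' Global (whole-box) barcode of one frame
#'
#' Rips barcode over every point of a species in the frame, the whole-box
#' reference against which the localized curves are compared.
#'
#' @inheritParams lph_average_pbn
#' @param config a [mol_config()].
#' @param max_dim highest homology dimension (default 1).
#' @param max_filt filtration limit; defaults to half the shortest box
#'   edge, past which minimum-image geometry stops resolving larger
#'   features.
#' @return A `ph_barcode` tibble.
#' @export
global_frame_barcode <- function(config, species = NULL, max_dim = 1L,
                                 max_filt = NULL) {
  stopifnot(inherits(config, "mol_config"))
  subset <- seq_len(nrow(config))
  if (!is.null(species)) {
    stopifnot(species %in% c("OSMOLYTE", "WATER"))
    subset <- which(config$type == species)
    if (length(subset) == 0L) abort(sprintf("no points of species %s", species))
  }
  if (is.null(max_filt)) max_filt <- min(box_lengths(config)) / 2
  d <- pairwise_distance_matrix(config, subset)
  rips_persistence(d, max_dim = max_dim, max_filt = max_filt)
}
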