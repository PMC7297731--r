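bars_of_dim <- function(barcode, k) {
  stopifnot(inherits(barcode, "ph_barcode") || is.data.frame(barcode))
  barcode[barcode$dimension == as.integer(k), , drop = FALSE]
}

finite_lengths <- function(bars) {
  len <- bars$death - bars$birth
  len[is.finite(bars$death)]
}

#' Persistent Betti number curve
#'
#' Counts, at each grid value `x`, the bars of dimension `k` whose closed
#' interval `[birth, death]` contains `x` (bars with infinite death count
#' for every `x` at or past their birth). For dimension 0 the value at
#' `x = 0` is the number of points and the curve is non-increasing.
#'
#' @param barcode a `ph_barcode`.
#' @param k homology dimension.
#' @param grid ascending filtration values (angstrom).
#' @return A `pbn_curve` tibble with columns `x`, `value`.
#' @export
persistent_betti_number <- function(barcode, k, grid) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be strictly ascending")
  bars <- bars_of_dim(barcode, k)
  value <- vapply(grid, function(x) {
    sum(bars$birth <= x & x <= bars$death)
  }, numeric(1))
  structure(tibble(x = grid, value = value),
            dimension = as.integer(k),
            class = c("pbn_curve", "tbl_df", "tbl", "data.frame"))
}

#' Largest finite death in one dimension
#'
#' The filtration value at which the dimension-`k` persistent Betti number
#' last drops, i.e. for a connected dimension-0 barcode the value where the
#' PBN reduces to one.
#'
#' @inheritParams persistent_betti_number
#' @return A length in angstrom.
#' @export
max_finite_death <- function(barcode, k = 0L) {
  bars <- bars_of_dim(barcode, k)
  d <- bars$death[is.finite(bars$death)]
  if (length(d) == 0L) abort(sprintf("no finite bars in dimension %d", k))
  max(d)
}

#' Parameters of the Betti energy
#'
#' The Betti energy of a finite bar of length `L` is
#' `E = alpha * (L / eta)^kappa`; Boltzmann weights are `exp(-E / kBT)`.
#' Defaults follow the convention `alpha = kBT`, `eta = 1` angstrom,
#' `kappa = 2`, under which `E / kBT = L^2` is temperature-independent and
#' no numeric temperature is ever needed (energies below are expressed in
#' units of `kBT`).
#'
#' @param alpha energy prefactor, in units of `kBT`.
#' @param eta length scale in angstrom.
#' @param kappa positive integer exponent.
#' @param kBT thermal energy scale (same units as `alpha`).
#' @return An `entropy_params` list.
#' @export
entropy_params <- function(alpha = 1, eta = 1, kappa = 2L, kBT = 1) {
  stopifnot(alpha > 0, eta > 0, kBT > 0)
  kappa <- as.integer(kappa)
  if (is.na(kappa) || kappa < 1L) abort("`kappa` must be a positive integer")
  structure(list(alpha = alpha, eta = eta, kappa = kappa, kBT = kBT),
            class = "entropy_params")
}

#' Persistent entropy
#'
#' Shannon entropy `sum(-p log p)` of bar lengths normalized to
#' probabilities, `p_j = L_j / sum(L)`, over the finite bars of dimension
#' `k`. With `include_infinite = TRUE` the infinitely persisting bar takes
#' probability exactly 1 and every finite bar probability 0 (the limiting
#' convention for an infinite length), so the entropy is exactly 0
#' regardless of the finite bars. An empty barcode has entropy 0 by
#' definition, so sparse local regions average cleanly.
#'
#' @inheritParams persistent_betti_number
#' @param include_infinite include the infinite bar under the limiting
#'   probability convention (default `FALSE`).
#' @return A non-negative real, at most `log` of the finite-bar count.
#' @export
persistent_entropy <- function(barcode, k = 0L, include_infinite = FALSE) {
  bars <- bars_of_dim(barcode, k)
  if (include_infinite && any(is.infinite(bars$death))) {
    return(0)
  }
  len <- finite_lengths(bars)
  len <- len[len > 0]
  if (length(len) == 0L) return(0)
  p <- len / sum(len)
  -sum(p * log(p))
}

#' Betti energy of bars
#'
#' `E = alpha * ((death - birth) / eta)^kappa` for finite bars; an infinite
#' bar has infinite energy, hence Boltzmann weight (and probability)
#' exactly zero.
#'
#' @param lengths bar lengths in angstrom (may contain `Inf`).
#' @param params an [entropy_params()].
#' @return Energies in the units of `params$alpha`.
#' @export
betti_energy <- function(lengths, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"), all(lengths >= 0))
  params$alpha * (lengths / params$eta)^params$kappa
}

#' Boltzmann probabilities of bars
#'
#' Normalized Boltzmann weights `exp(-E / kBT)` of the Betti energies of
#' dimension-`k` bars. Longer bars carry larger energy and hence lower
#' probability, the reverse of the length-proportional weighting of
#' traditional persistent entropy. Infinite bars get probability exactly 0;
#' weights are computed relative to the smallest energy so arbitrarily long
#' (finite) bars do not underflow the normalization.
#'
#' @inheritParams persistent_entropy
#' @param params an [entropy_params()].
#' @return A tibble with columns `birth`, `death`, `length`, `energy`,
#'   `probability`; the probabilities sum to 1.
#' @export
boltzmann_probabilities <- function(barcode, k = 0L, params = entropy_params()) {
  bars <- bars_of_dim(barcode, k)
  if (!any(is.finite(bars$death))) {
    abort(sprintf("no finite bars in dimension %d", k))
  }
  len <- bars$death - bars$birth
  energy <- betti_energy(len, params)
  fin <- is.finite(len)
  e_scaled <- energy[fin] / params$kBT
  w <- exp(-(e_scaled - min(e_scaled)))
  p <- numeric(nrow(bars))
  p[fin] <- w / sum(w)
  tibble(birth = bars$birth, death = bars$death, length = len,
         energy = energy, probability = p)
}

#' Boltzmann persistent entropy
#'
#' Shannon entropy of the Boltzmann probabilities of the finite
#' dimension-`k` bars. Equal-length bars give the maximum `log(N)`; a
#' barcode with no finite bars (in particular an empty one, as happens for
#' sparse local regions) has BPE 0 by definition.
#'
#' @inheritParams boltzmann_probabilities
#' @return A non-negative real.
#' @export
boltzmann_persistent_entropy <- function(barcode, k = 0L,
                                         params = entropy_params()) {
  bars <- bars_of_dim(barcode, k)
  if (!any(is.finite(bars$death))) return(0)
  p <- boltzmann_probabilities(barcode, k, params)$probability
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Persistent radial distribution function from a dimension-0 barcode
#'
#' Histograms the finite dimension-0 death radii into bins of width
#' `bin_width` and normalizes each bin. In `"conventional"` mode the bin at
#' center `r` takes the value `count / (4 pi r^2 bin_width * rho)`, which
#' for the global-scale interactive model reproduces the conventional
#' radial distribution function (tail tending to 1 for a uniform liquid).
#' In `"literal_eq4"` mode the curve is instead
#' `(x_t / N_0) * count / (4 pi r^2 bin_width)` -- the defining expression
#' read literally, with `x_t` the largest finite death (the scale where the
#' PBN reduces to one) and `N_0` the total number of dimension-0 bars --
#' kept as an explicit mode because its prefactor is not dimensionally
#' compatible with the RDF limit.
#'
#' @param barcode a `ph_barcode` with at least one finite dimension-0 bar.
#' @param bin_width positive bin width in angstrom.
#' @param rho number density in angstrom^-3 (used by `"conventional"` mode).
#' @param mode `"conventional"` or `"literal_eq4"`.
#' @param r_max optional histogram upper edge; defaults to covering the
#'   largest finite death. Deaths beyond `r_max` are not binned.
#' @return A `prdf_curve` tibble with columns `r` (bin centers), `value`,
#'   carrying `x_t`, `n0`, `rho`, `bin_width` and `mode` as attributes.
#' @export
prdf_from_barcode <- function(barcode, bin_width = 0.1, rho,
                              mode = c("conventional", "literal_eq4"),
                              r_max = NULL) {
  mode <- match.arg(mode)
  if (bin_width <= 0) abort("`bin_width` must be positive")
  if (mode == "conventional" && (missing(rho) || rho <= 0)) {
    abort("conventional mode needs a positive number density `rho`")
  }
  bars <- bars_of_dim(barcode, 0L)
  deaths <- bars$death[is.finite(bars$death)]
  if (length(deaths) == 0L) abort("no finite dimension-0 bars")
  x_t <- max(deaths)
  n0 <- nrow(bars)
  if (is.null(r_max)) r_max <- x_t
  # Bins are centered on multiples of bin_width, bin j covering
  # ((j - 1/2), (j + 1/2)] * bin_width; the radius-0 bin is excluded (its
  # 4 pi r^2 shell volume vanishes and zero-persistence deaths are dropped
  # upstream anyway).
  n_bins <- max(1L, ceiling(r_max / bin_width - 0.5))
  breaks <- (seq_len(n_bins + 1L) - 0.5) * bin_width
  centers <- bin_width * seq_len(n_bins)
  counts <- hist_counts(deaths, breaks)
  value <- switch(mode,
    conventional = counts / (4 * pi * centers^2 * bin_width * rho),
    literal_eq4 = (x_t / n0) * counts / (4 * pi * centers^2 * bin_width))
  structure(tibble(r = centers, value = value),
            x_t = x_t, n0 = n0, rho = if (missing(rho)) NA_real_ else rho,
            bin_width = bin_width, mode = mode,
            class = c("prdf_curve", "tbl_df", "tbl", "data.frame"))
}

# Left-open, right-closed bin counts; values outside [breaks[1], breaks[end]]
# are discarded.
hist_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, left.open = TRUE)
  idx <- idx[idx >= 1L & idx <= length(breaks) - 1L]
  tabulate(idx, nbins = length(breaks) - 1L)
}
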