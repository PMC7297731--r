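#' Tidy a persistence barcode
#'
#' One row per bar with its persistence (bar length) added.
#'
#' @param x a `ph_barcode`.
#' @param ... unused.
#' @return A tibble with columns `dimension`, `birth`, `death`,
#'   `persistence`.
#' @method tidy ph_barcode
#' @export
tidy.ph_barcode <- function(x, ...) {
  out <- as_tibble(x)
  out$persistence <- out$death - out$birth
  out
}

#' One-row barcode summary
#'
#' Per-dimension counts plus the descriptor scalars: the largest finite
#' death, the traditional persistent entropy and the Boltzmann persistent
#' entropy (default parameters), per dimension.
#'
#' @param x a `ph_barcode`.
#' @param params an [entropy_params()].
#' @param ... unused.
#' @return A tibble with one row per dimension present: `dimension`,
#'   `n_bars`, `n_finite`, `n_infinite`, `max_finite_death`, `pe`, `bpe`.
#' @method glance ph_barcode
#' @export
glance.ph_barcode <- function(x, params = entropy_params(), ...) {
  dims <- sort(unique(x$dimension))
  dplyr::bind_rows(lapply(dims, function(k) {
    bars <- bars_of_dim(x, k)
    fin <- is.finite(bars$death)
    tibble(dimension = k,
           n_bars = nrow(bars),
           n_finite = sum(fin),
           n_infinite = sum(!fin),
           max_finite_death = if (any(fin)) max(bars$death[fin]) else NA_real_,
           pe = persistent_entropy(x, k),
           bpe = boltzmann_persistent_entropy(x, k, params))
  }))
}
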