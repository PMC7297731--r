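new_barcode <- function(dim, birth, death) {
  ord <- order(dim, birth, death)
  out <- tibble(dimension = as.integer(dim)[ord],
                birth = as.numeric(birth)[ord],
                death = as.numeric(death)[ord])
  structure(out, class = c("ph_barcode", class(out)))
}

validate_distmat <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  storage.mode(d) <- "double"
  if (nrow(d) < 1L) abort("distance matrix must have at least one point")
  fin <- is.finite(d)
  if (any(is.na(d))) abort("distance matrix contains NA")
  if (!isTRUE(all.equal(d[fin], t(d)[t(fin)], tolerance = 1e-12)) ||
      !identical(fin, t(fin))) {
    abort("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) abort("distance matrix must have a zero diagonal")
  if (any(d[fin] < 0)) abort("distances must be non-negative")
  d
}

#' Build a Vietoris-Rips filtration
#'
#' Enumerates every simplex up to `max_dim` whose vertices are pairwise at
#' finite distance at most `max_filt`; a simplex enters the filtration at
#' the maximum pairwise distance among its vertices (an edge at the distance
#' itself, not half of it). Infinite entries never form simplices, so a
#' matrix that is infinite off-diagonal yields vertices only.
#'
#' @param distmat symmetric matrix with zero diagonal; entries are
#'   non-negative lengths in angstrom or `Inf`.
#' @param max_dim highest simplex dimension built (1, 2 or 3).
#' @param max_filt largest filtration value (angstrom).
#' @return A `rips_filtration` tibble with columns `vertices` (list of
#'   ascending integer tuples), `dim`, `value`, ordered by
#'   (value, dimension, vertex tuple).
#' @export
build_rips_filtration <- function(distmat, max_dim = 2L, max_filt = Inf) {
  d <- validate_distmat(distmat)
  max_dim <- as.integer(max_dim)
  if (!max_dim %in% 1:3) abort("`max_dim` must be 1, 2 or 3")
  n <- nrow(d)
  verts <- lapply(seq_len(n), identity)
  dims <- rep(0L, n)
  vals <- rep(0, n)
  for (p in seq_len(max_dim)) {
    if (n < p + 1L) break
    tuples <- combn(n, p + 1L)
    pair_idx <- combn(p + 1L, 2L)
    simplex_val <- apply(tuples, 2L, function(tp) {
      max(d[cbind(tp[pair_idx[1L, ]], tp[pair_idx[2L, ]])])
    })
    keep <- is.finite(simplex_val) & simplex_val <= max_filt
    if (any(keep)) {
      kept <- tuples[, keep, drop = FALSE]
      verts <- c(verts, lapply(seq_len(ncol(kept)), function(i) kept[, i]))
      dims <- c(dims, rep(p, ncol(kept)))
      vals <- c(vals, simplex_val[keep])
    }
  }
  key <- vapply(verts, function(v) paste(sprintf("%06d", v), collapse = ""), "")
  ord <- order(vals, dims, key)
  out <- tibble(vertices = verts[ord], dim = as.integer(dims[ord]),
                value = vals[ord])
  structure(out, n_points = n, max_dim = max_dim, max_filt = max_filt,
            class = c("rips_filtration", class(out)))
}

#' Persistence barcode of a filtration
#'
#' Pairs simplices by boundary-matrix reduction over GF(2) and reports bars
#' for homology dimensions 0 to `max_dim - 1` (the top-dimensional simplices
#' only act as killers). Zero-persistence pairs are discarded; unpaired
#' cycle creators give bars with infinite death, in particular one infinite
#' dimension-0 bar per connected component of the finite-distance graph.
#'
#' @param filtration a [build_rips_filtration()] result.
#' @return A `ph_barcode` tibble with columns `dimension`, `birth`, `death`
#'   (`Inf` for features that never die).
#' @examples
#' square <- matrix(c(0, 1, sqrt(2), 1,
#'                    1, 0, 1, sqrt(2),
#'                    sqrt(2), 1, 0, 1,
#'                    1, sqrt(2), 1, 0), 4, 4)
#' compute_persistence(build_rips_filtration(square, max_dim = 2))
#' @export
compute_persistence <- function(filtration) {
  stopifnot(inherits(filtration, "rips_filtration"))
  homdim <- attr(filtration, "max_dim") - 1L
  verts0 <- unlist(filtration$vertices, use.names = FALSE) - 1L
  offsets <- c(0L, cumsum(lengths(filtration$vertices)))
  res <- cpp_reduce_filtration(as.integer(verts0), as.integer(offsets),
                               as.numeric(filtration$value), homdim)
  new_barcode(res$dim, res$birth, res$death)
}

#' Rips persistence straight from a distance matrix
#'
#' Convenience composition of [build_rips_filtration()] and
#' [compute_persistence()] with the simplex enumeration done in compiled
#' code, suitable for the per-molecule local regions of the LPH pipeline.
#'
#' @inheritParams build_rips_filtration
#' @param max_dim highest homology dimension reported (0, 1 or 2); the
#'   complex is built one dimension higher.
#' @return A `ph_barcode` tibble.
#' @export
rips_persistence <- function(distmat, max_dim = 1L, max_filt = Inf) {
  d <- validate_distmat(distmat)
  max_dim <- as.integer(max_dim)
  if (!max_dim %in% 0:2) abort("`max_dim` must be 0, 1 or 2")
  res <- cpp_rips_persistence(d, max_dim, max_filt)
  new_barcode(res$dim, res$birth, res$death)
}

#' Dimension-0 barcode by sorted-edge union-find
#'
#' Single-linkage fast path for connected components: finite edges are
#' processed in ascending order and every union of two components records a
#' death at the edge value. The finite deaths therefore equal the edge
#' weights of a minimum spanning forest of the finite-distance graph, and
#' the result matches the dimension-0 output of [compute_persistence()].
#' One infinite bar remains per connected component.
#'
#' @inheritParams build_rips_filtration
#' @return A `ph_barcode` tibble with dimension-0 bars only.
#' @export
betti0_union_find <- function(distmat, max_filt = Inf) {
  d <- validate_distmat(distmat)
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[ut]
  keep <- is.finite(w) & w <= max_filt
  ut <- ut[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(w, ut[, 1L], ut[, 2L])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  deaths <- numeric(0)
  for (e in ord) {
    a <- find(ut[e, 1L]); b <- find(ut[e, 2L])
    if (a != b) {
      parent[a] <- b
      deaths <- c(deaths, w[e])
    }
  }
  n_inf <- n - length(deaths)        # one infinite bar per component
  deaths <- deaths[deaths > 0]       # zero-persistence pairs are dropped
  new_barcode(rep(0L, length(deaths) + n_inf),
              rep(0, length(deaths) + n_inf),
              c(deaths, rep(Inf, n_inf)))
}

#' Simplices present at a fixed filtration value
#'
#' Slice of the filtration used e.g. to extract the 2-simplexes (triangles)
#' that have formed by a given scale.
#'
#' @param filtration a [build_rips_filtration()] result.
#' @param r filtration value (angstrom); must not exceed the filtration's
#'   `max_filt`.
#' @param dims integer dimensions to keep (default: all built).
#' @return The filtration tibble restricted to simplices with
#'   `value <= r` and dimension in `dims`.
#' @export
simplices_at_filtration <- function(filtration, r, dims = NULL) {
  stopifnot(inherits(filtration, "rips_filtration"))
  if (r > attr(filtration, "max_filt")) {
    abort("`r` exceeds the filtration's max_filt; rebuild with a larger one")
  }
  if (is.null(dims)) dims <- 0:attr(filtration, "max_dim")
  filtration[filtration$value <= r & filtration$dim %in% as.integer(dims), ]
}

#' @export
print.ph_barcode <- function(x, ...) {
  tab <- table(factor(x$dimension, levels = sort(unique(x$dimension))))
  cat("# ph_barcode:",
      paste(sprintf("dim %s: %d bars", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  NextMethod()
}
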