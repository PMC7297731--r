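#' Molecular point configuration in a periodic box
#'
#' A configuration is one frame of coarse-grained molecular positions: a
#' tibble with columns `x`, `y`, `z` (angstrom) and `type` (one of
#' `"OSMOLYTE"`, `"WATER"`), carrying the orthorhombic box lengths and the
#' frame index as attributes. Coordinates may lie outside the box; use
#' [wrap_coordinates()] to reduce them into `[0, box)`.
#'
#' @param coords numeric matrix or data frame with three columns (x, y, z in
#'   angstrom).
#' @param box positive numeric of length 1 or 3: orthorhombic box lengths in
#'   angstrom (a scalar is recycled to a cubic box).
#' @param types character vector of point types, recycled to the number of
#'   points; each must be `"OSMOLYTE"` or `"WATER"`.
#' @param frame_index non-negative integer frame label.
#' @return A `mol_config` tibble with columns `x`, `y`, `z`, `type`.
#' @examples
#' cfg <- mol_config(matrix(runif(30, 0, 20), ncol = 3), box = 20)
#' box_lengths(cfg)
#' @export
mol_config <- function(coords, box, types = "WATER", frame_index = 0L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("`coords` must have three columns (x, y, z)")
  if (nrow(coords) < 1L) abort("a configuration needs at least one point")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) {
    bad <- which(!is.finite(coords), arr.ind = TRUE)[1L, 1L]
    abort(sprintf("non-finite coordinate at point %d", bad))
  }
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
    abort("`box` must be 1 or 3 positive finite lengths")
  }
  types <- rep_len(as.character(types), nrow(coords))
  if (!all(types %in% c("OSMOLYTE", "WATER"))) {
    abort("`types` must be \"OSMOLYTE\" or \"WATER\"")
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) abort("`frame_index` must be >= 0")
  out <- tibble(x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                type = types)
  structure(out,
            box = box, frame_index = frame_index,
            class = c("mol_config", class(out)))
}

#' @rdname mol_config
#' @param config a `mol_config`.
#' @export
box_lengths <- function(config) {
  stopifnot(inherits(config, "mol_config"))
  attr(config, "box")
}

coords_matrix <- function(config) {
  cbind(config$x, config$y, config$z)
}

#' Wrap coordinates into the primary periodic cell
#'
#' Reduces every coordinate component into `[0, box_i)` by modular
#' arithmetic; point order and types are unchanged.
#'
#' @param config a [mol_config()].
#' @return A `mol_config` with wrapped coordinates.
#' @export
wrap_coordinates <- function(config) {
  stopifnot(inherits(config, "mol_config"))
  box <- box_lengths(config)
  config$x <- config$x %% box[1L]
  config$y <- config$y %% box[2L]
  config$z <- config$z %% box[3L]
  config
}

#' Minimum-image distance between two points
#'
#' Euclidean distance with each axis displacement reduced to
#' `[-box_i/2, box_i/2]`, i.e. the distance to the nearest periodic image.
#'
#' @param p,q numeric 3-vectors (angstrom).
#' @param box positive numeric of length 1 or 3 (angstrom).
#' @return A single non-negative length in angstrom.
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9, 0, 0), box = 10) # 2
#' @export
minimum_image_distance <- function(p, q, box) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(length(p) == 3L, length(q) == 3L, length(box) == 3L,
            all(is.finite(c(p, q))), all(box > 0))
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Min-image displacement matrix along one axis for coordinate vectors a, b.
min_image_cross <- function(a, b, box_i) {
  d <- outer(a, b, "-")
  d - box_i * round(d / box_i)
}

# All-pairs min-image distances between the rows of two coordinate sets.
cross_distance_matrix <- function(ca, cb, box) {
  dx <- min_image_cross(ca[, 1L], cb[, 1L], box[1L])
  dy <- min_image_cross(ca[, 2L], cb[, 2L], box[2L])
  dz <- min_image_cross(ca[, 3L], cb[, 3L], box[3L])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Pairwise minimum-image distance matrix
#'
#' @param config a [mol_config()].
#' @param subset integer indices of the points to include (default: all).
#' @return Symmetric matrix of min-image distances (angstrom), zero diagonal.
#' @export
pairwise_distance_matrix <- function(config, subset = NULL) {
  stopifnot(inherits(config, "mol_config"))
  if (is.null(subset)) subset <- seq_len(nrow(config))
  subset <- as.integer(subset)
  if (length(subset) == 0L) abort("`subset` must not be empty")
  if (anyNA(subset) || any(subset < 1L) || any(subset > nrow(config))) {
    abort("`subset` contains invalid point indices")
  }
  cm <- coords_matrix(config)[subset, , drop = FALSE]
  d <- cross_distance_matrix(cm, cm, box_lengths(config))
  diag(d) <- 0
  d
}

#' Extract the spherical local region around one molecule
#'
#' Collects every point (optionally restricted to one species) whose
#' minimum-image distance from the chosen center is at most `r_c`, the center
#' itself included, and builds the min-image distance matrix among the
#' members. Requires `2 * r_c <= min(box)` so each neighbor has a unique
#' periodic image inside the sphere.
#'
#' @param config a [mol_config()].
#' @param center index of the central point.
#' @param r_c cutoff radius in angstrom.
#' @param species optional `"OSMOLYTE"` or `"WATER"`: restrict members to
#'   this type (the center is always kept).
#' @return A `local_region` list: `center_index`, `member_indices` (ascending,
#'   containing the center), `dist` (symmetric matrix in member order), `r_c`.
#' @export
extract_local_region <- function(config, center, r_c, species = NULL) {
  stopifnot(inherits(config, "mol_config"))
  box <- box_lengths(config)
  if (2 * r_c > min(box)) {
    abort(sprintf(
      "local region requires 2 * r_c <= min(box) (got r_c = %g, min box = %g)",
      r_c, min(box)))
  }
  center <- as.integer(center)
  n <- nrow(config)
  if (is.na(center) || center < 1L || center > n) abort("invalid `center` index")
  candidates <- seq_len(n)
  if (!is.null(species)) {
    stopifnot(species %in% c("OSMOLYTE", "WATER"))
    candidates <- which(config$type == species)
  }
  cm <- coords_matrix(config)
  d_to_center <- cross_distance_matrix(cm[candidates, , drop = FALSE],
                                       cm[center, , drop = FALSE], box)[, 1L]
  members <- sort(unique(c(center, candidates[d_to_center <= r_c])))
  dist <- pairwise_distance_matrix(config, members)
  structure(list(center_index = center, member_indices = members,
                 dist = dist, r_c = r_c),
            class = "local_region")
}

#' @export
print.mol_config <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("# mol_config: %d points, box %.3g x %.3g x %.3g A, frame %d\n",
              nrow(x), box[1L], box[2L], box[3L], attr(x, "frame_index")))
  NextMethod()
}
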