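# Element symbols used when writing coarse-grained XYZ: osmolytes as their
# nitrogen/carbon coarse-grain atom, waters as oxygen.
xyz_symbol_of_type <- c(OSMOLYTE = "N", WATER = "O")

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text multi-frame XYZ; the comment line carries the box as
#' `box=Lx,Ly,Lz` (angstrom) and the frame index. Osmolytes are written
#' with symbol `N`, waters with symbol `O`.
#'
#' @param traj a [mol_trajectory()] or single [mol_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path) {
  if (inherits(traj, "mol_config")) traj <- mol_trajectory(list(traj))
  stopifnot(inherits(traj, "mol_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (config in traj$frames) {
    box <- box_lengths(config)
    writeLines(as.character(nrow(config)), con)
    writeLines(sprintf("box=%.6f,%.6f,%.6f frame=%d",
                       box[1L], box[2L], box[3L],
                       attr(config, "frame_index")), con)
    writeLines(sprintf("%s %.6f %.6f %.6f",
                       xyz_symbol_of_type[config$type],
                       config$x, config$y, config$z), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Expects the box on each frame's comment line as `box=Lx,Ly,Lz`
#' (angstrom), or supplied through `box`. Atom symbols are mapped to point
#' types through `type_map`; unmapped symbols are an error.
#'
#' @param path XYZ file path.
#' @param box optional box lengths overriding/replacing the comment line.
#' @param type_map named character vector from atom symbol to type label.
#' @return A [mol_trajectory()].
#' @export
read_xyz_frames <- function(path, box = NULL,
                            type_map = c(N = "OSMOLYTE", O = "WATER",
                                         OW = "WATER")) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      abort(sprintf("frame %d: malformed atom-count line %d",
                    frame_no + 1L, i))
    }
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines)) {
      abort(sprintf("frame %d: truncated (expected %d atoms)",
                    frame_no + 1L, n))
    }
    comment <- lines[i + 1L]
    bx <- box
    m <- regmatches(comment,
                    regexec("box=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                            comment))[[1L]]
    if (length(m) == 4L) bx <- as.numeric(m[2:4])
    if (is.null(bx)) {
      abort(sprintf(
        "frame %d: no box information (comment key box=Lx,Ly,Lz or `box`)",
        frame_no + 1L))
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    sym <- vapply(rows, `[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) abort(sprintf("frame %d: non-numeric coordinates",
                                  frame_no + 1L))
    unknown <- setdiff(unique(sym), names(type_map))
    if (length(unknown)) {
      abort(paste0("unmapped atom symbols: ",
                   paste(unknown, collapse = ", ")))
    }
    frames[[frame_no + 1L]] <- mol_config(xyz, bx,
                                          types = unname(type_map[sym]),
                                          frame_index = frame_no)
    frame_no <- frame_no + 1L
    i <- i + 2L + n
  }
  if (length(frames) == 0L) abort("no frames found")
  mol_trajectory(frames)
}

#' Read GROMACS GRO frames (atomistic, nanometre-native)
#'
#' Fixed-column GRO records, possibly concatenated into multiple frames.
#' Coordinates and box vectors are converted from nm to angstrom. Only
#' orthorhombic boxes (three box values) are accepted. The result keeps
#' residue/atom names for [coarse_grain()].
#'
#' @param path GRO file path.
#' @return A `raw_trajectory`: list of frames, each a tibble with columns
#'   `resid`, `resname`, `atom`, `x`, `y`, `z` (angstrom) plus a `box`
#'   attribute.
#' @export
read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) {
      abort(sprintf("truncated GRO file near line %d", i))
    }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) abort(sprintf("bad atom count at line %d", i + 1L))
    if (i + 2L + n > length(lines)) {
      abort(sprintf("truncated GRO frame starting at line %d", i))
    }
    at <- lines[(i + 2L):(i + 1L + n)]
    frame <- tibble(
      resid = as.integer(substr(at, 1L, 5L)),
      resname = trimws(substr(at, 6L, 10L)),
      atom = trimws(substr(at, 11L, 15L)),
      x = 10 * as.numeric(substr(at, 21L, 28L)),
      y = 10 * as.numeric(substr(at, 29L, 36L)),
      z = 10 * as.numeric(substr(at, 37L, 44L)))
    boxvals <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]])
    if (length(boxvals) != 3L || any(!is.finite(boxvals)) ||
        any(boxvals <= 0)) {
      abort(sprintf("non-orthorhombic or invalid box line at line %d",
                    i + 2L + n))
    }
    attr(frame, "box") <- 10 * boxvals
    frames[[length(frames) + 1L]] <- frame
    i <- i + 3L + n
  }
  structure(frames, class = "raw_trajectory")
}

#' Default coarse-graining rules
#'
#' One labeled point per molecule: TMAO by its nitrogen, urea by its
#' carbon, water (SOL) by its oxygen.
#'
#' @return A tibble with columns `resname`, `atom`, `type`.
#' @export
default_cg_rules <- function() {
  tibble(resname = c("TMAO", "UREA", "URE", "SOL", "SOL"),
         atom = c("N", "C", "C", "OW", "O"),
         type = c("OSMOLYTE", "OSMOLYTE", "OSMOLYTE", "WATER", "WATER"))
}

#' Coarse-grain a raw trajectory to labeled points
#'
#' Keeps, per molecule (residue), exactly the one atom named by the rule
#' and labels it with the rule's type.
#'
#' @param raw a [read_gro_frames()] result.
#' @param rules a rule tibble as from [default_cg_rules()].
#' @return A [mol_trajectory()].
#' @export
coarse_grain <- function(raw, rules = default_cg_rules()) {
  stopifnot(inherits(raw, "raw_trajectory"))
  frames <- lapply(seq_along(raw), function(fi) {
    frame <- raw[[fi]]
    unmapped <- setdiff(unique(frame$resname), unique(rules$resname))
    if (length(unmapped)) {
      abort(paste0("no coarse-grain rule for residue(s): ",
                   paste(unmapped, collapse = ", ")))
    }
    kept <- dplyr::inner_join(frame, rules, by = c("resname", "atom"))
    per_mol <- dplyr::count(kept, .data$resid, .data$resname)
    all_mols <- dplyr::distinct(frame, .data$resid, .data$resname)
    if (nrow(per_mol) != nrow(all_mols) || any(per_mol$n != 1L)) {
      abort("coarse-grain rule must keep exactly one atom per molecule")
    }
    mol_config(cbind(kept$x, kept$y, kept$z), attr(frame, "box"),
               types = kept$type, frame_index = fi - 1L)
  })
  mol_trajectory(frames)
}

#' Serialize barcodes to JSON
#'
#' Records of the form `{"dim": k, "birth": a, "death": b}` with infinite
#' deaths written as the string `"inf"`; an empty barcode is a valid empty
#' list. [read_barcodes_json()] restores the `ph_barcode`.
#'
#' @param barcode a `ph_barcode`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcodes_json <- function(barcode, path) {
  stopifnot(inherits(barcode, "ph_barcode"))
  recs <- purrr::pmap(
    list(barcode$dimension, barcode$birth, barcode$death),
    function(d, b, dd) {
      list(dim = d, birth = b,
           death = if (is.finite(dd)) dd else "inf")
    })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_barcodes_json
#' @export
read_barcodes_json <- function(path) {
  recs <- jsonlite::read_json(path)
  if (length(recs) == 0L) {
    return(new_barcode(integer(0), numeric(0), numeric(0)))
  }
  new_barcode(vapply(recs, function(r) as.integer(r$dim), integer(1)),
              vapply(recs, function(r) as.numeric(r$birth), numeric(1)),
              vapply(recs, function(r) {
                if (identical(r$death, "inf")) Inf else as.numeric(r$death)
              }, numeric(1)))
}

#' Write a descriptor curve as CSV
#'
#' Two columns with a header: the abscissa (`x` for PBN curves, `r` for
#' PRDF curves) and `value`, in deterministic row order.
#'
#' @param curve a `pbn_curve` or `prdf_curve` (any two-column tibble whose
#'   first column is the abscissa).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(as_tibble(curve)[, 1:2], path)
  invisible(path)
}
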