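#' Construct a conformer
#'
#' A conformer is one 3-D realisation of a small molecule: an ordered atom
#' table (element symbol plus Cartesian coordinates in Angstrom) and an
#' optional bond list. Atom order is significant throughout the package:
#' pose comparisons pair atoms positionally, so conformers read from the
#' same docking run keep their file order.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param bonds data frame with integer columns `from`, `to` (1-based atom
#'   indices) and `order`, or NULL for no connectivity.
#' @param name identifier carried through reports.
#' @return An object of class `conformer`.
#' @export
conformer <- function(elements, coords, bonds = NULL, name = "") {
  coords <- as.matrix(coords)
  if (length(elements) == 0L) stop("conformer needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching 'elements'")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(nzchar(elements))) stop("element symbols must be non-empty")
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("from", "to", "order") %in% names(bonds)))
    n <- length(elements)
    if (nrow(bonds) && (any(bonds$from < 1L | bonds$from > n) ||
                        any(bonds$to < 1L | bonds$to > n)))
      stop("bond indices out of range")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(elements = as.character(elements), coords = coords,
         bonds = bonds, name = as.character(name)),
    class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms (%d heavy), %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x), n_atoms(heavy_atom_view(x)), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a conformer
#' @param conf a `conformer`.
#' @return integer atom count.
#' @export
n_atoms <- function(conf) length(conf$elements)

#' Restrict a conformer to its heavy atoms
#'
#' Drops hydrogen and deuterium while preserving atom order; bonds touching
#' a dropped atom are removed and the remainder reindexed. Idempotent.
#'
#' @param conf a `conformer`.
#' @return A `conformer` containing only non-hydrogen atoms.
#' @export
heavy_atom_view <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  keep <- !is_hydrogen(conf$elements)
  if (!any(keep)) stop("conformer has no heavy atoms")
  if (all(keep)) return(conf)
  idx <- which(keep)
  remap <- integer(length(conf$elements))
  remap[idx] <- seq_along(idx)
  b <- conf$bonds
  b <- b[b$from %in% idx & b$to %in% idx, , drop = FALSE]
  b$from <- remap[b$from]
  b$to <- remap[b$to]
  conformer(conf$elements[idx], conf$coords[idx, , drop = FALSE],
            b, conf$name)
}

is_hydrogen <- function(elements) toupper(elements) %in% c("H", "D")

#' Construct a pose set
#'
#' A pose set bundles a reference conformer (typically the co-crystallised
#' ligand in the receptor frame) with an ordered ensemble of docked poses
#' of the same molecule and, optionally, per-pose scores from one or more
#' scoring functions. Pose order is the docking output order ("pose rank"
#' N means the pose at 1-based position N).
#'
#' @param reference a `conformer`.
#' @param poses list of `conformer` objects, same heavy-atom element
#'   sequence as `reference`.
#' @param scores named list of numeric vectors, one value per pose, keyed
#'   by scoring-function name. May be empty.
#' @param ligand_id identifier for the ligand.
#' @return An object of class `pose_set`.
#' @export
pose_set <- function(reference, poses, scores = list(), ligand_id = reference$name) {
  stopifnot(inherits(reference, "conformer"))
  if (length(poses) == 0L) stop("pose set needs at least one pose")
  ref_h <- heavy_atom_view(reference)
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    if (!inherits(p, "conformer")) stop("poses must be conformers")
    p_h <- heavy_atom_view(p)
    if (n_atoms(p_h) != n_atoms(ref_h))
      stop(sprintf("pose %d: heavy-atom count %d != reference %d",
                   i, n_atoms(p_h), n_atoms(ref_h)))
    if (!identical(sort(p_h$elements), sort(ref_h$elements)))
      stop(sprintf("pose %d: heavy-atom element multiset differs from reference", i))
  }
  if (length(scores)) {
    bad <- names(scores)[vapply(scores, length, 1L) != length(poses)]
    if (length(bad))
      stop("score vectors must have one value per pose: ", paste(bad, collapse = ", "))
  }
  structure(list(reference = reference, poses = poses,
                 scores = scores, ligand_id = as.character(ligand_id)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %s: %d poses, scores: %s\n", x$ligand_id,
              length(x$poses),
              if (length(x$scores)) paste(names(x$scores), collapse = ", ")
              else "(none)"))
  invisible(x)
}
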