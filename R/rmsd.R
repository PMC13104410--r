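#' In-place heavy-atom RMSD between a reference and a docked pose
#'
#' Root-mean-square deviation over non-hydrogen atoms, computed in the
#' shared (receptor) coordinate frame without re-superposition: redocking
#' accuracy is a statement about where the docking engine placed the
#' ligand, so the frames are never aligned first. With `symmetry = TRUE`
#' the RMSD is minimised over all element- and bond-preserving atom
#' permutations (graph automorphisms of the reference heavy-atom graph),
#' which removes artefactual RMSD from topologically equivalent atoms
#' (e.g. a flipped symmetric ring).
#'
#' @param ref,pose `conformer`s with identical heavy-atom element
#'   sequences. Atoms are paired by position after dropping hydrogens.
#' @param symmetry if TRUE, minimise over graph automorphisms.
#' @param max_mappings safety cap on the number of automorphisms examined.
#' @return RMSD in Angstrom (non-negative scalar).
#' @export
inplace_rmsd <- function(ref, pose, symmetry = FALSE, max_mappings = 1e4) {
  rh <- heavy_atom_view(ref)
  ph <- heavy_atom_view(pose)
  if (n_atoms(rh) != n_atoms(ph))
    stop(sprintf("heavy-atom count mismatch: reference %d vs pose %d",
                 n_atoms(rh), n_atoms(ph)))
  if (!identical(rh$elements, ph$elements))
    stop("heavy-atom element sequences differ between reference and pose")
  A <- rh$coords
  B <- ph$coords
  identity_rmsd <- coord_rmsd(A, B)
  if (!symmetry) return(identity_rmsd)
  maps <- heavy_automorphisms(rh, max_mappings)
  min(vapply(maps, function(p) coord_rmsd(A[p, , drop = FALSE], B),
             numeric(1)))
}

coord_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# Element- and bond-preserving automorphisms of a heavy-atom graph,
# as permutation vectors (position i of the result holds the atom mapped
# onto atom i). Enumerated with VF2 on an element-coloured graph.
heavy_automorphisms <- function(conf, max_mappings = 1e4) {
  n <- n_atoms(conf)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(conf$bonds))
    g <- igraph::add_edges(g, rbind(conf$bonds$from, conf$bonds$to))
  col <- as.integer(factor(conf$elements))
  n_maps <- igraph::count_isomorphisms(g, g, method = "vf2",
                                       vertex.color1 = col,
                                       vertex.color2 = col)
  if (n_maps > max_mappings)
    stop(sprintf("automorphism group too large (%d > cap %d)",
                 n_maps, max_mappings))
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = col, vertex.color2 = col)
  lapply(maps, as.integer)
}

#' Best (lowest-RMSD) pose in a comparison list
#'
#' @param rmsds numeric vector of per-pose RMSD values in pose (file)
#'   order.
#' @return list with `rmsd` (the minimum) and `rank` (its 1-based
#'   position; ties resolve to the lowest position).
#' @export
best_pose <- function(rmsds) {
  if (!length(rmsds)) stop("empty RMSD list")
  i <- which.min(rmsds)
  list(rmsd = rmsds[i], rank = i)
}

#' RMSD of the top-scored pose under one scoring function
#'
#' Selects the pose the scoring function ranks first (highest score for
#' `orientation = "higher"`, lowest for `"lower"`; ties resolve to file
#' order) and returns that pose's RMSD to the reference together with its
#' pose rank (1-based file position).
#'
#' @param ps a [pose_set] whose `scores` contain `fun`.
#' @param fun scoring-function name.
#' @param orientation "higher" (better) or "lower".
#' @param symmetry passed to [inplace_rmsd].
#' @return list with `rmsd` and `rank`.
#' @export
top_pose_rmsd <- function(ps, fun, orientation = c("higher", "lower"),
                          symmetry = FALSE) {
  orientation <- match.arg(orientation)
  if (!fun %in% names(ps$scores))
    stop("no score vector named '", fun, "' in pose set ", ps$ligand_id)
  s <- ps$scores[[fun]]
  i <- if (orientation == "higher") which.max(s) else which.min(s)
  list(rmsd = inplace_rmsd(ps$reference, ps$poses[[i]], symmetry = symmetry),
       rank = i)
}

#' Redocking success rate
#'
#' Percentage of ligands whose RMSD falls strictly below the cutoff:
#' 100 x (number of ligands < cutoff) / (total ligands). The boundary is
#' exclusive: an RMSD exactly at the cutoff does not count as a success.
#'
#' @param rmsds numeric vector, one RMSD per ligand.
#' @param cutoff success threshold in Angstrom (default 2).
#' @return list with `n_success`, `n_total`, `rate` (exact percent) and
#'   `percent` (rounded to the nearest whole percent, as reported).
#' @export
success_rate <- function(rmsds, cutoff = 2) {
  if (!length(rmsds)) stop("empty RMSD list")
  stopifnot(cutoff > 0)
  n_success <- sum(rmsds < cutoff)
  n_total <- length(rmsds)
  rate <- 100 * n_success / n_total
  list(n_success = n_success, n_total = n_total,
       rate = rate, percent = round_half_up(rate, 0))
}

#' Mean RMSD across ligands
#'
#' @param rmsds numeric vector.
#' @return list with `mean` (exact) and `reported` (1-decimal rounding, as
#'   tabulated).
#' @export
average_rmsd <- function(rmsds) {
  if (!length(rmsds)) stop("empty RMSD list")
  m <- mean(rmsds)
  list(mean = m, reported = round_half_up(m, 1))
}

#' Summarise redocking accuracy for one docking algorithm
#'
#' For each ligand's pose set: the best pose (minimum RMSD over the whole
#' ensemble) and, per scoring function, the RMSD of the top-scored pose.
#' Column summaries give the success count, success rate and average RMSD
#' of the best-pose column and of every scoring-function column.
#'
#' @param pose_sets named list of [pose_set]s (one per ligand), all scored
#'   by the same functions.
#' @param cutoff success threshold in Angstrom.
#' @param orientations named character vector of score orientations per
#'   function; unnamed functions default to "higher".
#' @param symmetry passed to [inplace_rmsd].
#' @param algorithm label carried into reports.
#' @return A `redock_summary`: list with `per_ligand` (data frame of RMSD
#'   and rank per column), `n_success`, `success_percent`, `success_rate`
#'   (exact), `average_rmsd` per column, plus `cutoff` and `algorithm`.
#' @export
redock_summary <- function(pose_sets, cutoff = 2, orientations = NULL,
                           symmetry = FALSE, algorithm = "") {
  stopifnot(length(pose_sets) >= 1L)
  funs <- names(pose_sets[[1L]]$scores)
  for (ps in pose_sets)
    if (!identical(names(ps$scores), funs))
      stop("all pose sets must carry the same scoring functions")
  orient_of <- function(f) {
    if (!is.null(orientations) && f %in% names(orientations))
      orientations[[f]] else "higher"
  }
  rows <- lapply(pose_sets, function(ps) {
    rmsds <- vapply(ps$poses, function(p)
      inplace_rmsd(ps$reference, p, symmetry = symmetry), numeric(1))
    bp <- best_pose(rmsds)
    row <- data.frame(ligand = ps$ligand_id, n_poses = length(ps$poses),
                      best_rmsd = bp$rmsd, best_rank = bp$rank,
                      stringsAsFactors = FALSE)
    for (f in funs) {
      tp <- top_pose_rmsd(ps, f, orient_of(f), symmetry = symmetry)
      row[[paste0(f, "_rmsd")]] <- tp$rmsd
      row[[paste0(f, "_rank")]] <- tp$rank
    }
    row
  })
  per_ligand <- do.call(rbind, c(rows, make.row.names = FALSE))
  cols <- c(best = "best_rmsd",
            stats::setNames(paste0(funs, "_rmsd"), funs))
  sr <- lapply(cols, function(cn) success_rate(per_ligand[[cn]], cutoff))
  av <- lapply(cols, function(cn) average_rmsd(per_ligand[[cn]]))
  structure(list(
    per_ligand = per_ligand,
    columns = names(cols),
    n_success = vapply(sr, `[[`, 0, "n_success"),
    n_total = length(pose_sets),
    success_percent = vapply(sr, `[[`, 0, "percent"),
    success_rate = vapply(sr, `[[`, 0, "rate"),
    average_rmsd = vapply(av, `[[`, 0, "reported"),
    average_rmsd_exact = vapply(av, `[[`, 0, "mean"),
    cutoff = cutoff, algorithm = algorithm),
    class = "redock_summary")
}

#' Combined redocking report across docking algorithms
#'
#' Stacks per-algorithm summaries into one long-form table (per-ligand
#' best/top RMSD with pose rank, then Total, Success rate and Average RMSD
#' rows per algorithm) and appends an overall success-rate row that pools
#' the ligand counts of all algorithms, so two algorithms at 2/3 each pool
#' to 4/6 = 67%.
#'
#' @param summaries list of `redock_summary` objects over the same ligand
#'   set.
#' @return A data frame shaped like a published redocking table: columns
#'   `algorithm`, `row`, then one column per summary column ("best" and
#'   each scoring function).
#' @export
redock_table <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  ligs <- sort(summaries[[1L]]$per_ligand$ligand)
  cols <- summaries[[1L]]$columns
  for (s in summaries) {
    if (!identical(sort(s$per_ligand$ligand), ligs))
      stop("summaries cover different ligand sets")
    if (!identical(s$columns, cols))
      stop("summaries cover different scoring-function columns")
  }
  fmt_cell <- function(rmsd, rank) sprintf("%.2f (%d)", rmsd, rank)
  out <- list()
  for (s in summaries) {
    pl <- s$per_ligand
    for (i in seq_len(nrow(pl))) {
      vals <- c(fmt_cell(pl$best_rmsd[i], pl$best_rank[i]),
                vapply(setdiff(cols, "best"), function(f)
                  fmt_cell(pl[[paste0(f, "_rmsd")]][i],
                           pl[[paste0(f, "_rank")]][i]), ""))
      out[[length(out) + 1L]] <- c(algorithm = s$algorithm,
                                   row = pl$ligand[i], vals)
    }
    out[[length(out) + 1L]] <- c(algorithm = s$algorithm, row = "Total",
                                 as.character(s$n_success))
    out[[length(out) + 1L]] <- c(algorithm = s$algorithm, row = "Success rate",
                                 paste0(s$success_percent, "%"))
    out[[length(out) + 1L]] <- c(algorithm = s$algorithm, row = "Average RMSD",
                                 sprintf("%.1f", s$average_rmsd))
  }
  pooled_n <- Reduce(`+`, lapply(summaries, `[[`, "n_success"))
  pooled_tot <- sum(vapply(summaries, `[[`, 0L, "n_total"))
  overall <- round_half_up(100 * pooled_n / pooled_tot, 0)
  out[[length(out) + 1L]] <- c(algorithm = "All", row = "Overall success rate",
                               paste0(overall, "%"))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("algorithm", "row", cols)
  df
}

# round half away from zero, the convention of printed report tables
# (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
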