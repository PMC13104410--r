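#' Build the toy reference ligand used by the synthetic pose generators
#'
#' A branched drug-like scaffold of 20 heavy atoms (one aromatic
#' six-ring, two heteroatom-bearing chains) with three explicit
#' hydrogens. The ring gives the molecule a non-trivial automorphism
#' group, so both the identity and the symmetry-corrected RMSD paths are
#' exercised by fixtures built on it.
#'
#' @param name conformer name.
#' @return A `conformer`.
#' @export
make_toy_ligand <- function(name = "TOY") {
  ring_ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(1.39 * cos(ring_ang), 1.39 * sin(ring_ang), 0)
  chain <- rbind(
    c(2.90, 0.00, 0.00),   # C7  (on C1)
    c(3.65, 1.20, 0.40),   # C8
    c(5.05, 1.10, 0.55),   # O9
    c(3.05, 2.45, 0.60),   # C10
    c(3.75, 3.60, 1.05),   # N11
    c(1.60, 2.60, 0.35),   # C12
    c(5.80, 2.20, 0.90),   # C13
    c(-2.90, 0.00, 0.00),  # O14 (on C4)
    c(-3.65, -1.15, 0.35), # C15
    c(-5.10, -1.00, 0.30), # C16
    c(-5.90, -2.20, 0.65), # O17
    c(-3.10, -2.45, 0.70), # C18
    c(5.25, 4.55, 0.10),   # C19 (on N11)
    c(3.10, 4.85, 1.45))   # C20 (on N11)
  hs <- rbind(
    c(3.45, -0.90, -0.30), # H on C7
    c(-3.40, 0.80, 0.30),  # H near O14 side chain
    c(1.10, 3.55, 0.55))   # H on C12
  coords <- rbind(ring, chain, hs)
  elements <- c(rep("C", 6),
                "C", "C", "O", "C", "N", "C", "C",
                "O", "C", "C", "O", "C", "C", "C",
                "H", "H", "H")
  bonds <- data.frame(
    from = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 8, 10, 10, 9, 4, 14, 15, 16, 15, 11, 11, 7, 16, 12),
    to   = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23),
    order = 1L)
  conformer(elements, coords, bonds, name)
}

#' Generate docked-pose ensembles with controlled RMSD to a reference
#'
#' Translation mode displaces every atom by a random unit vector scaled
#' to the target: a uniform translation of magnitude t has heavy-atom
#' RMSD exactly t, so the targets are hit to floating-point precision.
#' Jitter mode additionally rotates the pose about its heavy-atom
#' centroid (angle found by bisection to contribute about half the
#' target), then tops up with a translation of magnitude
#' sqrt(target^2 - rmsd_rot^2); rotation about the centroid leaves the
#' mean displacement zero, so the two contributions add in quadrature and
#' the achieved RMSD lands well inside 0.01 Angstrom of the target while
#' the pose stays rigid.
#'
#' @param ref reference `conformer`.
#' @param rmsd_targets non-negative RMSD targets in Angstrom, one pose
#'   each.
#' @param seed integer seed; identical seed and arguments give identical
#'   poses.
#' @param mode "translate" (exact) or "jitter" (rigid rotation +
#'   translation).
#' @return list of `conformer` poses, in target order.
#' @export
gen_translated_poses <- function(ref, rmsd_targets, seed = 1,
                                 mode = c("translate", "jitter")) {
  mode <- match.arg(mode)
  if (any(rmsd_targets < 0)) stop("RMSD targets must be >= 0")
  set.seed(as.integer(seed))
  lapply(seq_along(rmsd_targets), function(i) {
    t_target <- rmsd_targets[i]
    if (mode == "translate" || t_target == 0) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- ref
      p$coords <- ref$coords + rep(t_target * u, each = nrow(ref$coords))
      p$name <- sprintf("%s_pose%d", ref$name, i)
      return(p)
    }
    jitter_pose(ref, t_target, i)
  })
}

jitter_pose <- function(ref, t_target, i) {
  heavy <- !is_hydrogen(ref$elements)
  centroid <- colMeans(ref$coords[heavy, , drop = FALSE])
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  rot_rmsd <- function(theta) {
    R <- rotation_matrix(axis, theta)
    moved <- sweep(ref$coords[heavy, , drop = FALSE], 2, centroid) %*% t(R)
    moved <- sweep(moved, 2, centroid, `+`)
    coord_rmsd(ref$coords[heavy, , drop = FALSE], moved)
  }
  goal <- t_target / 2
  lo <- 0; hi <- pi
  if (rot_rmsd(hi) < goal) {
    theta <- hi  # small/compact molecule: take the full rotation
  } else {
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (rot_rmsd(mid) < goal) lo <- mid else hi <- mid
    }
    theta <- (lo + hi) / 2
  }
  R <- rotation_matrix(axis, theta)
  coords <- sweep(ref$coords, 2, centroid) %*% t(R)
  coords <- sweep(coords, 2, centroid, `+`)
  achieved <- coord_rmsd(ref$coords[heavy, , drop = FALSE],
                         coords[heavy, , drop = FALSE])
  t_extra <- sqrt(max(0, t_target^2 - achieved^2))
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  p <- ref
  p$coords <- coords + rep(t_extra * u, each = nrow(coords))
  p$name <- sprintf("%s_pose%d", ref$name, i)
  p
}

rotation_matrix <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c_, x * y * C - z * s_, x * z * C + y * s_,
           y * x * C + z * s_, y * y * C + c_, y * z * C - x * s_,
           z * x * C - y * s_, z * y * C + x * s_, z * z * C + c_),
         3, 3, byrow = TRUE)
}

#' Generate a seeded active/decoy score table with controlled separation
#'
#' Decoy scores are standard normal; active scores are shifted by
#' `delta`, so the expected AUC of the resulting screen is
#' Phi(delta / sqrt(2)) under the binormal model. A large delta (e.g. 10)
#' forces an essentially perfect ranking, the regime in which the
#' enrichment factor reaches its ceiling.
#'
#' @param n_decoys,n_actives compound counts (>= 1 each).
#' @param delta mean score separation between actives and decoys, in
#'   decoy standard deviations.
#' @param orientation "higher" (actives shifted up) or "lower" (down).
#' @param seed integer seed.
#' @param combination name of the score column.
#' @return A [score_table] with `n_decoys + n_actives` rows.
#' @export
gen_seeded_database <- function(n_decoys = 300, n_actives = 3, delta = 3,
                                orientation = c("higher", "lower"),
                                seed = 1, combination = "score") {
  orientation <- match.arg(orientation)
  stopifnot(n_decoys >= 1, n_actives >= 1)
  set.seed(as.integer(seed))
  shift <- if (orientation == "higher") delta else -delta
  scores <- c(rnorm(n_decoys), rnorm(n_actives) + shift)
  ids <- c(sprintf("DEC%04d", seq_len(n_decoys)),
           sprintf("ACT%02d", seq_len(n_actives)))
  labels <- c(rep("decoy", n_decoys), rep("active", n_actives))
  score_table(ids, labels, stats::setNames(list(scores), combination))
}

#' Generate a sink-condition Franz diffusion cell time course
#'
#' Linear permeation model: Q(t) = Papp x A x C0 x max(0, t - lag), with
#' t in seconds internally. Full-volume withdrawal means each sampled
#' concentration reflects only the interval since the previous sample:
#' C_n = (Q(t_n) - Q(t_{n-1})) / V_acceptor, perturbed by multiplicative
#' noise with coefficient of variation `noise_cv` (assay precision is
#' naturally relative, so the noise model is CV-based).
#'
#' @param true_papp apparent permeability in cm/s.
#' @param C0 donor concentration, ug/mL.
#' @param area diffusion area, cm^2 (default 1.77, a typical Franz cell).
#' @param V_acceptor,V_donor chamber volumes, mL.
#' @param times sampling schedule in minutes.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param n_replicates number of diffusion cells.
#' @param lag_min lag time before steady state, minutes.
#' @param seed integer seed.
#' @return A [franz_experiment].
#' @export
gen_franz_series <- function(true_papp, C0, area = 1.77,
                             V_acceptor = 2, V_donor = 1,
                             times = c(20, 40, 60, 80, 100, 120),
                             noise_cv = 0, n_replicates = 6,
                             lag_min = 0, seed = 1) {
  stopifnot(true_papp >= 0, C0 > 0, area > 0, noise_cv >= 0,
            n_replicates >= 1)
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("times must be positive and strictly increasing")
  set.seed(as.integer(seed))
  Q <- true_papp * area * C0 * pmax(0, times - lag_min) * 60  # ug
  dq <- diff(c(0, Q))
  conc_clean <- dq / V_acceptor
  conc <- vapply(seq_len(n_replicates), function(j)
    pmax(0, conc_clean * (1 + rnorm(length(times), 0, noise_cv))),
    numeric(length(times)))
  franz_experiment(times = times, conc = conc, C0_donor = C0,
                   area = area, V_acceptor = V_acceptor,
                   V_donor = V_donor, withdrawal = "full")
}

# Published-style redocking layout used by gen_redock_fixture: per
# structure and docking algorithm, each ligand's pose count, its best
# (minimum) RMSD with pose position, and per scoring function the RMSD
# and position of the top-scored pose. Scoring-function column order is
# fixed: Native, LigScore1, LigScore2, PLP1, PLP2, Jain, PMF, PMF4.
redock_layout <- function() {
  fns <- c("Native", "LigScore1", "LigScore2", "PLP1", "PLP2",
           "Jain", "PMF", "PMF4")
  L <- function(n, best, ...) {
    cells <- list(...)
    stopifnot(length(cells) == 8)
    names(cells) <- fns
    list(n_poses = n, best = best, cells = cells)
  }
  # each cell is c(rmsd, pose position); native top pose is position 1
  list(
    `6PT0` = list(
      LibDock = list(
        `9JU` = L(98, c(1.16, 96), c(8.68, 1), c(1.84, 72), c(1.84, 72),
                  c(8.60, 7), c(8.60, 7), c(8.82, 16), c(4.58, 87), c(4.58, 87)),
        E3R = L(98, c(1.65, 81), c(7.99, 1), c(8.10, 26), c(8.10, 26),
                c(7.83, 3), c(7.83, 3), c(4.66, 66), c(1.65, 81), c(1.65, 81)),
        `5IW` = L(100, c(1.02, 57), c(1.87, 1), c(1.02, 57), c(1.02, 57),
                  c(1.63, 15), c(1.87, 1), c(2.54, 45), c(2.09, 30), c(7.95, 97))),
      LigandFit = list(
        `9JU` = L(100, c(1.18, 65), c(1.84, 1), c(1.63, 30), c(1.92, 81),
                  c(1.37, 12), c(1.64, 47), c(1.63, 30), c(1.77, 24), c(2.06, 100)),
        E3R = L(100, c(1.41, 93), c(8.11, 1), c(8.01, 4), c(8.28, 10),
                c(2.59, 86), c(2.59, 86), c(2.59, 86), c(8.09, 33), c(8.24, 100)),
        `5IW` = L(7, c(1.00, 2), c(1.06, 1), c(1.06, 1), c(1.06, 1),
                  c(1.06, 1), c(1.06, 1), c(8.40, 6), c(1.06, 1), c(2.46, 7)))),
    `6KPC` = list(
      LibDock = list(
        `9JU` = L(98, c(1.96, 34), c(8.46, 1), c(3.32, 15), c(3.32, 15),
                  c(8.46, 1), c(8.46, 1), c(8.46, 1), c(3.32, 15), c(3.32, 15)),
        E3R = L(98, c(0.67, 41), c(2.20, 1), c(0.76, 15), c(0.76, 15),
                c(2.20, 1), c(2.20, 1), c(7.62, 73), c(0.67, 41), c(0.67, 41)),
        `5IW` = L(100, c(1.58, 49), c(1.97, 1), c(8.42, 58), c(8.42, 58),
                  c(1.81, 3), c(2.60, 23), c(2.71, 94), c(2.16, 18), c(2.16, 18))),
      LigandFit = list(
        `9JU` = L(100, c(2.38, 42), c(2.53, 1), c(2.59, 10), c(2.71, 47),
                  c(2.73, 76), c(2.56, 59), c(2.80, 15), c(2.73, 77), c(2.69, 53)),
        E3R = L(100, c(0.68, 57), c(0.81, 1), c(1.15, 49), c(0.81, 1),
                c(0.74, 14), c(0.74, 14), c(1.73, 96), c(0.80, 17), c(0.88, 51)),
        `5IW` = L(7, c(1.04, 54), c(2.20, 1), c(8.32, 51), c(1.23, 22),
                  c(1.33, 3), c(1.41, 6), c(1.96, 33), c(2.33, 2), c(2.33, 2)))),
    `5ZTY` = list(
      LibDock = list(
        `9JU` = L(98, c(1.46, 71), c(6.98, 1), c(1.97, 24), c(1.97, 24),
                  c(7.21, 9), c(7.21, 9), c(7.30, 84), c(2.18, 69), c(7.21, 9)),
        E3R = L(98, c(10.72, 17), c(12.05, 1), c(11.54, 63), c(12.18, 85),
                c(11.20, 2), c(11.20, 2), c(12.78, 64), c(11.94, 3), c(11.94, 3)),
        `5IW` = L(100, c(1.27, 23), c(7.72, 1), c(5.27, 10), c(5.27, 10),
                  c(6.60, 2), c(6.60, 2), c(7.79, 40), c(8.05, 62), c(7.94, 55))),
      LigandFit = list(
        `9JU` = L(100, c(0.85, 7), c(0.97, 1), c(1.18, 40), c(1.19, 26),
                  c(0.97, 1), c(1.07, 78), c(1.51, 85), c(1.20, 13), c(1.20, 13)),
        E3R = L(100, c(10.92, 37), c(11.88, 1), c(11.91, 25), c(11.94, 100),
                c(11.77, 29), c(11.77, 29), c(11.85, 61), c(11.59, 10), c(11.60, 8)),
        `5IW` = L(7, c(0.72, 1), c(0.72, 1), c(0.72, 1), c(0.72, 1),
                  c(1.39, 48), c(1.39, 48), c(7.93, 18), c(0.72, 1), c(7.88, 61)))))
}

#' Generate a redocking regression fixture for one structure/algorithm
#'
#' Builds pose sets whose measured per-pose RMSDs and per-function
#' top-pose positions reproduce a published-style redocking layout, so
#' [redock_summary] and [redock_table] can be regression-tested end to
#' end. For each ligand the designated pose positions receive poses at
#' the tabulated RMSD (all other positions get a large filler RMSD) and
#' each scoring function's score vector peaks at its tabulated position.
#' Pose-count cells whose printed value is smaller than the largest
#' tabulated position are widened to that position. The layout itself is
#' constant; the seed only changes the geometric realisation of the
#' poses.
#'
#' @param structure one of "6PT0", "6KPC", "5ZTY".
#' @param algorithm "LibDock" or "LigandFit".
#' @param seed integer seed.
#' @return list with `pose_sets` (named by ligand), `structure`,
#'   `algorithm` and `functions` (scoring-function column order).
#' @export
gen_redock_fixture <- function(structure = c("6PT0", "6KPC", "5ZTY"),
                               algorithm = c("LibDock", "LigandFit"),
                               seed = 1) {
  structure <- match.arg(structure)
  algorithm <- match.arg(algorithm)
  layout <- redock_layout()[[structure]][[algorithm]]
  ref0 <- make_toy_ligand()
  filler <- 15
  pose_sets <- lapply(names(layout), function(lig) {
    lay <- layout[[lig]]
    positions <- c(lay$best[2],
                   vapply(lay$cells, `[`, 0, 2))
    values <- c(lay$best[1], vapply(lay$cells, `[`, 0, 1))
    n <- max(lay$n_poses, positions)
    target <- rep(filler, n)
    for (k in seq_along(positions)) {
      p <- positions[k]
      if (target[p] != filler && abs(target[p] - values[k]) > 1e-9)
        stop(sprintf("layout conflict at %s pose %d: %.2f vs %.2f",
                     lig, p, target[p], values[k]))
      target[p] <- values[k]
    }
    if (min(target) < lay$best[1] - 1e-9)
      stop("layout conflict: best pose is not the ensemble minimum")
    ref <- ref0
    ref$name <- lig
    # shave a relative 1e-12 off the targets so achieved values can only
    # sit below the tabulated ones, keeping reported column means stable
    poses <- gen_translated_poses(ref, target * (1 - 1e-12),
                                  seed = seed + match(lig, names(layout)))
    scores <- lapply(lay$cells, function(cell)
      -abs(seq_len(n) - cell[2]))
    pose_set(ref, poses, scores, ligand_id = lig)
  })
  names(pose_sets) <- names(layout)
  list(pose_sets = pose_sets, structure = structure,
       algorithm = algorithm, functions = names(layout[[1]]$cells))
}
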