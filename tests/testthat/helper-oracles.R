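# Independent brute-force oracles used across the suite. These stay
# deliberately naive: enumeration and event simulation, no shared code
# with the implementation paths they check.

# all permutations of 1..n (n small), cached per n
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (n == 1L) list(1L) else {
    out <- list()
    for (p in all_perms(n - 1L)) {
      for (k in seq_len(n)) {
        out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
      }
    }
    out
  }
  .perm_cache[[key]] <- res
  res
}

# brute-force symmetry-corrected RMSD: minimum over every permutation of
# pose atoms that preserves elements and the bond set
brute_symmetry_rmsd <- function(ref, pose) {
  rh <- heavy_atom_view(ref)
  ph <- heavy_atom_view(pose)
  n <- n_atoms(rh)
  edge_set <- function(b, perm = seq_len(n)) {
    if (!nrow(b)) return(character())
    sort(paste(pmin(perm[b$from], perm[b$to]),
               pmax(perm[b$from], perm[b$to])))
  }
  ref_edges <- edge_set(rh$bonds)
  best <- Inf
  for (perm in all_perms(n)) {
    perm <- as.integer(perm)
    if (!identical(rh$elements[perm], rh$elements)) next
    if (!identical(edge_set(rh$bonds, order(perm)), ref_edges)) next
    d <- rh$coords[perm, , drop = FALSE] - ph$coords
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

# pairwise-concordance AUC by explicit double loop, ties = 1/2
brute_auc <- function(active_scores, decoy_scores) {
  tot <- 0
  for (a in active_scores) {
    for (d in decoy_scores) {
      tot <- tot + if (a > d) 1 else if (a == d) 0.5 else 0
    }
  }
  tot / (length(active_scores) * length(decoy_scores))
}

# mass-balance event simulation of a Franz cell sampling protocol:
# between samples the acceptor accumulates the permeated mass; at each
# sample V_withdraw mL is removed (and assayed) and replaced with blank
# buffer. Returns the sampled concentrations and the cumulative amount
# recovered, per time point.
simulate_franz_events <- function(perm_rate_ug_min, times,
                                  V_acceptor = 2, V_withdraw = V_acceptor) {
  amount_in_acceptor <- 0
  t_prev <- 0
  conc <- cum <- numeric(length(times))
  removed_total <- 0
  for (i in seq_along(times)) {
    amount_in_acceptor <- amount_in_acceptor +
      perm_rate_ug_min * (times[i] - t_prev)
    c_i <- amount_in_acceptor / V_acceptor
    removed <- c_i * V_withdraw
    amount_in_acceptor <- amount_in_acceptor - removed
    removed_total <- removed_total + removed
    conc[i] <- c_i
    # cumulative permeated so far = everything removed + what remains
    cum[i] <- removed_total + amount_in_acceptor
    t_prev <- times[i]
  }
  list(conc = conc, cumulative = cum)
}

# small labelled table for enrichment tests
random_score_table <- function(n_decoys, n_actives, seed) {
  set.seed(seed)
  score_table(
    c(sprintf("d%03d", seq_len(n_decoys)), sprintf("a%02d", seq_len(n_actives))),
    c(rep("decoy", n_decoys), rep("active", n_actives)),
    list(s = stats::rnorm(n_decoys + n_actives)))
}

# tiny para-substituted ring: planar C6 ring in the xy-plane with two
# on-axis substituents, so a 180-degree rotation about the x-axis is a
# bond-preserving automorphism realised by a rigid motion
para_ring <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  subs <- rbind(c(2.9, 0, 0), c(-2.9, 0, 0))
  conformer(c(rep("C", 6), "O", "O"), rbind(ring, subs),
            data.frame(from = c(1:6, 1, 4), to = c(2:6, 1, 7, 8),
                       order = 1L),
            "para")
}

rotate_about_x <- function(conf) {
  conf$coords[, 2] <- -conf$coords[, 2]
  conf$coords[, 3] <- -conf$coords[, 3]
  conf
}
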