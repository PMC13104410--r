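#' Rank a seeded database under one docking/scoring combination
#'
#' Sorts compounds by orientation-adjusted score, best first; ties keep
#' input order (stable sort). Compounds without a score for this
#' combination are placed last and flagged unscored — a compound a
#' docking run failed to place is not the same as a bad score, and
#' unscored compounds are excluded from enrichment and ROC statistics.
#'
#' @param table a [score_table].
#' @param combination name of the score column to rank by.
#' @param orientation "higher" if larger scores are better, else "lower".
#' @return A `ranked_list`: data frame with `compound_id`, `label`,
#'   `score`, `scored` (logical), ordered best first, with attributes
#'   `combination` and `orientation`.
#' @export
rank_compounds <- function(table, combination,
                           orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (!combination %in% names(table))
    stop("no score column named '", combination, "'")
  s <- table[[combination]]
  scored <- !is.na(s)
  if (!any(scored & table$label == "active"))
    stop("no scored active compounds under ", combination)
  if (!any(scored & table$label == "decoy"))
    stop("no scored decoy compounds under ", combination)
  key <- if (orientation == "higher") -s else s
  key[!scored] <- Inf  # unscored sink to the bottom
  ord <- order(key)    # radix/stable: ties keep input order
  out <- data.frame(compound_id = table$compound_id[ord],
                    label = table$label[ord], score = s[ord],
                    scored = scored[ord], stringsAsFactors = FALSE)
  attr(out, "combination") <- combination
  attr(out, "orientation") <- orientation
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Enrichment factor at a top fraction of a ranked database
#'
#' EF = (Hits_sel / Hits_tot) x (NC_tot / NC_sel), where NC_tot counts
#' the scored compounds, NC_sel = floor(fraction x NC_tot) is the
#' selection size, Hits_tot the scored actives and Hits_sel the actives
#' inside the selection. With floor, a 303-compound database at 10% gives
#' NC_sel = 30 and a perfect screen reaches EF = 10.1.
#'
#' @param ranked a `ranked_list` from [rank_compounds].
#' @param fraction top fraction of the database to select (0, 1].
#' @return An `enrichment_result`: list with `fraction`, `Hits_sel`,
#'   `Hits_tot`, `NC_tot`, `NC_sel`, `ef` (exact), `ef_reported`
#'   (1 decimal) and `ef_max`.
#' @export
enrichment_factor <- function(ranked, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  sc <- ranked[ranked$scored, , drop = FALSE]
  NC_tot <- nrow(sc)
  Hits_tot <- sum(sc$label == "active")
  if (Hits_tot == 0L) stop("no scored actives")
  NC_sel <- floor(fraction * NC_tot)
  if (NC_sel == 0L) stop("selection size is zero at fraction ", fraction)
  Hits_sel <- sum(sc$label[seq_len(NC_sel)] == "active")
  ef <- (Hits_sel / Hits_tot) * (NC_tot / NC_sel)
  structure(list(fraction = fraction, Hits_sel = Hits_sel,
                 Hits_tot = Hits_tot, NC_tot = NC_tot, NC_sel = NC_sel,
                 ef = ef, ef_reported = round_half_up(ef, 1),
                 ef_max = NC_tot / Hits_tot),
            class = "enrichment_result")
}

#' Maximum attainable enrichment factor
#'
#' The EF reached when the selection is exactly the actives
#' (Hits_sel = Hits_tot, NC_sel = Hits_tot): NC_tot / Hits_tot. A
#' 303-compound database with 3 actives caps at 101; 271 compounds cap
#' at 90.3.
#'
#' @param NC_tot total number of scored compounds.
#' @param Hits_tot number of actives.
#' @return list with `ef_max` (exact) and `reported` (1 decimal).
#' @export
max_enrichment_factor <- function(NC_tot, Hits_tot) {
  stopifnot(NC_tot >= 1)
  if (Hits_tot < 1) stop("need at least one active")
  if (Hits_tot > NC_tot) stop("more actives than compounds")
  m <- NC_tot / Hits_tot
  list(ef_max = m, reported = round_half_up(m, 1))
}

#' ROC curve and AUC for an active/decoy ranking
#'
#' The AUC is the probability that a random active outranks a random
#' decoy, computed by the tie-aware pairwise-concordance (rank-sum)
#' formulation: ties count 1/2. This equals the trapezoidal area under
#' the tie-aware ROC curve. The standard error follows Hanley & McNeil,
#' and the p-value against AUC = 0.5 uses the normal approximation to the
#' Mann-Whitney statistic with tie-corrected variance. The quality band
#' uses the conventional cut-offs: excellent [0.9, 1.0], good [0.8, 0.9),
#' fair [0.7, 0.8), poor [0.5, 0.7), failure below 0.5.
#'
#' @param ranked a `ranked_list`; unscored compounds are excluded.
#' @return A `roc_result`: list with `curve` (data frame fpr/tpr, from
#'   (0,0) to (1,1)), `auc`, `se`, `p_vs_half`, `stars` ("" / "*" / "**"
#'   at 0.05 / 0.01), `band`, `n_active`, `n_decoy`.
#' @export
roc_auc <- function(ranked) {
  sc <- ranked[ranked$scored, , drop = FALSE]
  act <- sc$label == "active"
  na_ <- sum(act)
  nd <- sum(!act)
  if (na_ == 0L || nd == 0L)
    stop("ROC needs at least one scored active and one scored decoy")
  # orientation-adjusted score: larger = better for both orientations
  adj <- if (attr(ranked, "orientation") == "higher") sc$score else -sc$score
  r <- rank(adj)  # midranks
  auc <- (sum(r[act]) - na_ * (na_ + 1) / 2) / (na_ * nd)

  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (na_ - 1) * (q1 - auc^2) +
                (nd - 1) * (q2 - auc^2)) / (na_ * nd))

  # normal approximation to the rank-sum statistic, tie-corrected
  n <- na_ + nd
  u <- auc * na_ * nd
  ties <- table(adj)
  var_u <- na_ * nd / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (var_u <= 0) 1 else 2 * stats::pnorm(-abs(u - na_ * nd / 2) / sqrt(var_u))
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""

  structure(list(curve = roc_curve_points(adj, act), auc = auc, se = se,
                 p_vs_half = p, stars = stars, band = auc_band(auc),
                 n_active = na_, n_decoy = nd),
            class = "roc_result")
}

# tie-aware ROC polyline: one vertex per distinct score threshold
roc_curve_points <- function(adj, act) {
  ord <- order(adj, decreasing = TRUE)
  a <- act[ord]
  s <- adj[ord]
  grp <- cumsum(!duplicated(s))       # runs of tied scores
  tp <- cumsum(a)
  fp <- cumsum(!a)
  last <- which(!duplicated(grp, fromLast = TRUE))
  data.frame(fpr = c(0, fp[last] / sum(!act)),
             tpr = c(0, tp[last] / sum(act)))
}

#' Quality band of a ROC-AUC value
#'
#' @param auc AUC in [0, 1].
#' @return one of "excellent", "good", "fair", "poor", "failure".
#' @export
auc_band <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.5) "poor"
  else "failure"
}

#' Trapezoidal area under a ROC polyline
#'
#' Convenience companion to [roc_auc]; on every ranking the trapezoidal
#' area under the tie-aware curve equals the concordance AUC.
#'
#' @param curve data frame with `fpr`, `tpr` columns.
#' @return area in [0, 1].
#' @export
trapezoid_auc <- function(curve) {
  x <- curve$fpr
  y <- curve$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Enrichment report for a set of docking/scoring combinations
#'
#' Runs [rank_compounds], [enrichment_factor] and [roc_auc] for every
#' score column and assembles a table shaped like a published screen
#' validation summary: EF at the chosen fraction, maximum EF, AUC with
#' standard error and significance stars, and the quality band.
#'
#' @param table a [score_table].
#' @param fraction top fraction for the EF (default 0.10).
#' @param orientations named character vector of per-combination score
#'   orientations; default "higher" for all.
#' @return data frame, one row per combination.
#' @export
enrichment_report <- function(table, fraction = 0.10, orientations = NULL) {
  combos <- score_columns(table)
  rows <- lapply(combos, function(cn) {
    orient <- if (!is.null(orientations) && cn %in% names(orientations))
      orientations[[cn]] else "higher"
    rk <- rank_compounds(table, cn, orient)
    ef <- enrichment_factor(rk, fraction)
    roc <- roc_auc(rk)
    data.frame(combination = cn, orientation = orient,
               NC_tot = ef$NC_tot, Hits_tot = ef$Hits_tot,
               NC_sel = ef$NC_sel, Hits_sel = ef$Hits_sel,
               ef = ef$ef_reported,
               ef_max = round_half_up(ef$ef_max, 1),
               auc = roc$auc, auc_se = roc$se, stars = roc$stars,
               band = roc$band, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
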