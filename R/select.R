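#' Apply validation thresholds to one docking/scoring combination
#'
#' The default criterion is the most stringent ROC band: the combination
#' is valid when its AUC band is "excellent" (AUC >= 0.9; the lower bound
#' is closed). Optional criteria on redocking success rate and enrichment
#' factor can be added through `criteria`. Every criterion's outcome is
#' recorded so an invalid verdict always carries its reasons.
#'
#' @param combination combination name (must match the inputs).
#' @param roc a `roc_result` for the combination.
#' @param enr optional `enrichment_result`.
#' @param success_rate optional exact success-rate percent from redocking.
#' @param average_rmsd optional average RMSD (reported alongside, not
#'   thresholded by default).
#' @param criteria list of thresholds: `band` (required AUC band,
#'   default "excellent"), `min_success` (percent, optional), `min_ef`
#'   (optional).
#' @return A `combo_verdict`: list with `combination`, `valid`, `reasons`
#'   (data frame criterion/required/observed/pass) and the input metrics.
#' @export
validate_combo <- function(combination, roc, enr = NULL,
                           success_rate = NULL, average_rmsd = NULL,
                           criteria = list(band = "excellent")) {
  bands <- c(failure = 0, poor = 1, fair = 2, good = 3, excellent = 4)
  req_band <- if (is.null(criteria$band)) "excellent" else criteria$band
  stopifnot(req_band %in% names(bands))
  reasons <- data.frame(criterion = "auc_band", required = req_band,
                        observed = roc$band,
                        pass = bands[[roc$band]] >= bands[[req_band]],
                        stringsAsFactors = FALSE)
  if (!is.null(criteria$min_success)) {
    if (is.null(success_rate))
      stop("min_success criterion set but no success rate supplied")
    reasons <- rbind(reasons, data.frame(
      criterion = "success_rate",
      required = paste0(">=", criteria$min_success),
      observed = as.character(round_half_up(success_rate, 0)),
      pass = success_rate >= criteria$min_success))
  }
  if (!is.null(criteria$min_ef)) {
    if (is.null(enr))
      stop("min_ef criterion set but no enrichment result supplied")
    reasons <- rbind(reasons, data.frame(
      criterion = "enrichment_factor",
      required = paste0(">=", criteria$min_ef),
      observed = as.character(enr$ef_reported),
      pass = enr$ef >= criteria$min_ef))
  }
  structure(list(combination = combination, valid = all(reasons$pass),
                 reasons = reasons, auc = roc$auc, band = roc$band,
                 ef = if (is.null(enr)) NA_real_ else enr$ef,
                 success_rate = if (is.null(success_rate)) NA_real_
                 else success_rate,
                 average_rmsd = if (is.null(average_rmsd)) NA_real_
                 else average_rmsd),
            class = "combo_verdict")
}

#' Flag screening compounds called by one combination
#'
#' Two operational rules for "has affinity" are supported: membership in
#' the top fraction of the ranked screen (the same selection the
#' enrichment factor uses; default fraction 0.10), or score at least as
#' good as a reference value (e.g. the co-crystallised ligand's score
#' under the same combination).
#'
#' @param ranked a `ranked_list` over the screening library.
#' @param rule "top_fraction" or "score_threshold".
#' @param fraction selection fraction for the top-fraction rule.
#' @param threshold reference score for the threshold rule (orientation
#'   taken from the ranking: "at least as good" means >= for
#'   higher-is-better scores, <= for lower-is-better).
#' @return character vector of flagged compound ids.
#' @export
flag_hits <- function(ranked, rule = c("top_fraction", "score_threshold"),
                      fraction = 0.10, threshold = NULL) {
  rule <- match.arg(rule)
  sc <- ranked[ranked$scored, , drop = FALSE]
  if (rule == "top_fraction") {
    n_sel <- floor(fraction * nrow(sc))
    if (n_sel == 0L) stop("selection size is zero at fraction ", fraction)
    return(sc$compound_id[seq_len(n_sel)])
  }
  if (is.null(threshold)) stop("score_threshold rule needs 'threshold'")
  ok <- if (attr(ranked, "orientation") == "higher")
    sc$score >= threshold else sc$score <= threshold
  sc$compound_id[ok]
}

#' Call virtual-screening hits under the either-algorithm rule
#'
#' A compound is a hit when any *valid* docking/scoring combination flags
#' it — combinations from different docking algorithms count equally
#' ("either algorithm, any validated function"). Flags from invalid
#' combinations are discarded, and with no valid combination at all the
#' call fails closed rather than returning an empty list.
#'
#' @param calls named list: combination name -> character vector of
#'   flagged compound ids (e.g. from [flag_hits]).
#' @param verdicts list of `combo_verdict`s covering the combinations in
#'   `calls`.
#' @return A `hit_list`: data frame with `compound_id` and `provenance`
#'   (comma-separated valid combinations that flagged it).
#' @export
select_hits <- function(calls, verdicts) {
  names(verdicts) <- vapply(verdicts, `[[`, "", "combination")
  unknown <- setdiff(names(calls), names(verdicts))
  if (length(unknown))
    stop("no verdict for combination(s): ", paste(unknown, collapse = ", "))
  valid <- names(verdicts)[vapply(verdicts, `[[`, TRUE, "valid")]
  if (!length(valid))
    stop("no valid docking/scoring combination; refusing to call hits")
  calls <- calls[intersect(names(calls), valid)]
  ids <- sort(unique(unlist(calls)))
  prov <- vapply(ids, function(id)
    paste(names(calls)[vapply(calls, function(v) id %in% v, TRUE)],
          collapse = ","), "")
  out <- data.frame(compound_id = ids, provenance = unname(prov),
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_list", "data.frame")
  out
}
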