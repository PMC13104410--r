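#' Construct a Franz diffusion cell experiment
#'
#' Holds the sampling schedule, the measured acceptor-chamber
#' concentrations per replicate, and the cell geometry. The default
#' protocol mirrors a standard nasal-epithelium setup: 1 mL donor, 2 mL
#' acceptor, six replicate cells, samples at 20..120 min with the full
#' acceptor volume withdrawn and replaced at every time point.
#'
#' @param times sampling times in minutes, strictly increasing, > 0.
#' @param conc numeric matrix of acceptor concentrations (ug/mL), one row
#'   per time point, one column per replicate cell.
#' @param C0_donor donor concentration in ug/mL.
#' @param area diffusion area in cm^2. Not a property of the tissue but of
#'   the cell; it must be supplied, and every permeability value is only
#'   interpretable together with it.
#' @param V_acceptor,V_donor chamber volumes in mL.
#' @param withdrawal "full" (entire acceptor volume replaced each sample)
#'   or "partial".
#' @param V_withdraw withdrawn volume in mL, required for partial
#'   withdrawal.
#' @return A `franz_experiment` object.
#' @export
franz_experiment <- function(times, conc, C0_donor, area,
                             V_acceptor = 2, V_donor = 1,
                             withdrawal = c("full", "partial"),
                             V_withdraw = NULL) {
  withdrawal <- match.arg(withdrawal)
  conc <- as.matrix(conc)
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("sampling times must be positive and strictly increasing")
  if (nrow(conc) != length(times))
    stop("conc must have one row per sampling time")
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  stopifnot(V_acceptor > 0, V_donor > 0, C0_donor > 0, area > 0)
  if (withdrawal == "partial") {
    if (is.null(V_withdraw)) stop("partial withdrawal needs 'V_withdraw'")
    stopifnot(V_withdraw > 0, V_withdraw <= V_acceptor)
  }
  structure(list(times = times, conc = conc, C0_donor = C0_donor,
                 area = area, V_acceptor = V_acceptor, V_donor = V_donor,
                 withdrawal = withdrawal, V_withdraw = V_withdraw,
                 n_replicates = ncol(conc)),
            class = "franz_experiment")
}

#' Read a Franz time series from long-format delimited text
#'
#' Expects a header with columns `replicate`, `time_min`,
#' `conc_ug_per_ml` (comma- or tab-separated); remaining experiment
#' parameters are passed through to [franz_experiment].
#'
#' @param path delimited text file.
#' @param ... parameters forwarded to [franz_experiment] (`C0_donor`,
#'   `area`, volumes, ...).
#' @param sep separator; inferred from the extension by default.
#' @return A `franz_experiment`.
#' @export
read_franz_series <- function(path, ..., sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("replicate", "time_min", "conc_ug_per_ml") %in% names(df)))
  times <- sort(unique(df$time_min))
  reps <- sort(unique(df$replicate))
  conc <- matrix(NA_real_, length(times), length(reps),
                 dimnames = list(NULL, paste0("rep", reps)))
  conc[cbind(match(df$time_min, times), match(df$replicate, reps))] <-
    df$conc_ug_per_ml
  if (anyNA(conc)) stop("incomplete time series: missing (replicate, time) cells")
  franz_experiment(times = times, conc = conc, ...)
}

#' Cumulative amount permeated per replicate
#'
#' With full-volume withdrawal every sample removes the entire acceptor
#' content, so the cumulative amount at time t_n is the running sum of
#' sampled amounts: Q(t_n) = V_acceptor x sum(C_1..C_n). With partial
#' withdrawal the standard back-correction applies:
#' Q(t_n) = V_acceptor x C_n + V_withdraw x sum(C_1..C_{n-1}).
#'
#' @param exp a [franz_experiment].
#' @return numeric matrix of cumulative amounts (ug), same shape as
#'   `exp$conc`.
#' @export
cumulative_amount <- function(exp) {
  stopifnot(inherits(exp, "franz_experiment"))
  if (exp$withdrawal == "full") {
    apply(exp$conc, 2, cumsum) * exp$V_acceptor
  } else {
    removed <- apply(exp$conc, 2, function(cc)
      c(0, cumsum(cc)[-length(cc)]))
    exp$V_acceptor * exp$conc + exp$V_withdraw * removed
  }
}

#' Steady-state flux from a cumulative permeation series
#'
#' Least-squares slope of Q versus time, converted to ug/s. The default
#' window uses all points; `window = "post-lag"` drops leading points one
#' at a time until the fit reaches the configured linearity (R^2) or only
#' `min_points` remain, which absorbs a lag phase before steady state.
#'
#' @param Q numeric vector of cumulative amounts (ug) at `times`.
#' @param times sampling times in minutes.
#' @param window "all" or "post-lag".
#' @param r2_min linearity target for the post-lag window.
#' @param min_points smallest window allowed (>= 3).
#' @return list with `flux_ug_s`, `slope_ug_min`, `intercept`, `r2`,
#'   `n_used`, `t_start`.
#' @export
steady_state_flux <- function(Q, times, window = c("all", "post-lag"),
                              r2_min = 0.95, min_points = 3) {
  window <- match.arg(window)
  stopifnot(length(Q) == length(times), min_points >= 3)
  if (length(Q) < 3) stop("need at least 3 points for a flux fit")
  if (diff(range(times)) <= 0) stop("zero time span")
  fit_from <- function(i) {
    tt <- times[i:length(times)]
    qq <- Q[i:length(Q)]
    fit <- stats::lm(qq ~ tt)
    ss_tot <- sum((qq - mean(qq))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), r2 = r2,
         n_used = length(qq), t_start = tt[1])
  }
  start <- 1L
  f <- fit_from(start)
  if (window == "post-lag") {
    while (f$r2 < r2_min && (length(Q) - start) >= min_points) {
      start <- start + 1L
      f <- fit_from(start)
    }
  }
  list(flux_ug_s = f$slope / 60, slope_ug_min = f$slope,
       intercept = f$intercept, r2 = f$r2, n_used = f$n_used,
       t_start = f$t_start)
}

#' Apparent permeability coefficient
#'
#' Papp = (dQ/dt) / (A x C0): steady-state flux normalised by the
#' diffusion area and the donor concentration. With flux in ug/s, area in
#' cm^2 and C0 in ug/mL (= ug/cm^3), the result is in cm/s.
#'
#' @param flux_ug_s steady-state flux in ug/s.
#' @param area diffusion area in cm^2.
#' @param C0 donor concentration in ug/mL.
#' @return Papp in cm/s.
#' @export
apparent_permeability <- function(flux_ug_s, area, C0) {
  if (area <= 0) stop("area must be positive")
  if (C0 <= 0) stop("donor concentration must be positive")
  flux_ug_s / (area * C0)
}

#' Percentage of the applied dose transported
#'
#' 100 x Q(final) / dose, with dose = C0_donor x V_donor unless given
#' explicitly.
#'
#' @param Q_final final cumulative amount (ug), scalar or per-replicate
#'   vector.
#' @param dose applied dose in ug.
#' @return percent transported, same shape as `Q_final`.
#' @export
percent_transport <- function(Q_final, dose) {
  if (dose <= 0) stop("dose must be positive")
  100 * Q_final / dose
}

#' Donor concentration of one component of an extract
#'
#' A working solution prepared at `extract_mg_ml` of whole extract
#' carries each component at its assayed content percentage:
#' C0 = extract_mg_ml x content/100, converted to ug/mL. 20 mg/mL of an
#' extract assayed at 3.465% gives 693 ug/mL of that component.
#'
#' @param extract_mg_ml working-solution concentration of the extract,
#'   mg/mL.
#' @param content_percent component content of the extract, percent.
#' @return component donor concentration in ug/mL.
#' @export
donor_concentration_from_extract <- function(extract_mg_ml, content_percent) {
  stopifnot(extract_mg_ml > 0, content_percent > 0)
  if (content_percent > 100) stop("content percentage cannot exceed 100")
  extract_mg_ml * (content_percent / 100) * 1000
}

#' Percentage of the dose retained in the tissue
#'
#' 100 x amount / dose. The amount recovered from a lysed tissue sample
#' is lysate concentration x lysate volume (default 5 mL of methanol).
#'
#' @param amount_ug amount recovered from the tissue, ug; alternatively
#'   supply `lysate_conc` (ug/mL) and `lysate_volume` (mL).
#' @param dose applied dose in ug.
#' @param lysate_conc,lysate_volume used when `amount_ug` is missing.
#' @return percent of dose in the tissue.
#' @export
tissue_content_percent <- function(amount_ug = NULL, dose,
                                   lysate_conc = NULL, lysate_volume = 5) {
  if (dose <= 0) stop("dose must be positive")
  if (is.null(amount_ug)) {
    if (is.null(lysate_conc)) stop("supply amount_ug or lysate_conc")
    amount_ug <- lysate_conc * lysate_volume
  }
  100 * amount_ug / dose
}

#' Membrane integrity verdict from a marker permeability
#'
#' An exclusion marker (e.g. Lucifer Yellow) should barely cross an
#' intact membrane; the mounted tissue passes when the marker Papp does
#' not exceed the threshold (closed bound: equality passes). The default
#' threshold, 5e-6 cm/s, sits at the order of magnitude expected for the
#' marker across intact epithelium.
#'
#' @param papp_marker marker Papp in cm/s.
#' @param threshold pass threshold in cm/s.
#' @return "pass" or "fail".
#' @export
integrity_check <- function(papp_marker, threshold = 5e-6) {
  stopifnot(threshold > 0)
  if (papp_marker <= threshold) "pass" else "fail"
}

#' Classify a permeability against reference benchmarks
#'
#' Nearest-benchmark classification on log10 scale against three ordered
#' reference Papp values: an exclusion marker ("low"), a low-to-moderate
#' reference ("low-moderate") and a moderate-to-high reference
#' ("moderate-high"). Values below the marker classify low; above the
#' highest, moderate-high. The class interval bounds (geometric midpoints
#' between benchmarks) are reported alongside the verdict.
#'
#' @param papp Papp to classify, cm/s.
#' @param benchmarks ascending numeric vector of three benchmark Papp
#'   values, names optional.
#' @return list with `class`, `nearest` (benchmark value), `bounds`
#'   (interval edges in cm/s).
#' @export
classify_permeability <- function(papp,
                                  benchmarks = c(marker = 2.92e-6,
                                                 low_moderate = 1.24e-5,
                                                 moderate_high = 4.73e-5)) {
  stopifnot(length(benchmarks) == 3, papp >= 0)
  if (is.unsorted(benchmarks, strictly = TRUE))
    stop("benchmarks must be strictly increasing")
  classes <- c("low", "low-moderate", "moderate-high")
  bounds <- sqrt(benchmarks[-3] * benchmarks[-1])  # geometric midpoints
  i <- findInterval(papp, bounds) + 1L
  list(class = classes[i], nearest = unname(benchmarks[i]),
       bounds = unname(bounds))
}

#' Full permeation analysis of a Franz experiment
#'
#' Per replicate: cumulative amounts, steady-state flux, Papp and percent
#' transport; summarised as mean +/- sd across the replicate cells (the
#' reporting convention for n diffusion cells).
#'
#' @param exp a [franz_experiment].
#' @param window,r2_min forwarded to [steady_state_flux].
#' @param dose applied dose in ug; default C0_donor x V_donor.
#' @return A `permeation_result`: list with `per_replicate` (data frame),
#'   `papp_mean`, `papp_sd`, `percent_mean`, `percent_sd`, `dose`,
#'   `area`, `Q` (cumulative matrix).
#' @export
analyze_franz <- function(exp, window = "all", r2_min = 0.95, dose = NULL) {
  Q <- cumulative_amount(exp)
  if (is.null(dose)) dose <- exp$C0_donor * exp$V_donor
  per <- lapply(seq_len(ncol(Q)), function(j) {
    f <- steady_state_flux(Q[, j], exp$times, window = window,
                           r2_min = r2_min)
    papp <- apparent_permeability(f$flux_ug_s, exp$area, exp$C0_donor)
    data.frame(replicate = j, flux_ug_s = f$flux_ug_s, r2 = f$r2,
               papp_cm_s = papp,
               percent = percent_transport(Q[nrow(Q), j], dose))
  })
  per <- do.call(rbind, per)
  structure(list(per_replicate = per,
                 papp_mean = mean(per$papp_cm_s),
                 papp_sd = stats::sd(per$papp_cm_s),
                 percent_mean = mean(per$percent),
                 percent_sd = stats::sd(per$percent),
                 dose = dose, area = exp$area, Q = Q),
            class = "permeation_result")
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf("<permeation_result> n = %d cells, area %.3g cm^2\n",
              nrow(x$per_replicate), x$area))
  cat(sprintf("  Papp: %.3g +/- %.2g cm/s\n", x$papp_mean, x$papp_sd))
  cat(sprintf("  transport: %.3f +/- %.3f %% of %.3g ug dose\n",
              x$percent_mean, x$percent_sd, x$dose))
  invisible(x)
}
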