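#' Nicotine metabolite ratio at fixed nominal times
#'
#' The CYP2A6 phenotyping index: concentration of 3-hydroxycotinine
#' divided by that of cotinine, at the requested nominal sampling times.
#' A ratio is defined only where both metabolites are quantifiable at
#' the same nominal time and cotinine is positive.
#'
#' @param cot_profile,ohc_profile [conc_profile()]s of cotinine and
#'   3-hydroxycotinine sharing the nominal sampling grid.
#' @param times Nominal times (h) at which to report the ratio; the
#'   default 4, 6 and 8 h.
#' @return Data frame `time_h`, `nmr` (NA where undefined).
#' @export
nmr_at_times <- function(cot_profile, ohc_profile, times = c(4, 6, 8)) {
  s <- .nmr_series(cot_profile, ohc_profile)
  data.frame(time_h = times, nmr = s$nmr[match(times, s$time_h)])
}

# full NMR series over the shared grid; only points where both analytes
# are quantifiable and cotinine > 0
.nmr_series <- function(cot_profile, ohc_profile) {
  stopifnot(inherits(cot_profile, "conc_profile"),
            inherits(ohc_profile, "conc_profile"))
  shared <- intersect(cot_profile$times_h, ohc_profile$times_h)
  ic <- match(shared, cot_profile$times_h)
  io <- match(shared, ohc_profile$times_h)
  cot <- cot_profile$conc_nM[ic]
  ohc <- ohc_profile$conc_nM[io]
  ok <- !cot_profile$censored[ic] & !ohc_profile$censored[io] &
    !is.na(cot) & !is.na(ohc) & cot > 0
  data.frame(time_h = shared[ok], nmr = ohc[ok] / cot[ok])
}

#' Partial-AUC ratio of the two nicotine metabolites
#'
#' Ratio of the 3-to-8-hour partial AUC of 3-hydroxycotinine to that of
#' cotinine, the window capturing cotinine's elimination phase and
#' 3-hydroxycotinine's formation phase. Set `convention =
#' "auc_of_ratio"` for the alternative reading — the trapezoidal AUC of
#' the NMR-vs-time series divided by the window width.
#'
#' @param cot_profile,ohc_profile [conc_profile()]s of the metabolites.
#' @param t_start,t_end Window (h), default 3 to 8.
#' @param convention `"ratio_of_aucs"` (default) or `"auc_of_ratio"`.
#' @return Dimensionless ratio, NA when either partial AUC is missing.
#' @export
partial_auc_ratio <- function(cot_profile, ohc_profile,
                              t_start = 3, t_end = 8,
                              convention = c("ratio_of_aucs",
                                             "auc_of_ratio")) {
  convention <- match.arg(convention)
  if (convention == "ratio_of_aucs") {
    num <- auc_interval(ohc_profile, t_start, t_end)
    den <- auc_interval(cot_profile, t_start, t_end)
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    return(num / den)
  }
  s <- .nmr_series(cot_profile, ohc_profile)
  s <- s[s$time_h >= t_start & s$time_h <= t_end, ]
  if (nrow(s) < 2L) return(NA_real_)
  prof <- conc_profile(s$time_h, s$nmr, analyte = "nmr")
  auc_interval(prof, min(s$time_h), max(s$time_h), method = "linear") /
    (max(s$time_h) - min(s$time_h))
}

#' Fit the slope of the nicotine metabolite ratio against time
#'
#' The "slope approach": ordinary least-squares slope of NMR vs. time,
#' (1) over all quantifiable points and (2) over the most linear window,
#' which runs from the observed tmax of cotinine to the observed tmax of
#' 3-hydroxycotinine (where cotinine decline and 3-hydroxycotinine
#' formation overlap and the ratio lacks curvature). Either slope is
#' reported only when its point set has at least 3 points.
#'
#' @param cot_profile,ohc_profile [conc_profile()]s of the metabolites.
#' @return Object of class `nmr_slope_fit` with elements `series` (the
#'   usable NMR points), `slope_all`, `slope_linear` (1/h), `window`
#'   (h), `n_points_all`, `n_points_linear`, and `pauc_ratio_3_8`.
#' @export
fit_nmr_slope <- function(cot_profile, ohc_profile) {
  s <- .nmr_series(cot_profile, ohc_profile)
  ols <- function(t, y) {
    if (length(t) < 3L) return(c(NA_real_, NA_real_))
    fit <- stats::lm.fit(cbind(1, t), y)
    fit$coefficients[2:1]
  }
  all_fit <- ols(s$time_h, s$nmr)

  tmax_cot <- unname(cmax_tmax(cot_profile)["tmax_h"])
  tmax_ohc <- unname(cmax_tmax(ohc_profile)["tmax_h"])
  window <- c(t_start = tmax_cot, t_end = tmax_ohc)
  lin <- if (!is.na(tmax_cot) && !is.na(tmax_ohc) && tmax_cot < tmax_ohc)
    s[s$time_h >= tmax_cot & s$time_h <= tmax_ohc, ]
  else s[0, ]
  lin_fit <- ols(lin$time_h, lin$nmr)

  structure(list(series = s,
                 slope_all = unname(all_fit[1L]),
                 intercept_all = unname(all_fit[2L]),
                 slope_linear = unname(lin_fit[1L]),
                 intercept_linear = unname(lin_fit[2L]),
                 window = window,
                 n_points_all = nrow(s),
                 n_points_linear = nrow(lin),
                 pauc_ratio_3_8 = partial_auc_ratio(cot_profile,
                                                    ohc_profile)),
            class = "nmr_slope_fit")
}

#' @export
print.nmr_slope_fit <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(signif(v, digits))
  cat("NMR slope fit\n")
  cat("  slope (all ", x$n_points_all, " points): ", fmt(x$slope_all),
      " /h\n", sep = "")
  cat("  slope (linear window ", fmt(x$window[1L]), "-",
      fmt(x$window[2L]), " h, ", x$n_points_linear, " points): ",
      fmt(x$slope_linear), " /h\n", sep = "")
  cat("  partial-AUC ratio 3-8 h: ", fmt(x$pauc_ratio_3_8), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.nmr_slope_fit <- function(object, ...) {
  c(slope_all = object$slope_all, slope_linear = object$slope_linear)
}

#' @export
plot.nmr_slope_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$time_h, s$nmr, pch = 16, xlab = "Time (h)",
                 ylab = "3-hydroxycotinine / cotinine", ...)
  if (!is.na(x$slope_all))
    graphics::abline(x$intercept_all, x$slope_all, lty = 2)
  if (!is.na(x$slope_linear)) {
    w <- x$window
    graphics::segments(w[1L], x$intercept_linear + x$slope_linear * w[1L],
                       w[2L], x$intercept_linear + x$slope_linear * w[2L],
                       lwd = 2)
  }
  invisible(x)
}

#' Classify the between-period pattern of the NMR slope
#'
#' Compares the linear-window slope under precipitant exposure with the
#' baseline slope. Parallel slopes suggest no inhibition over the
#' sampling day (or an inhibitor that was itself cleared); a reduced
#' exposure slope suggests inhibition accrued with time.
#'
#' @param baseline,exposure `nmr_slope_fit` objects (or bare numeric
#'   slopes).
#' @param rel_tol Relative tolerance on the slope ratio within which the
#'   two are called parallel (default 0.10).
#' @return One of `"parallel"`, `"reduced_slope"`, `"increased_slope"`;
#'   NA when either slope is missing.
#' @export
classify_pattern <- function(baseline, exposure, rel_tol = 0.10) {
  s_b <- if (inherits(baseline, "nmr_slope_fit"))
    baseline$slope_linear else baseline
  s_e <- if (inherits(exposure, "nmr_slope_fit"))
    exposure$slope_linear else exposure
  if (is.na(s_b) || is.na(s_e) || s_b == 0) return(NA_character_)
  ratio <- s_e / s_b
  if (abs(ratio - 1) <= rel_tol) "parallel"
  else if (ratio < 1 - rel_tol) "reduced_slope"
  else "increased_slope"
}

#' Per-subject NMR endpoints over a whole study dataset
#'
#' Computes the fixed-time ratios, the 3-8 h partial-AUC ratio and both
#' slopes for every subject x period, and the between-period pattern per
#' subject.
#'
#' @param data A `study_dataset`, `study_records`, or records data
#'   frame.
#' @param cot_analyte,ohc_analyte Analyte names of cotinine and
#'   3-hydroxycotinine in the dataset.
#' @param times Nominal ratio times (h).
#' @param rel_tol Parallelism tolerance for [classify_pattern()].
#' @return Data frame: subject_id, period, `nmr_<t>h` columns,
#'   pauc_ratio_3_8, slope_all, slope_linear, window_start, window_end,
#'   pattern (reported on exposure rows).
#' @export
nmr_table <- function(data, cot_analyte = "cotinine",
                      ohc_analyte = "3-hydroxycotinine",
                      times = c(4, 6, 8), rel_tol = 0.10) {
  records <- if (inherits(data, "study_dataset")) data$records else data
  subjects <- unique(records$subject_id)
  rows <- list()
  for (subject in subjects) {
    fits <- list()
    for (period in c("baseline", "exposure")) {
      cot <- .profile_from_records(records, subject, period, cot_analyte)
      ohc <- .profile_from_records(records, subject, period, ohc_analyte)
      if (is.null(cot) || is.null(ohc)) next
      fit <- fit_nmr_slope(cot, ohc)
      fits[[period]] <- fit
      at <- nmr_at_times(cot, ohc, times)
      row <- data.frame(subject_id = subject, period = period)
      for (k in seq_along(times))
        row[[sprintf("nmr_%gh", times[k])]] <- at$nmr[k]
      row$pauc_ratio_3_8 <- fit$pauc_ratio_3_8
      row$slope_all <- fit$slope_all
      row$slope_linear <- fit$slope_linear
      row$window_start <- unname(fit$window[1L])
      row$window_end <- unname(fit$window[2L])
      row$pattern <- NA_character_
      rows[[length(rows) + 1L]] <- row
    }
    if (!is.null(fits$baseline) && !is.null(fits$exposure)) {
      pat <- classify_pattern(fits$baseline, fits$exposure, rel_tol)
      rows[[length(rows)]]$pattern <- pat
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
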