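#' A single concentration-time profile
#'
#' One subject x period x analyte series. Censored (below-LOQ) points
#' carry no numeric value and are skipped by every estimator. A predose
#' draw (time <= 0) is treated as the t = 0 baseline: kept (at t = 0)
#' when it is positive and quantifiable, excluded when zero or censored;
#' when several predose samples exist the latest is used.
#'
#' @param times_h Strictly increasing sampling times (h).
#' @param conc_nM Concentrations (nM); NA where censored.
#' @param censored Logical censoring flags (default: `is.na(conc_nM)`).
#' @param analyte Analyte name.
#' @param dose_nmol Molar dose (nmol); supply for dosed parent analytes
#'   so that CL/F can be computed, NA for metabolites.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(times_h, conc_nM, censored = is.na(conc_nM),
                         analyte = "analyte", dose_nmol = NA_real_) {
  if (is.unsorted(times_h, strictly = TRUE))
    stop("'times_h' must be strictly increasing", call. = FALSE)
  if (length(conc_nM) != length(times_h) ||
      length(censored) != length(times_h))
    stop("lengths of times, concentrations and flags must match",
         call. = FALSE)
  if (any(!censored & !is.na(conc_nM) & conc_nM < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  conc_nM[censored] <- NA_real_
  keep <- times_h > 0
  pre <- which(times_h <= 0)
  if (length(pre)) {
    # latest predose sample acts as the t = 0 baseline if quantifiable
    i0 <- pre[length(pre)]
    if (!censored[i0] && !is.na(conc_nM[i0]) && conc_nM[i0] > 0) {
      keep[i0] <- TRUE
      times_h[i0] <- 0
    }
  }
  structure(list(times_h = times_h[keep], conc_nM = conc_nM[keep],
                 censored = censored[keep], analyte = analyte,
                 dose_nmol = dose_nmol),
            class = "conc_profile")
}

# usable (time, conc) pairs of a profile
.usable <- function(profile) {
  ok <- !profile$censored & !is.na(profile$conc_nM)
  list(t = profile$times_h[ok], c = profile$conc_nM[ok])
}

#' Maximum concentration and its time
#'
#' The maximum observed uncensored concentration; ties go to the
#' earliest time.
#'
#' @param profile A [conc_profile()].
#' @return Named vector `c(cmax_nM, tmax_h)`; both NA when no point is
#'   quantifiable.
#' @export
cmax_tmax <- function(profile) {
  u <- .usable(profile)
  if (!length(u$t)) return(c(cmax_nM = NA_real_, tmax_h = NA_real_))
  i <- which.max(u$c)  # which.max takes the first maximum: earliest time
  c(cmax_nM = u$c[i], tmax_h = u$t[i])
}

# concentration interpolated at time tt between bracketing usable points,
# by the same rule as the trapezoid: linear going up (or touching zero),
# log-linear going down
.interp_conc <- function(t1, c1, t2, c2, tt) {
  w <- (tt - t1) / (t2 - t1)
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
    c1 + w * (c2 - c1)
  } else {
    c1 * (c2 / c1)^w
  }
}

# area of one segment
.segment_auc <- function(t1, c1, t2, c2) {
  dt <- t2 - t1
  if (c2 >= c1 || c1 <= 0 || c2 <= 0) {
    (c1 + c2) / 2 * dt
  } else {
    (c1 - c2) / log(c1 / c2) * dt
  }
}

#' Windowed area under the concentration-time curve
#'
#' Trapezoidal AUC over `[t_start, t_end]`. The default
#' `linear_up_log_down` rule uses the linear trapezoid where
#' concentration is non-decreasing across a segment or touches zero, and
#' the logarithmic trapezoid `(C1 - C2) / ln(C1 / C2) * dt` where it is
#' strictly decreasing with both ends positive; `linear` uses the linear
#' trapezoid throughout. Window endpoints falling between sampling times
#' are filled by interpolation under the same rule; internal censored
#' points are skipped, bridging the segment between the neighbouring
#' quantifiable points. A window starting at 0 before the first sample
#' is anchored at C(0) = 0 (single extravascular dose). No extrapolation
#' beyond the last quantifiable point: a window reaching past it returns
#' NA.
#'
#' @param profile A [conc_profile()].
#' @param t_start,t_end Window bounds (h), `t_start < t_end`.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @return AUC in nM*h, or NA when fewer than 2 usable points cover the
#'   window.
#' @export
auc_interval <- function(profile, t_start, t_end,
                         method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  if (t_start >= t_end) stop("'t_start' must be < 't_end'", call. = FALSE)
  u <- .usable(profile)
  if (t_start <= 0 && (!length(u$t) || u$t[1L] > 0)) {
    # zero anchor at dose time (single extravascular dose)
    u$t <- c(0, u$t)
    u$c <- c(0, u$c)
  }
  t_start <- max(t_start, 0)
  if (length(u$t) < 2L) return(NA_real_)
  if (t_start < u$t[1L] || t_end > u$t[length(u$t)]) return(NA_real_)

  seg <- if (method == "linear")
    function(t1, c1, t2, c2) (c1 + c2) / 2 * (t2 - t1)
  else .segment_auc
  itp <- if (method == "linear")
    function(t1, c1, t2, c2, tt) c1 + (tt - t1) / (t2 - t1) * (c2 - c1)
  else .interp_conc

  # knots: window bounds plus interior sampling times
  inner <- u$t[u$t > t_start & u$t < t_end]
  knots <- c(t_start, inner, t_end)
  conc_at <- function(tt) {
    i <- findInterval(tt, u$t)
    if (u$t[i] == tt) return(u$c[i])
    itp(u$t[i], u$c[i], u$t[i + 1L], u$c[i + 1L], tt)
  }
  cs <- vapply(knots, conc_at, numeric(1))
  total <- 0
  for (s in seq_len(length(knots) - 1L)) {
    total <- total + seg(knots[s], cs[s], knots[s + 1L], cs[s + 1L])
  }
  total
}

#' Terminal elimination rate constant by best-fit log-linear regression
#'
#' Ordinary least squares of ln C on t over candidate terminal point
#' sets: the last 3, 4, ... quantifiable points strictly after tmax.
#' Among candidates with a positive elimination rate the set maximising
#' adjusted R-squared wins (the usual "best fit" rule of NCA software).
#'
#' @param profile A [conc_profile()].
#' @return Named vector `c(lambda_z, t_half_h, lz_n_points, lz_r2_adj)`;
#'   all NA when no candidate set of >= 3 declining points exists.
#' @export
terminal_slope <- function(profile) {
  miss <- c(lambda_z = NA_real_, t_half_h = NA_real_,
            lz_n_points = NA_real_, lz_r2_adj = NA_real_)
  u <- .usable(profile)
  pos <- u$c > 0
  u$t <- u$t[pos]; u$c <- u$c[pos]
  if (length(u$t) < 3L) return(miss)
  tmax <- u$t[which.max(u$c)]
  after <- u$t > tmax
  tt <- u$t[after]; cc <- u$c[after]
  n_av <- length(tt)
  if (n_av < 3L) return(miss)

  best <- NULL
  for (m in 3:n_av) {
    idx <- seq.int(n_av - m + 1L, n_av)
    x <- tt[idx]; y <- log(cc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2L]
    if (!is.finite(slope) || slope >= 0) next
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    r2_adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || r2_adj > best$r2_adj)
      best <- list(lambda = -slope, n = m, r2_adj = r2_adj)
  }
  if (is.null(best)) return(miss)
  c(lambda_z = unname(best$lambda),
    t_half_h = log(2) / unname(best$lambda),
    lz_n_points = best$n, lz_r2_adj = unname(best$r2_adj))
}

#' Non-compartmental endpoint bundle for one profile
#'
#' Assembles Cmax/tmax, the requested windowed AUCs, AUC to the last
#' quantifiable point, the terminal slope, extrapolated AUC to infinity
#' (`AUC0-tlast + Clast / lambda_z`), apparent clearance `CL/F =
#' dose / AUC0-inf` (dosed parent analytes only), and diagnostics. An
#' extrapolated fraction above 0.2 sets the `extrapolation_flag`
#' reliability warning.
#'
#' @param profile A [conc_profile()].
#' @param auc_windows List of 2-vectors `c(t_start, t_end)`; each adds a
#'   windowed AUC endpoint.
#' @param extrapolate Compute AUC0-inf and CL/F (default TRUE).
#' @param method AUC trapezoid rule, see [auc_interval()].
#' @return Object of class `nca_result`: a list of endpoints with NA for
#'   anything not estimable.
#' @export
nca <- function(profile, auc_windows = list(),
                extrapolate = TRUE,
                method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_profile"))
  ct <- cmax_tmax(profile)
  u <- .usable(profile)
  res <- list(analyte = profile$analyte, dose_nmol = profile$dose_nmol,
              cmax_nM = unname(ct["cmax_nM"]),
              tmax_h = unname(ct["tmax_h"]))

  wins <- list()
  for (w in auc_windows) {
    wins[[sprintf("auc_%g_%g", w[1L], w[2L])]] <-
      auc_interval(profile, w[1L], w[2L], method = method)
  }
  res$auc_windows <- wins

  t_last <- if (length(u$t)) max(u$t) else NA_real_
  res$t_last_h <- t_last
  res$auc_0_tlast <- if (length(u$t) >= 2L)
    auc_interval(profile, 0, t_last, method = method) else NA_real_

  ts <- terminal_slope(profile)
  res$lambda_z <- unname(ts["lambda_z"])
  res$t_half_h <- unname(ts["t_half_h"])
  res$lz_n_points <- unname(ts["lz_n_points"])
  res$lz_r2_adj <- unname(ts["lz_r2_adj"])

  res$auc_inf <- NA_real_
  res$extrapolated_fraction <- NA_real_
  res$cl_f_Lh <- NA_real_
  res$extrapolation_flag <- FALSE
  res$invalid_dose <- FALSE
  if (extrapolate && is.finite(res$lambda_z) &&
      is.finite(res$auc_0_tlast)) {
    c_last <- u$c[length(u$c)]
    res$auc_inf <- res$auc_0_tlast + c_last / res$lambda_z
    res$extrapolated_fraction <- 1 - res$auc_0_tlast / res$auc_inf
    res$extrapolation_flag <- res$extrapolated_fraction > 0.2
    if (!is.na(profile$dose_nmol)) {
      if (profile$dose_nmol == 0) {
        res$cl_f_Lh <- 0
        res$invalid_dose <- TRUE
      } else {
        res$cl_f_Lh <- profile$dose_nmol / res$auc_inf
      }
    }
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, digits = 4, ...) {
  cat("Non-compartmental analysis:", x$analyte, "\n")
  fmt <- function(v) if (is.na(v)) "-" else format(signif(v, digits))
  cat("  Cmax ", fmt(x$cmax_nM), " nM at tmax ", fmt(x$tmax_h), " h\n",
      sep = "")
  for (nm in names(x$auc_windows))
    cat("  ", nm, " = ", fmt(x$auc_windows[[nm]]), " nM*h\n", sep = "")
  cat("  AUC0-tlast ", fmt(x$auc_0_tlast), " nM*h (tlast ",
      fmt(x$t_last_h), " h)\n", sep = "")
  cat("  lambda_z ", fmt(x$lambda_z), " /h (t1/2 ", fmt(x$t_half_h),
      " h, n = ", fmt(x$lz_n_points), ", adj R2 ", fmt(x$lz_r2_adj),
      ")\n", sep = "")
  cat("  AUC0-inf ", fmt(x$auc_inf), " nM*h (extrapolated ",
      fmt(100 * x$extrapolated_fraction), "%",
      if (isTRUE(x$extrapolation_flag)) ", > 20% flag" else "", ")\n",
      sep = "")
  cat("  CL/F ", fmt(x$cl_f_Lh), " L/h",
      if (isTRUE(x$invalid_dose)) " [invalid dose]" else "", "\n",
      sep = "")
  invisible(x)
}

# extract one subject x period x analyte profile from long records
.profile_from_records <- function(records, subject, period, analyte,
                                  dose_nmol = NA_real_) {
  d <- records[records$subject_id == subject & records$period == period &
                 records$analyte == analyte, ]
  d <- d[order(d$time_h), ]
  if (!nrow(d)) return(NULL)
  conc_profile(d$time_h, d$conc_nM, d$censored, analyte = analyte,
               dose_nmol = dose_nmol)
}

#' Per-profile NCA over a whole study dataset
#'
#' Runs [nca()] on every subject x period x analyte series of a long
#' dataset and returns one row per profile.
#'
#' @param data A `study_dataset`, `study_records`, or records data
#'   frame.
#' @param dose_nmol Named vector of molar doses per dosed (parent)
#'   analyte; analytes absent from it get no CL/F.
#' @param auc_windows Named list mapping analyte to a list of AUC
#'   windows, e.g. `list(nicotine = list(c(0, 4)))`.
#' @param extrapolate Character vector of analytes for which AUC0-inf /
#'   CL/F are computed (default: the dosed analytes).
#' @param method AUC trapezoid rule.
#' @return Data frame, one row per profile, with the NCA endpoints as
#'   columns.
#' @export
nca_table <- function(data, dose_nmol = numeric(),
                      auc_windows = list(),
                      extrapolate = names(dose_nmol),
                      method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  records <- if (inherits(data, "study_dataset")) data$records else data
  combos <- unique(records[c("subject_id", "period", "analyte")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    subject <- combos$subject_id[i]
    period <- combos$period[i]
    analyte <- combos$analyte[i]
    dose <- if (analyte %in% names(dose_nmol))
      dose_nmol[[analyte]] else NA_real_
    prof <- .profile_from_records(records, subject, period, analyte,
                                  dose)
    wins <- if (analyte %in% names(auc_windows))
      auc_windows[[analyte]] else list()
    r <- nca(prof, auc_windows = wins,
             extrapolate = analyte %in% extrapolate, method = method)
    base <- data.frame(subject_id = subject, period = period,
                       analyte = analyte, cmax_nM = r$cmax_nM,
                       tmax_h = r$tmax_h, auc_0_tlast = r$auc_0_tlast,
                       lambda_z = r$lambda_z, t_half_h = r$t_half_h,
                       lz_n_points = r$lz_n_points,
                       lz_r2_adj = r$lz_r2_adj, auc_inf = r$auc_inf,
                       extrapolated_fraction = r$extrapolated_fraction,
                       cl_f_Lh = r$cl_f_Lh)
    for (nm in names(r$auc_windows)) base[[nm]] <- r$auc_windows[[nm]]
    base
  })
  # windowed-AUC columns differ per analyte; union the columns
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
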