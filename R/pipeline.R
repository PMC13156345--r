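#' End-to-end crossover drug-interaction analysis
#'
#' The package's top-level fit: runs per-profile non-compartmental
#' analysis, per-subject nicotine-metabolite-ratio endpoints (when the
#' metabolite analytes are present), and the paired geometric-mean-ratio
#' statistics for every endpoint, returning the full result bundle.
#' Subjects missing either period are excluded listwise per endpoint and
#' counted; endpoints evaluable in fewer than 2 subjects are skipped
#' with a warning rather than an error.
#'
#' @param data A `study_dataset` from [simulate_crossover_study()], a
#'   `study_records` from [read_study_dataset()], or a records data
#'   frame in the long format.
#' @param dose_nmol Named molar doses (nmol) of the dosed parent
#'   analytes (defaults taken from the dataset's generator parameters
#'   when `data` is a `study_dataset`).
#' @param auc_windows Named list of AUC windows per analyte, e.g.
#'   `list(nicotine = list(c(0, 4)))`.
#' @param nmr_analytes Length-2 character vector naming the cotinine and
#'   3-hydroxycotinine analytes, or NULL to skip the NMR stage.
#' @param level Confidence level for all intervals (default 0.90).
#' @param bounds No-effect range (default `c(0.80, 1.25)`).
#' @param rel_tol Parallelism tolerance for the slope-pattern
#'   classification.
#' @return Object of class `crossover_ddi` with elements `nca` (per
#'   profile), `nmr` (per subject, or NULL), `comparisons` (one
#'   [paired_gmr()] per endpoint), `gmr_table` (flat summary),
#'   `tmax_summary` (descriptive medians and ranges), and `log`.
#' @export
crossover_ddi <- function(data,
                          dose_nmol = NULL,
                          auc_windows = list(),
                          nmr_analytes = NULL,
                          level = 0.90, bounds = c(0.80, 1.25),
                          rel_tol = 0.10) {
  records <- if (inherits(data, "study_dataset")) data$records else data
  if (is.null(dose_nmol) && inherits(data, "study_dataset")) {
    p <- data$params
    dose_nmol <- stats::setNames(p$dose_nmol, p$analytes[1L])
  }
  if (is.null(dose_nmol)) dose_nmol <- numeric()

  # listwise accounting of subjects missing a period
  tab <- table(unique(records[c("subject_id", "period")])$subject_id)
  incomplete <- names(tab)[tab < 2L]
  excl_n <- length(incomplete)
  if (excl_n)
    message(excl_n, " subject(s) excluded (one period missing): ",
            paste(incomplete, collapse = ", "))
  records <- records[!records$subject_id %in% incomplete, ]

  nca_tab <- nca_table(records, dose_nmol = dose_nmol,
                       auc_windows = auc_windows)
  nmr_tab <- NULL
  if (!is.null(nmr_analytes) &&
      all(nmr_analytes %in% records$analyte)) {
    nmr_tab <- nmr_table(records, cot_analyte = nmr_analytes[1L],
                         ohc_analyte = nmr_analytes[2L],
                         rel_tol = rel_tol)
  }

  comparisons <- list()
  gmr_rows <- list()
  add_endpoint <- function(label, tab, column) {
    wide <- .pair_endpoint(tab, column)
    if (is.null(wide)) return(invisible(NULL))
    cmp <- tryCatch(
      paired_gmr(wide$baseline, wide$exposure, level = level,
                 bounds = bounds),
      error = function(e) NULL)
    if (is.null(cmp)) {
      warning("endpoint '", label, "' evaluable for < 2 subjects; skipped",
              call. = FALSE)
      return(invisible(NULL))
    }
    comparisons[[label]] <<- cmp
    gmr_rows[[label]] <<- data.frame(
      endpoint = label, n = cmp$n,
      gm_baseline = unname(cmp$gm_baseline["gm"]),
      gm_baseline_lo = unname(cmp$gm_baseline["ci_low"]),
      gm_baseline_hi = unname(cmp$gm_baseline["ci_high"]),
      gm_exposure = unname(cmp$gm_exposure["gm"]),
      gm_exposure_lo = unname(cmp$gm_exposure["ci_low"]),
      gm_exposure_hi = unname(cmp$gm_exposure["ci_high"]),
      gmr = cmp$gmr, ci_low = cmp$ci_low, ci_high = cmp$ci_high,
      p_value = cmp$p_value, decision = cmp$decision)
  }

  for (analyte in unique(nca_tab$analyte)) {
    sub <- nca_tab[nca_tab$analyte == analyte, ]
    colmap <- c(cmax_nM = "Cmax")
    for (w in grep("^auc_\\d", names(sub), value = TRUE))
      colmap[w] <- sub("^auc_(\\S+)_(\\S+)$", "AUC\\1-\\2", w)
    colmap["auc_inf"] <- "AUC0-inf"
    colmap["t_half_h"] <- "t1/2"
    colmap["cl_f_Lh"] <- "CL/F"
    for (column in names(colmap)) {
      if (!column %in% names(sub)) next
      if (all(is.na(sub[[column]]))) next
      add_endpoint(paste(analyte, colmap[[column]]), sub, column)
    }
  }
  if (!is.null(nmr_tab)) {
    for (column in setdiff(names(nmr_tab),
                           c("subject_id", "period", "window_start",
                             "window_end", "pattern"))) {
      if (all(is.na(nmr_tab[[column]]))) next
      add_endpoint(paste("NMR", column), nmr_tab, column)
    }
  }

  tmax_summary <- do.call(rbind, lapply(unique(nca_tab$analyte),
    function(analyte) {
      sub <- nca_tab[nca_tab$analyte == analyte, ]
      do.call(rbind, lapply(c("baseline", "exposure"), function(p) {
        v <- sub$tmax_h[sub$period == p]
        v <- v[!is.na(v)]
        data.frame(analyte = analyte, period = p,
                   median = if (length(v)) stats::median(v) else NA_real_,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_)
      }))
    }))

  gmr_table <- do.call(rbind, gmr_rows)
  rownames(gmr_table) <- NULL
  structure(list(nca = nca_tab, nmr = nmr_tab,
                 comparisons = comparisons, gmr_table = gmr_table,
                 tmax_summary = tmax_summary,
                 level = level, bounds = bounds,
                 log = list(n_subjects = length(tab),
                            n_excluded = excl_n,
                            excluded = incomplete,
                            n_records = nrow(records))),
            class = "crossover_ddi")
}

# baseline/exposure pairs of one endpoint column; positive values only
.pair_endpoint <- function(tab, column) {
  b <- tab[tab$period == "baseline", c("subject_id", column)]
  e <- tab[tab$period == "exposure", c("subject_id", column)]
  m <- merge(b, e, by = "subject_id", suffixes = c(".b", ".e"))
  vb <- m[[paste0(column, ".b")]]
  ve <- m[[paste0(column, ".e")]]
  ok <- !is.na(vb) & !is.na(ve) & vb > 0 & ve > 0
  if (!sum(ok)) return(NULL)
  list(subject_id = m$subject_id[ok], baseline = vb[ok],
       exposure = ve[ok])
}

#' @export
print.crossover_ddi <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}

#' @export
summary.crossover_ddi <- function(object, ...) {
  list(gmr_table = object$gmr_table, tmax = object$tmax_summary,
       log = object$log)
}

#' Render the analysis as fixed-format text tables
#'
#' Geometric mean (CI) cells per period, the exposure/baseline ratio row
#' with its interval, p-value and decision per endpoint, and tmax as
#' median (min-max). Missing cells print as an em-dash. Output is
#' deterministic for identical inputs.
#'
#' @param results A `crossover_ddi` object.
#' @param digits Significant digits for the numeric cells.
#' @return Character vector of report lines.
#' @export
render_report <- function(results, digits = 3) {
  stopifnot(inherits(results, "crossover_ddi"))
  g <- results$gmr_table
  fmt <- function(v) ifelse(is.na(v), "—", signif(v, digits))
  lines <- c(
    sprintf("Crossover interaction analysis (%g%% CI, no-effect %g-%g)",
            100 * results$level, results$bounds[1L], results$bounds[2L]),
    sprintf("Subjects: %d analysed, %d excluded (missing period)",
            results$log$n_subjects - results$log$n_excluded,
            results$log$n_excluded),
    "")
  if (!is.null(g)) {
    header <- sprintf("%-32s %3s %-22s %-22s %-20s %-8s %s",
                      "Endpoint", "n", "Baseline GM (CI)",
                      "exposure GM (CI)", "exposure/Baseline (CI)",
                      "p", "decision")
    lines <- c(lines, header)
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf(
        "%-32s %3d %-22s %-22s %-20s %-8s %s",
        g$endpoint[i], g$n[i],
        sprintf("%s (%s-%s)", fmt(g$gm_baseline[i]),
                fmt(g$gm_baseline_lo[i]), fmt(g$gm_baseline_hi[i])),
        sprintf("%s (%s-%s)", fmt(g$gm_exposure[i]),
                fmt(g$gm_exposure_lo[i]), fmt(g$gm_exposure_hi[i])),
        sprintf("%s (%s-%s)", fmt(g$gmr[i]), fmt(g$ci_low[i]),
                fmt(g$ci_high[i])),
        ifelse(is.na(g$p_value[i]), "—",
               format(round(g$p_value[i], 4))),
        g$decision[i]))
    }
  }
  t <- results$tmax_summary
  if (!is.null(t) && nrow(t)) {
    lines <- c(lines, "", "tmax, median (min-max), h:")
    for (i in seq_len(nrow(t))) {
      lines <- c(lines, sprintf("  %-24s %-9s %s (%s-%s)",
                                t$analyte[i], t$period[i],
                                fmt(t$median[i]), fmt(t$min[i]),
                                fmt(t$max[i])))
    }
  }
  lines
}
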