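#' Crossover simulation design
#'
#' Study-level settings for the two-period (baseline vs. precipitant
#' exposure) crossover generator. Variability is log-normal throughout:
#' inter-subject deviates on clearance and volume (CV `iiv_cv`),
#' independent period-level deviates on clearance (CV `intra_cv`), and
#' multiplicative proportional assay noise (CV `prop_error_cv`).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sampling_times_h Sampling grid (h), positive strictly
#'   increasing. Default: the 12-hour clinical schedule.
#' @param iiv_cv Inter-subject CV (fraction) on CL/F and V/F.
#' @param intra_cv Intra-subject (period-to-period) CV (fraction) on
#'   clearance; 0.26 matches the nicotine-AUC assumption of the design,
#'   0.16 the letrozole one.
#' @param prop_error_cv Proportional residual-error CV (fraction).
#' @param loq_nM Lower limit of quantification (nM): a single value or a
#'   named per-analyte vector. Concentrations strictly below it are
#'   censored ("below LOQ treated as missing").
#' @param seed Integer RNG seed; fixing it makes the dataset
#'   bit-reproducible.
#' @param activity_exposure [cyp2a6_activity()] applied in the exposure
#'   period (baseline always runs at full activity).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_subjects = 16,
                              sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4,
                                                   6, 8, 10, 12),
                              iiv_cv = 0.30,
                              intra_cv = 0.26,
                              prop_error_cv = 0.10,
                              loq_nM = 0,
                              seed = 1L,
                              activity_exposure = cyp2a6_activity()) {
  if (n_subjects < 2) stop("'n_subjects' must be at least 2", call. = FALSE)
  if (any(sampling_times_h <= 0) ||
      is.unsorted(sampling_times_h, strictly = TRUE))
    stop("'sampling_times_h' must be positive, strictly increasing",
         call. = FALSE)
  if (iiv_cv < 0 || intra_cv < 0 || prop_error_cv < 0)
    stop("CVs must be nonnegative", call. = FALSE)
  if (any(loq_nM < 0)) stop("'loq_nM' must be nonnegative", call. = FALSE)
  stopifnot(inherits(activity_exposure, "cyp2a6_activity"))
  structure(list(n_subjects = as.integer(n_subjects),
                 sampling_times_h = sampling_times_h,
                 iiv_cv = iiv_cv, intra_cv = intra_cv,
                 prop_error_cv = prop_error_cv, loq_nM = loq_nM,
                 seed = as.integer(seed),
                 activity_exposure = activity_exposure),
            class = "simulation_design")
}

#' Read a simulation design from a YAML configuration file
#'
#' Keys mirror the [simulation_design()] arguments; the
#' `activity_exposure` entry is a mapping with `phi0`, `mode` and
#' `k_change`. Absent keys fall back to the function defaults.
#'
#' @param path Path to a YAML file.
#' @return A [simulation_design()] object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("n_subjects: 8", "intra_cv: 0.26", "seed: 4",
#'              "activity_exposure:", "  phi0: 0.8"), cfg)
#' read_design_config(cfg)
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(simulation_design))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$activity_exposure))
    cfg$activity_exposure <- do.call(cyp2a6_activity,
                                     cfg$activity_exposure)
  if (!is.null(cfg$loq_nM)) cfg$loq_nM <- unlist(cfg$loq_nM)
  if (!is.null(cfg$sampling_times_h))
    cfg$sampling_times_h <- as.numeric(unlist(cfg$sampling_times_h))
  do.call(simulation_design, cfg)
}

#' The extended 240-hour letrozole sampling grid
#'
#' The 12-hour clinical schedule plus follow-up draws out to 240 h
#' (needed to capture the 46-h terminal phase).
#' @return Numeric vector of hours.
#' @export
letrozole_times <- function() {
  c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 48, 72, 96, 120, 168, 240)
}

#' Default nicotine-assay LOQ in nM
#'
#' The LC-MS/MS lower calibration limit of 1.2 ng/mL converted to molar
#' units for each analyte of the nicotine cascade.
#' @return Named vector (nM) for nicotine, cotinine, 3-hydroxycotinine.
#' @export
nicotine_loq_nM <- function() {
  c(nicotine = 1.2 * 1000 / MW_NICOTINE,
    cotinine = 1.2 * 1000 / MW_COTININE,
    `3-hydroxycotinine` = 1.2 * 1000 / MW_HYDROXYCOTININE)
}

#' Censor concentrations below the limit of quantification
#'
#' Values strictly below the LOQ are flagged censored and their numeric
#' value removed (treated as missing downstream); values exactly at the
#' LOQ are retained.
#'
#' @param conc_nM Nonnegative concentrations (nM).
#' @param loq_nM Lower limit of quantification (nM), a single value.
#' @return Data frame with columns `conc_nM` (NA where censored) and
#'   `censored`.
#' @export
apply_loq <- function(conc_nM, loq_nM) {
  if (length(loq_nM) != 1L || loq_nM < 0)
    stop("'loq_nM' must be a single nonnegative value", call. = FALSE)
  if (any(conc_nM < 0, na.rm = TRUE))
    stop("negative concentration passed to apply_loq", call. = FALSE)
  censored <- !is.na(conc_nM) & conc_nM < loq_nM
  conc_nM[censored] <- NA_real_
  data.frame(conc_nM = conc_nM, censored = censored)
}

#' Simulate a two-period crossover study
#'
#' Generates the full long-format dataset of a baseline-vs-exposure
#' crossover: per subject, log-normal inter-subject deviates on CL/F and
#' V/F; per period, an independent log-normal deviate on clearance; in
#' the exposure period the design's CYP2A6 activity factor multiplies
#' the CYP2A6-mediated steps; multiplicative log-normal proportional
#' noise is applied to every concentration and the LOQ censoring rule to
#' every record. All draws come from one generator seeded with
#' `design$seed`, in a fixed documented order (per subject: CL deviate,
#' V deviate, baseline-period CL deviate, exposure-period CL deviate,
#' then per period the residual-noise vector), so a fixed seed gives a
#' bit-identical dataset.
#'
#' @param design A [simulation_design()] object.
#' @param params A [cascade_params()] object (e.g. [nicotine_params()]).
#' @return An object of class `study_dataset`: list with `records` (data
#'   frame `subject_id`, `period`, `analyte`, `time_h`, `conc_nM`,
#'   `censored`), `design`, `params`, and `truth` (the realised
#'   per-subject, per-period clearances and volumes, for recovery
#'   tests).
#' @export
simulate_crossover_study <- function(design, params) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(params, "cascade_params"))
  set.seed(design$seed)
  sd_iiv <- sqrt(log(1 + design$iiv_cv^2))
  sd_intra <- sqrt(log(1 + design$intra_cv^2))
  sd_prop <- sqrt(log(1 + design$prop_error_cv^2))
  times <- design$sampling_times_h
  periods <- c("baseline", "exposure")

  rec <- list()
  truth <- list()
  for (i in seq_len(design$n_subjects)) {
    eta_cl <- stats::rnorm(1, 0, sd_iiv)
    eta_v <- stats::rnorm(1, 0, sd_iiv)
    eps_p <- stats::rnorm(2, 0, sd_intra)
    v_i <- params$v_f * exp(eta_v)
    for (p in 1:2) {
      cl_ip <- params$cl_f * exp(eta_cl + eps_p[p])
      act <- if (p == 2L) design$activity_exposure else cyp2a6_activity()
      prof <- simulate_profile(params, act, times,
                               cl_f = cl_ip, v_f = v_i)
      analytes <- setdiff(names(prof), "time_h")
      conc <- as.matrix(prof[analytes])
      if (design$prop_error_cv > 0) {
        noise <- matrix(stats::rnorm(length(conc), 0, sd_prop),
                        nrow(conc), ncol(conc))
        conc <- conc * exp(noise)
      }
      for (a in seq_along(analytes)) {
        loq <- .loq_for(design$loq_nM, analytes[a])
        cens <- apply_loq(conc[, a], loq)
        rec[[length(rec) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", i), period = periods[p],
          analyte = analytes[a], time_h = times,
          conc_nM = cens$conc_nM, censored = cens$censored)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", i), period = periods[p],
        cl_f = cl_ip, v_f = v_i)
    }
  }
  records <- do.call(rbind, rec)
  records <- records[order(records$subject_id, records$period,
                           records$analyte, records$time_h), ]
  rownames(records) <- NULL
  structure(list(records = records, design = design, params = params,
                 truth = do.call(rbind, truth)),
            class = "study_dataset")
}

.loq_for <- function(loq, analyte) {
  if (length(loq) == 1L && is.null(names(loq))) return(unname(loq))
  if (!analyte %in% names(loq))
    stop("no LOQ given for analyte '", analyte, "'", call. = FALSE)
  unname(loq[[analyte]])
}

#' @export
print.study_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "Crossover study dataset: %d subjects x 2 periods, analytes: %s\n",
    x$design$n_subjects, paste(unique(r$analyte), collapse = ", ")))
  cat(sprintf("  %d records, %d censored (below LOQ); seed %d\n",
              nrow(r), sum(r$censored), x$design$seed))
  invisible(x)
}

#' Plot simulated concentration-time profiles
#'
#' Spaghetti plot per analyte, one line per subject-period.
#'
#' @param x A `study_dataset`.
#' @param analyte Analyte to plot (default: first).
#' @param log_y Plot concentrations on a log scale.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly `x`.
#' @export
plot.study_dataset <- function(x, analyte = NULL, log_y = FALSE, ...) {
  r <- x$records
  if (is.null(analyte)) analyte <- r$analyte[1L]
  r <- r[r$analyte == analyte & !r$censored, ]
  key <- interaction(r$subject_id, r$period)
  times <- sort(unique(r$time_h))
  mat <- sapply(split(r, key, drop = TRUE), function(d)
    d$conc_nM[match(times, d$time_h)])
  graphics::matplot(times, mat, type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    log = if (log_y) "y" else "",
                    xlab = "Time (h)", ylab = "Concentration (nM)",
                    main = analyte, ...)
  invisible(x)
}

#' Write a study dataset as long-format delimited text
#'
#' Comma-separated, UTF-8, header `subject_id, period, analyte, time_h,
#' conc_nM, censored`; censored records carry an empty concentration
#' field; rows ordered by subject, period, analyte, time.
#'
#' @param x A `study_dataset` or a bare records data frame.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_study_dataset <- function(x, path) {
  records <- if (inherits(x, "study_dataset")) x$records else x
  stopifnot(identical(names(records),
                      c("subject_id", "period", "analyte", "time_h",
                        "conc_nM", "censored")))
  records <- records[order(records$subject_id, records$period,
                           records$analyte, records$time_h), ]
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(records, utf8, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a long-format study dataset
#'
#' Validates the schema written by [write_study_dataset()]: exact
#' header, nonnegative concentrations, no duplicate (subject, period,
#' analyte, time) rows, censored rows with an empty concentration field.
#'
#' @param path File path.
#' @return A data frame of records (class `study_records`).
#' @export
read_study_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  expected <- c("subject_id", "period", "analyte", "time_h", "conc_nM",
                "censored")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, expected)) {
    bad <- c(setdiff(expected, header), setdiff(header, expected))
    stop("dataset header mismatch; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      period = "character",
                                      analyte = "character",
                                      time_h = "numeric",
                                      conc_nM = "numeric",
                                      censored = "logical"))
  neg <- which(!is.na(d$conc_nM) & d$conc_nM < 0)
  if (length(neg))
    stop("negative concentration at data row ", neg[1L], call. = FALSE)
  bad_cens <- which(d$censored & !is.na(d$conc_nM))
  if (length(bad_cens))
    stop("censored record carries a numeric concentration at data row ",
         bad_cens[1L], call. = FALSE)
  key <- paste(d$subject_id, d$period, d$analyte, d$time_h)
  if (anyDuplicated(key))
    stop("duplicate (subject, period, analyte, time) row: ",
         key[anyDuplicated(key)], call. = FALSE)
  per_profile <- split(d$time_h, paste(d$subject_id, d$period, d$analyte))
  if (any(vapply(per_profile, is.unsorted, logical(1), strictly = TRUE)))
    stop("non-monotone sampling times within a profile", call. = FALSE)
  class(d) <- c("study_records", "data.frame")
  d
}
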