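# Experiment-specific analyses: total-sleep-deprivation efficacy and
# rebound, treatment (prazosin) windows and dose contrasts, ELISA
# normalization and region fold ratios.

state_percent_in_window <- function(h, window) {
  require_window_covered(h, window)
  idx <- window_epoch_idx(h, window)
  if (length(idx) == 0) stop("window contains no epochs", call. = FALSE)
  vapply(stats::setNames(STATES, STATES),
         function(s) 100 * sum(h$states[idx] == s) / length(idx),
         numeric(1))
}

#' Sleep-deprivation efficacy check
#'
#' Percent of the deprivation window spent in each state, with an efficacy
#' flag raised when wake falls below the threshold (default 96%, the level
#' both genotypes exceeded under gentle handling).
#'
#' @param h A [hypnogram()] covering the window.
#' @param tsd_window Clock window (list with `start`, `end`).
#' @param wake_threshold Efficacy threshold in percent wake (default 96).
#' @return A list with `percent` (named W/NR/R) and `efficacious` (logical).
#' @export
tsd_efficacy <- function(h, tsd_window, wake_threshold = 96) {
  p <- state_percent_in_window(h, tsd_window)
  list(percent = p, efficacious = p[["W"]] >= wake_threshold)
}

#' Percent change in NREM delta power between baseline and rebound
#'
#' `100 * (delta_rebound - delta_baseline) / delta_baseline`, where each
#' delta value is the delta-band fraction of a normalized NREM-averaged
#' spectrum. Inputs may be normalized `power_spectrum` objects or named
#' band-fraction vectors containing a `"delta"` entry (the epoch-fidelity
#' path).
#'
#' @param baseline_nrem Baseline NREM spectrum or band-fraction vector.
#' @param rebound_nrem Rebound NREM spectrum or band-fraction vector.
#' @return Percent change of delta power.
#' @export
rebound_delta_shift <- function(baseline_nrem, rebound_nrem) {
  delta_of <- function(x) {
    if (inherits(x, "power_spectrum")) return(band_power(x, "delta"))
    if (!is.null(names(x)) && "delta" %in% names(x)) {
      return(as.numeric(x[["delta"]]))
    }
    if (is.numeric(x) && length(x) == 1) return(as.numeric(x))
    stop("expected a normalized spectrum or a band-fraction vector",
         call. = FALSE)
  }
  d0 <- delta_of(baseline_nrem)
  d1 <- delta_of(rebound_nrem)
  if (d0 <= 0) stop("zero baseline delta power", call. = FALSE)
  100 * (d1 - d0) / d0
}

#' Baseline vs rebound state-time percentages
#'
#' Paired per-subject percentages in the circadian-matched baseline window
#' and the rebound window, the inputs to the mixed (genotype x time-period)
#' ANOVA.
#'
#' @param h A [hypnogram()] covering both windows.
#' @param baseline_window,rebound_window Clock windows (lists with
#'   `start`/`end`); must be of equal length.
#' @return A data.frame with one row per state and columns `baseline_pct`,
#'   `rebound_pct`, `change_pct`.
#' @export
rebound_duration_change <- function(h, baseline_window, rebound_window) {
  len_b <- as.numeric(baseline_window$end - baseline_window$start,
                      units = "secs")
  len_r <- as.numeric(rebound_window$end - rebound_window$start,
                      units = "secs")
  if (abs(len_b - len_r) > 1e-6) {
    stop("baseline and rebound windows must have equal length",
         call. = FALSE)
  }
  pb <- state_percent_in_window(h, baseline_window)
  pr <- state_percent_in_window(h, rebound_window)
  data.frame(state = STATES, baseline_pct = pb[STATES],
             rebound_pct = pr[STATES],
             change_pct = pr[STATES] - pb[STATES], row.names = NULL)
}

#' State composition of a post-injection treatment window
#'
#' Percent W/NR/R over the analysis window starting at the injection time.
#'
#' @param h A [hypnogram()] covering the window.
#' @param injection_time Clock time of injection (`POSIXct` or string).
#' @param window_h Analysis window length in hours (default 2).
#' @return Named numeric of percentages (W, NR, R).
#' @export
treatment_window_summary <- function(h, injection_time, window_h = 2) {
  t0 <- as_clock(injection_time)
  state_percent_in_window(h, clock_window(t0, t0 + window_h * 3600))
}

#' Dose-minus-vehicle NREM contrast per genotype
#'
#' Group-mean NREM percentage-point difference between a dose group and
#' the vehicle group, per genotype, from per-subject treatment-window
#' summaries.
#'
#' @param summaries A data.frame with columns `genotype`, `dose`
#'   (mg/kg, 0 = vehicle) and `nrem_pct`.
#' @param dose Dose to contrast against vehicle.
#' @return A data.frame with columns `genotype`, `dose`, `vehicle_mean`,
#'   `dose_mean`, `nrem_change` (percentage points).
#' @export
dose_contrast <- function(summaries, dose) {
  out <- list()
  for (g in unique(summaries$genotype)) {
    v <- summaries$nrem_pct[summaries$genotype == g & summaries$dose == 0]
    d <- summaries$nrem_pct[summaries$genotype == g & summaries$dose == dose]
    if (length(v) == 0 || length(d) == 0) {
      stop("missing vehicle or dose group for genotype ", g, call. = FALSE)
    }
    out[[g]] <- data.frame(genotype = g, dose = dose,
                           vehicle_mean = mean(v), dose_mean = mean(d),
                           nrem_change = mean(d) - mean(v))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalize ELISA readings to total protein
#'
#' Adds `normalized_pg_mg = abeta_pg_ml / protein_mg_ml`. Rows with
#' nonpositive protein are rejected with an error naming them.
#'
#' @param table A data.frame with columns `region`, `abeta_pg_ml`,
#'   `protein_mg_ml`.
#' @return The table with a `normalized_pg_mg` column appended.
#' @export
normalize_elisa <- function(table) {
  need <- c("region", "abeta_pg_ml", "protein_mg_ml")
  if (!all(need %in% names(table))) {
    stop("ELISA table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(table$protein_mg_ml <= 0)
  if (length(bad) > 0) {
    stop("nonpositive protein content in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  table$normalized_pg_mg <- table$abeta_pg_ml / table$protein_mg_ml
  table
}

#' Fold ratios of region group means
#'
#' Ratio of group means of `normalized_pg_mg` for every ordered pair of
#' regions, the convention behind "x-fold greater" comparisons.
#'
#' @param table A normalized ELISA table (see [normalize_elisa()]).
#' @return A data.frame with columns `region_a`, `region_b`, `fold`
#'   (mean_a / mean_b).
#' @export
region_fold_ratios <- function(table) {
  if (!"normalized_pg_mg" %in% names(table)) table <- normalize_elisa(table)
  regions <- unique(table$region)
  if (length(regions) < 2) {
    stop("fold ratios require at least 2 regions", call. = FALSE)
  }
  counts <- table(table$region)
  if (any(counts < 2)) {
    stop("each region needs at least 2 samples", call. = FALSE)
  }
  means <- tapply(table$normalized_pg_mg, table$region, mean)
  pairs <- expand.grid(region_a = regions, region_b = regions,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$region_a != pairs$region_b, ]
  pairs$fold <- as.numeric(means[pairs$region_a] / means[pairs$region_b])
  rownames(pairs) <- NULL
  pairs
}

#' Look up one fold ratio
#'
#' @param folds Output of [region_fold_ratios()].
#' @param region_a,region_b Regions to compare (`a` over `b`).
#' @return The fold value.
#' @export
fold_between <- function(folds, region_a, region_b) {
  hit <- folds$fold[folds$region_a == region_a & folds$region_b == region_b]
  if (length(hit) != 1) stop("fold not found for ", region_a, "/", region_b,
                             call. = FALSE)
  hit
}
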