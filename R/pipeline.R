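# End-to-end orchestration: run a fixture-driven scenario (simulate ->
# score/bypass -> spectra -> architecture -> protocol analyses -> stats),
# write TSV outputs plus a manifest, and build summary report tables.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run a scenario pipeline
#'
#' Drives a full analysis from a packaged fixture: generates the cohort at
#' the requested fidelity, computes per-subject architecture (and protocol
#' metrics where the scenario defines them), runs the scenario's ANOVA,
#' and writes stage outputs as TSV plus a JSON manifest with seeds and
#' file checksums. Identical config and seed reproduce identical outputs.
#'
#' @param fixture Fixture name or path (see [read_fixture()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param fidelity `"epoch"` (default) or `"signal"`.
#' @param stages Character vector of stages to run; subset of
#'   `c("architecture", "stats")` for baseline scenarios.
#' @return The manifest, invisibly; stage tables as attributes.
#' @export
run_pipeline <- function(fixture, out_dir, seed, fidelity = "epoch",
                         stages = c("architecture", "stats")) {
  fx <- if (is.character(fixture)) read_fixture(fixture) else fixture
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tables <- list()
  if (fx$scenario == "baseline_cohort") {
    design <- fixture_configs(fx, fidelity = fidelity)
    cohort <- simulate_cohort(design, seed = seed)
    if ("architecture" %in% stages) {
      arch <- do.call(rbind, lapply(cohort, function(an) {
        s <- architecture_summary(an$hypnogram)
        s$subject <- an$subject_id
        s$group <- an$group
        s
      }))
      files <- c(files, write_tsv(arch, file.path(out_dir,
                                                  "architecture.tsv")))
      tables$architecture <- arch
    }
    if ("stats" %in% stages && length(design) >= 2 &&
        "architecture" %in% stages) {
      arch <- tables$architecture
      wake_dark <- arch[arch$phase == "dark" & arch$state == "W", ]
      tt <- t_unpaired(
        wake_dark$percent_time[wake_dark$group == names(design)[1]],
        wake_dark$percent_time[wake_dark$group == names(design)[2]])
      stats_df <- data.frame(effect = "dark wake group difference",
                             statistic = tt$t, df = tt$df, p = tt$p)
      files <- c(files, write_tsv(stats_df, file.path(out_dir, "stats.tsv")))
      tables$stats <- stats_df
    }
  } else if (fx$scenario == "treatment") {
    design <- fixture_configs(fx, fidelity = fidelity)
    day <- fx$day %||% "2015-01-02"
    inj <- as_clock(paste(day, paste0(fx$injection_time %||% "10:00",
                                      ":00")))
    cohort <- simulate_cohort(design, seed = seed, duration_s = 24 * 3600,
                              start_time = paste(fx$day_start %||%
                                                   "2015-01-01",
                                                 "20:00:00"))
    meta <- do.call(rbind, lapply(names(design), function(nm) {
      data.frame(group = nm, genotype = design[[nm]]$genotype,
                 dose = design[[nm]]$dose)
    }))
    summaries <- do.call(rbind, lapply(cohort, function(an) {
      p <- treatment_window_summary(an$hypnogram, inj,
                                    fx$window_h %||% 2)
      i <- match(an$group, meta$group)
      data.frame(subject = an$subject_id, genotype = meta$genotype[i],
                 dose = meta$dose[i], wake_pct = p[["W"]],
                 nrem_pct = p[["NR"]], rem_pct = p[["R"]])
    }))
    files <- c(files, write_tsv(summaries, file.path(out_dir,
                                                     "treatment.tsv")))
    tables$treatment <- summaries
  } else {
    stop("run_pipeline does not drive scenario: ", fx$scenario,
         call. = FALSE)
  }
  manifest <- list(
    scenario = fx$scenario, seed = seed, fidelity = fidelity,
    stages = stages,
    package_version = as.character(utils::packageVersion("murisomnia")),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  attr(manifest, "tables") <- tables
  invisible(manifest)
}

#' Summary report tables (mean +/- SEM) from pipeline output
#'
#' Builds per-group mean and SEM tables in the conventional layouts:
#' percent time per state per phase, episode duration and transition
#' counts, or dose tables, depending on which stage outputs exist in the
#' manifest's directory.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return A list of data.frames; groups with a single subject carry
#'   `NA` SEMs and an attached `flag`.
#' @export
make_report <- function(out_dir) {
  sem <- function(x) if (length(x) < 2) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  out <- list()
  arch_path <- file.path(out_dir, "architecture.tsv")
  if (file.exists(arch_path)) {
    arch <- utils::read.delim(arch_path)
    agg <- stats::aggregate(
      cbind(percent_time, mean_episode_s, n_transitions) ~
        group + phase + state, data = arch,
      FUN = function(x) c(mean = mean(x), sem = sem(x)))
    flat <- do.call(data.frame, agg)
    names(flat) <- c("group", "phase", "state",
                     "percent_mean", "percent_sem",
                     "episode_s_mean", "episode_s_sem",
                     "transitions_mean", "transitions_sem")
    out$architecture <- flat
  }
  trt_path <- file.path(out_dir, "treatment.tsv")
  if (file.exists(trt_path)) {
    trt <- utils::read.delim(trt_path)
    agg <- stats::aggregate(
      cbind(wake_pct, nrem_pct, rem_pct) ~ genotype + dose, data = trt,
      FUN = function(x) c(mean = mean(x), sem = sem(x)))
    flat <- do.call(data.frame, agg)
    names(flat) <- c("genotype", "dose", "wake_mean", "wake_sem",
                     "nrem_mean", "nrem_sem", "rem_mean", "rem_sem")
    out$treatment <- flat
  }
  if (length(out) == 0) stop("no stage outputs found in ", out_dir,
                             call. = FALSE)
  if (any(vapply(out, function(df)
    anyNA(df[grep("_sem$", names(df))]), logical(1)))) {
    attr(out, "flag") <- "SEM undefined for single-subject group(s)"
  }
  out
}
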