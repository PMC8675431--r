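# End-to-end orchestration: QC -> harmonize -> FP selection -> correlations
# -> variability -> centiles, driven by one config, with per-stage seeds.

#' Pipeline configuration
#'
#' Either `input` (path to a cohort CSV) or `preset` must be given. All
#' analysis thresholds live here with their conventional defaults; nothing
#' is hard-coded downstream.
#'
#' @param out_dir Output directory (required).
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param preset Synthetic preset name (currently `"enigma_like"`).
#' @param scale Preset size multiplier.
#' @param seed Master seed; fans out to per-stage substreams.
#' @param alpha Closed-test selection alpha, default 0.01.
#' @param mad_k QC MAD multiplier, default 5.
#' @param var_threshold Bonferroni threshold of the variability ANOVA,
#'   default 0.0007.
#' @param sex_threshold_early,sex_threshold_middle Regional thresholds for
#'   the sex comparison of correlations (defaults 0.0007 and 0.0002).
#' @param age_groups An [age_group_def()].
#' @param centile_regions Regions to build centile tables for (`NULL` = all).
#' @param centile_edf Target edf for [fit_lms()], or `"auto"`.
#' @param centile_grid Age grid for centile tables.
#' @param config_file Optional YAML file whose entries override the above.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, preset = "enigma_like",
                            scale = 0.05, seed = 1, alpha = 0.01,
                            mad_k = 5, var_threshold = 0.0007,
                            sex_threshold_early = 0.0007,
                            sex_threshold_middle = 0.0002,
                            age_groups = age_group_def(),
                            centile_regions = NULL,
                            centile_edf = c(lambda = 1, mu = 4, sigma = 2),
                            centile_grid = seq(3, 90, by = 0.5),
                            config_file = NULL) {
  cfg <- list(out_dir = out_dir, input = input, preset = preset,
              scale = scale, seed = seed, alpha = alpha, mad_k = mad_k,
              var_threshold = var_threshold,
              sex_threshold_early = sex_threshold_early,
              sex_threshold_middle = sex_threshold_middle,
              age_groups = age_groups,
              centile_regions = centile_regions,
              centile_edf = centile_edf, centile_grid = centile_grid)
  if (!is.null(config_file)) {
    over <- yaml::read_yaml(config_file)
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  }
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir))
    stop("pipeline config is missing the field 'out_dir'")
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_seed <- function(master, stage) .site_seed(master, stage)

#' Run the full lifespan analysis pipeline
#'
#' Sequence: load or simulate the cohort, MAD quality control, empirical-
#' Bayes site harmonization, exhaustive FP trajectory selection per region,
#' age-group correlations with male/female comparison, residual-dispersion
#' ANOVA plus lnSD meta-analysis, and LMS centile tables. Emits
#' `selection.csv`, `correlations.csv`, `sex_comparison.csv`,
#' `variability.csv`, `meta.csv` and `centiles/` under `out_dir`, along with
#' a run log recording the seed and row counts after each stage. Every
#' output is a pure function of (input, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Named character vector of output paths (the manifest), with the
#'   in-memory stage results attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(line, log_con)
    message(line)
  }
  logmsg("cortlife ", as.character(utils::packageVersion("cortlife")),
         " | seed ", config$seed)
  stage <- "load"
  manifest <- c(log = log_path)
  result <- withCallingHandlers(
    tryCatch({
      cohort <- if (!is.null(config$input)) {
        logmsg("reading cohort from ", config$input)
        read_cohort(config$input)
      } else {
        logmsg("generating preset '", config$preset, "' at scale ",
               config$scale)
        if (!identical(config$preset, "enigma_like"))
          stop("unknown preset '", config$preset, "'")
        gen <- generate_cohort(enigma_like_config(
          scale = config$scale, seed = .stage_seed(config$seed, "synth")))
        gen$cohort
      }
      logmsg("cohort rows: ", nrow(cohort))

      stage <- "qc"
      cohort <- qc_cohort(cohort, k = config$mad_k)
      qc <- attr(cohort, "qc")
      logmsg("qc: ", qc["values_flagged"], " values flagged, ",
             qc["subjects_dropped"], " subjects dropped, rows now ",
             nrow(cohort))

      stage <- "harmonize"
      site_n <- table(cohort$site_id)
      small <- names(site_n)[site_n < 2]
      if (length(small)) {
        cohort <- cohort[!cohort$site_id %in% small, , drop = FALSE]
        logmsg("dropped ", length(small),
               " site(s) with < 2 subjects after QC")
      }
      model <- fit_combat(cohort)
      harmonized <- apply_combat(model, cohort)
      path <- file.path(config$out_dir, "harmonized.csv")
      write_cohort(harmonized, path)
      manifest["harmonized"] <- path
      logmsg("harmonized ", length(model$sites), " sites")

      stage <- "fit-trajectories"
      regions <- cohort_regions(harmonized)
      selections <- lapply(regions, function(rg)
        select_fp_model(harmonized, rg, alpha = config$alpha))
      names(selections) <- regions
      sel_df <- do.call(rbind, lapply(selections, function(s)
        data.frame(region = s$region,
                   powers = paste(s$selected_powers, collapse = ";"),
                   degree = s$selected_degree,
                   r_squared = s$variance_explained,
                   age_at_max = s$age_at_max,
                   stringsAsFactors = FALSE)))
      path <- file.path(config$out_dir, "selection.csv")
      utils::write.csv(sel_df, path, row.names = FALSE)
      manifest["selection"] <- path
      logmsg("selected FP models for ", length(regions), " regions")

      stage <- "correlations"
      cors <- agegroup_correlations(harmonized, config$age_groups)
      path <- file.path(config$out_dir, "correlations.csv")
      utils::write.csv(cors, path, row.names = FALSE)
      manifest["correlations"] <- path
      sexcmp <- sex_correlation_comparison(
        harmonized, config$age_groups,
        threshold = config$sex_threshold_early)
      sexcmp$significant_middle <- sexcmp$p < config$sex_threshold_middle
      path <- file.path(config$out_dir, "sex_comparison.csv")
      utils::write.csv(sexcmp, path, row.names = FALSE)
      manifest["sex_comparison"] <- path

      stage <- "variability"
      grp <- assign_age_group(harmonized$age, config$age_groups)
      var_df <- do.call(rbind, lapply(regions, function(rg) {
        rd <- residual_dispersion(selections[[rg]]$selected$residuals, grp,
                                  threshold = config$var_threshold)
        df <- data.frame(region = rg, F = rd$F, p = rd$p,
                         significant = rd$significant,
                         stringsAsFactors = FALSE)
        for (i in seq_len(nrow(rd$per_group)))
          df[[paste0("msr_", rd$per_group$group[i])]] <-
            rd$per_group$mean_sq_residual[i]
        df
      }))
      path <- file.path(config$out_dir, "variability.csv")
      utils::write.csv(var_df, path, row.names = FALSE)
      manifest["variability"] <- path
      meta_df <- do.call(rbind, lapply(regions, function(rg)
        site_sd_meta(harmonized, rg, config$age_groups)))
      path <- file.path(config$out_dir, "meta.csv")
      utils::write.csv(meta_df, path, row.names = FALSE)
      manifest["meta"] <- path
      logmsg("variability + meta-analysis for ", length(regions),
             " regions")

      stage <- "centiles"
      cent_dir <- file.path(config$out_dir, "centiles")
      dir.create(cent_dir, showWarnings = FALSE)
      cent_regions <- config$centile_regions
      if (is.null(cent_regions)) cent_regions <- regions
      cent <- build_centile_tables(harmonized, regions = cent_regions,
                                   grid = config$centile_grid,
                                   edf = config$centile_edf)
      for (rg in unique(cent$region)) {
        utils::write.csv(cent[cent$region == rg, , drop = FALSE],
                         file.path(cent_dir, paste0(rg, ".csv")),
                         row.names = FALSE)
      }
      manifest["centiles"] <- cent_dir
      logmsg("centile tables for ", length(unique(cent$region)),
             " regions")

      attr(manifest, "results") <- list(
        cohort = harmonized, selections = selections,
        correlations = cors, sex_comparison = sexcmp,
        variability = var_df, meta = meta_df, centiles = cent)
      manifest
    }, error = function(e) {
      logmsg("ERROR in stage '", stage, "': ", conditionMessage(e))
      stop("pipeline failed in stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      logmsg("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  result
}
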