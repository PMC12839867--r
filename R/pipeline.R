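.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.write_units_csv <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full occurrence-to-risk pipeline
#'
#' Stages, in order: data (synthetic generation or CSV ingestion),
#' occurrence statistics (regional summaries, pooled means, Kruskal-Wallis
#' and pairwise Wilcoxon/BH tests, SCCP-MCCP correlations), congener
#' profiles, Monte Carlo exposure per population group and analyte class
#' (with rank-regression sensitivity for the whole population), and MOE risk
#' characterization. All stage outputs are written to `out_dir` as CSV (each
#' with a units comment line) plus a JSON run manifest; outputs are pure
#' functions of (inputs, config, seed).
#'
#' @param config `cp_config` list, see [default_run_config()].
#' @param out_dir output directory (created if missing).
#' @return named list of output file paths, invisibly; the loaded results
#'   are returned in the `results` attribute.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- config$constants %||% cp_constants()

  dat <- .stage("data", {
    if (isTRUE(config$simulate)) {
      specs <- default_study_specs(survey_scale = config$survey_scale %||% 1)
      conc <- gen_concentrations(specs$regions, config$seed)
      survey <- gen_survey(specs$subgroups, config$seed)
      write_concentrations(conc, file.path(out_dir, "concentrations.csv"))
      write_survey(survey, file.path(out_dir, "survey.csv"))
      list(conc = conc, survey = survey,
           inputs = file.path(out_dir, c("concentrations.csv", "survey.csv")))
    } else {
      for (f in c(config$concentrations_csv, config$survey_csv)) {
        if (is.null(f) || !file.exists(f)) {
          stop("input file not found: ", if (is.null(f)) "<unset>" else f)
        }
      }
      list(conc = read_concentrations(config$concentrations_csv,
                                      config$mdl_policy, constants),
           survey = read_survey(config$survey_csv),
           inputs = c(config$concentrations_csv, config$survey_csv))
    }
  })

  occ <- .stage("occurrence", {
    summ <- summarize_regions(dat$conc, constants)
    rg <- region_groups()
    pooled <- do.call(rbind, lapply(unique(summ$analyte_class), function(cl) {
      s <- summ[summ$analyte_class == cl, ]
      scopes <- c(list(Total = s),
                  split(s, rg$super_region[match(s$region, rg$region)]))
      do.call(rbind, lapply(names(scopes), function(nm) {
        data.frame(scope = nm, analyte_class = cl,
                   pooled_mean = pooled_mean(scopes[[nm]]),
                   n = sum(scopes[[nm]]$n), stringsAsFactors = FALSE)
      }))
    }))
    tot <- class_totals(dat$conc)
    tests <- do.call(rbind, lapply(unique(tot$analyte_class), function(cl) {
      g <- split(tot$total_ng_g[tot$analyte_class == cl],
                 tot$region[tot$analyte_class == cl])
      kw <- kruskal_wallis(g)
      pw <- pairwise_wilcoxon_bh(g)
      rbind(
        data.frame(analyte_class = cl, group1 = "all-regions", group2 = "",
                   statistic = kw$statistic, raw_p = kw$raw_p,
                   adjusted_p = NA_real_, method = kw$method,
                   stringsAsFactors = FALSE),
        cbind(analyte_class = cl, pw)
      )
    }))
    cors <- class_correlations(dat$conc, config$correlation_method)
    list(summ = summ, pooled = pooled, tests = tests, cors = cors)
  })
  .write_units_csv(occ$summ, file.path(out_dir, "occurrence_summary.csv"),
                   "concentrations ng/g wet weight")
  .write_units_csv(occ$pooled, file.path(out_dir, "pooled_means.csv"),
                   "pooled_mean ng/g wet weight")
  .write_units_csv(occ$tests, file.path(out_dir, "tests.csv"),
                   "dimensionless (test statistics, p-values)")
  .write_units_csv(occ$cors, file.path(out_dir, "correlations.csv"),
                   "dimensionless (correlation coefficients)")

  prof <- .stage("profiles", {
    p <- decompose_profiles(dat$conc, "per_region",
                            config$profile_aggregation)
    profiles_long(p)
  })
  .write_units_csv(prof, file.path(out_dir, "profiles.csv"),
                   "fraction of class (or total CP) concentration")

  expo <- .stage("exposure", {
    survey <- assign_subgroups(dat$survey,
                               consumer_rule = config$consumer_rule)
    tot <- class_totals(dat$conc)
    groups <- c(default_subgroups()$label, "Consumer only", "All")
    summaries <- list()
    draws_all <- list()
    for (cl in c("SCCP", "MCCP")) {
      conc_fit <- fit_distribution(tot$total_ng_g[tot$analyte_class == cl],
                                   config$families)
      for (g in groups) {
        members <- survey[subgroup_members(survey, g), , drop = FALSE]
        if (nrow(members) == 0L) next
        days <- unlist(members[, c("day1", "day2", "day3")], use.names = FALSE)
        days <- days[!is.na(days)]
        p_day <- mean(days > 0)
        amounts <- days[days > 0]
        cm <- cons_model(p_day, fit_distribution(amounts, config$families))
        bw_fit <- fit_distribution(members$body_weight, config$families)
        keep <- g == "All"
        s <- simulate_exposure(
          conc_fit, cm, bw_fit, n_iter = config$n_iterations,
          seed = substream_seed(config$seed, paste0("mc/", cl, "/", g)),
          subgroup = g, analyte_class = cl, keep_draws = keep
        )
        if (keep) draws_all[[cl]] <- s$draws
        s$draws <- NULL
        summaries[[paste(cl, g)]] <- s
      }
    }
    sens <- do.call(rbind, lapply(names(draws_all), function(cl) {
      ctv <- contribution_to_variance(
        draws_all[[cl]][c("c", "f", "bw")], draws_all[[cl]]$edi)
      cbind(analyte_class = cl, subgroup = "All", ctv,
            r_squared = attr(ctv, "r_squared"))
    }))
    list(summaries = summaries, table = exposure_table(summaries),
         sens = sens)
  })
  .write_units_csv(expo$table, file.path(out_dir, "exposure_summary.csv"),
                   "mean/ci_half_width/p95/median ng/kg bw/d")
  .write_units_csv(expo$sens, file.path(out_dir, "sensitivity.csv"),
                   "contribution percent of output variance")

  risk <- .stage("risk", moe_table(expo$summaries, constants))
  .write_units_csv(risk, file.path(out_dir, "moe.csv"),
                   "exposure ng/kg bw/d; pod mg/kg bw/d; moe dimensionless")

  manifest <- .stage("manifest", {
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "constants")],
                                 auto_unbox = TRUE, digits = NA, null = "null")
    cfg_file <- file.path(out_dir, "config.json")
    writeLines(cfg_json, cfg_file)
    list(
      package_version = as.character(utils::packageVersion("cpexposure")),
      master_seed = config$seed,
      config_digest = unname(tools::md5sum(cfg_file)),
      input_digests = as.list(tools::md5sum(dat$inputs)),
      created = format(Sys.time(), tz = "UTC")
    )
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  paths <- file.path(out_dir, c(
    "occurrence_summary.csv", "pooled_means.csv", "tests.csv",
    "correlations.csv", "profiles.csv", "exposure_summary.csv",
    "sensitivity.csv", "moe.csv", "manifest.json"
  ))
  names(paths) <- basename(paths)
  res <- list(occurrence = occ, profiles = prof, exposure = expo,
              risk = risk, manifest = manifest)
  attr(paths, "results") <- res
  invisible(paths)
}
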