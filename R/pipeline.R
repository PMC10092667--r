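#' Write a self-contained synthetic demo study
#'
#' Generates a small study -- 2 species x 6 colonies x 30 years of counts
#' (one species counted as individuals with a conversion series), colony
#' locations, a species configuration and 20 x 20 monthly grids for the four
#' environmental variables -- plus a ground-truth JSON sidecar recording
#' every generating parameter. The fixture's true density coefficients span
#' 0 to -0.0025 so both the density-dependent and density-independent
#' branches of the pipeline are exercised.
#'
#' @param outdir Writable output directory (created if needed).
#' @param seed Integer seed; all files are deterministic in it.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_demo_dataset <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  species <- list(
    kittiwake = list(unit = "pairs", clutch_max = 2, foraging_km = 60,
                     beta0 = 0.25, beta1s = c(0, -5e-4, -1e-3, -1.5e-3,
                                              -2e-3, -2.5e-3),
                     N0 = 250),
    guillemot = list(unit = "individuals", clutch_max = 1, foraging_km = 80,
                     beta0 = 0.2, beta1s = c(0, -4e-4, -8e-4, -1.2e-3,
                                             -1.6e-3, -2e-3),
                     N0 = 400))
  years <- 1986:2015
  series <- list()
  truth <- list(seed = seed, colonies = list())
  colonies <- NULL
  conv <- simulate_conversion_factors(years, level = 0.67, wiggle_sd = 0.005,
                                      se = 0.02, seed = seed + 900L)
  idx <- 0
  for (sp in names(species)) {
    cfg <- species[[sp]]
    for (i in seq_along(cfg$beta1s)) {
      idx <- idx + 1
      b1 <- cfg$beta1s[i]
      kind <- if (b1 == 0) "M0" else "M1"
      # equilibrium ~ N0 when DD present: beta0 scaled to the coefficient
      b0 <- if (b1 == 0) 0.02 else -b1 * cfg$N0
      spec <- sim_spec(kind, beta0 = b0, beta1 = if (b1 == 0) NULL else b1,
                       sigma_eps = 0.1, n_years = length(years),
                       N0 = cfg$N0, count_unit = cfg$unit,
                       missing_fraction = 0.1, start_year = years[1],
                       seed = seed + idx)
      sim <- simulate_colony_counts(spec, conversion = conv)
      s <- sim$series
      s$colony_id <- sprintf("%s_%02d", sp, i)
      s$species <- sp
      series[[s$colony_id]] <- s
      truth$colonies[[s$colony_id]] <- list(
        species = sp, model_kind = kind, beta0 = b0, beta1 = b1,
        sigma_eps = 0.1, N0 = cfg$N0, unit = cfg$unit)
      colonies <- rbind(colonies, data.frame(
        colony_id = s$colony_id, species = sp,
        lat = 55 + 0.15 * i, lon = -2 + 0.25 * (idx %% 5),
        stringsAsFactors = FALSE))
    }
  }
  paths <- list(
    counts = file.path(outdir, "counts.csv"),
    colonies = file.path(outdir, "colonies.csv"),
    species = file.path(outdir, "species_config.csv"),
    conversion = file.path(outdir, "conversion.csv"),
    truth = file.path(outdir, "truth.json"))
  write_counts(series, paths$counts)
  utils::write.csv(colonies, paths$colonies, row.names = FALSE)
  utils::write.csv(data.frame(
    species = names(species),
    clutch_max = vapply(species, `[[`, 1.0, "clutch_max"),
    survival_floor = 0.2,
    foraging_range_km = vapply(species, `[[`, 1.0, "foraging_km"),
    breeding_months = "4-7",
    unit = vapply(species, `[[`, "", "unit"),
    stringsAsFactors = FALSE), paths$species, row.names = FALSE)
  utils::write.csv(data.frame(year = conv$years, m_kt = conv$m_kt,
                              s_kt = conv$s_kt),
                   paths$conversion, row.names = FALSE)
  # environmental grids: spatial trends in the SD field so colonies differ
  vars <- c("SST", "SSH", "CHL", "TF")
  for (v in seq_along(vars)) {
    nm <- vars[v]
    sd_field <- outer(seq(0.5, 1.5, length.out = 20),
                      seq(0.8, 1.2, length.out = 20))
    g <- simulate_env_grid(env_grid_spec(
      nm, n_lat = 20, n_lon = 20, cell_km = 10, years = years, months = 4:7,
      mean_field = 10, temporal_sd_field = sd_field,
      origin_lat = 54.8, origin_lon = -2.6, seed = seed + 100L + v))
    paths[[paste0("grid_", nm)]] <- file.path(outdir,
                                              paste0("grid_", nm, ".csv"))
    write_env_grid(g, paths[[paste0("grid_", nm)]])
  }
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

config_hash <- function(config) {
  # small FNV-1a style hash of the deparsed config, for provenance stamps
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

read_species_config <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    mr <- as.integer(strsplit(tab$breeding_months[i], "-")[[1]])
    species_params(tab$species[i], tab$clutch_max[i], tab$survival_floor[i],
                   tab$foraging_range_km[i], seq(mr[1], mr[2]))
  })
  stats::setNames(out, tab$species)
}

#' Run the full two-stage analysis pipeline
#'
#' Orchestrates filtering, state-space fitting of the configured models,
#' model assessment, environmental metrics and the stage-two regressions
#' from a single configuration, writing delimited result tables plus a JSON
#' sidecar (seed, config hash, R-hat summaries) into the output directory.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `counts`, `colonies`, `species_config`, `grids` (named list or vector
#'   of CSV paths keyed by variable), optional `conversion`; `outdir`;
#'   optional `models` (default `c("M0","M1")`), `mcmc` (list of
#'   [mcmc_config()] fields), `filters` (list: min_years, max_q, first_q,
#'   max_gap), `seed`, `strict` (error on non-convergence).
#' @return Invisibly, a list with the assessment table, environmental
#'   metrics, regression report and per-fit objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  need <- c("counts", "colonies", "species_config", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing entries: ",
                         paste(miss, collapse = ", "))
  paths <- c(config$counts, config$colonies, config$species_config,
             unlist(config$grids), config$conversion)
  bad <- paths[!file.exists(paths)]
  if (length(bad)) stop("pre-flight failure, missing input files: ",
                        paste(bad, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  models <- config$models %||% c("M0", "M1")
  filt <- config$filters %||% list()
  seed <- as.integer(config$seed %||% 1L)
  mcfg <- do.call(mcmc_config, c(config$mcmc %||%
                                   list(n_iter = 6000, n_burnin = 1500,
                                        thin = 3),
                                 list(seed = seed)))
  strict <- isTRUE(config$strict)
  meta <- list(seed = seed,
               config_hash = config_hash(config[setdiff(names(config),
                                                        "outdir")]),
               models = models, timestamp = format(Sys.time(), tz = "UTC"))

  # stage 0: load + filter ---------------------------------------------
  collection <- read_counts(config$counts)
  filtered <- filter_colonies(collection,
                              min_years = filt$min_years %||% 20,
                              max_q = filt$max_q %||% 0.10,
                              first_q = filt$first_q %||% 0.05,
                              max_gap = filt$max_gap %||% 5)
  report <- attr(filtered, "report")
  utils::write.csv(report, file.path(config$outdir, "filtering_report.csv"),
                   row.names = FALSE)
  write_counts(filtered, file.path(config$outdir, "filtered_counts.csv"))
  message(sprintf("[filter] %d of %d series retained", length(filtered),
                  length(collection)))

  species_cfg <- read_species_config(config$species_config)
  species_unit <- {
    tab <- utils::read.csv(config$species_config, stringsAsFactors = FALSE)
    stats::setNames(tab$unit %||% rep("pairs", nrow(tab)), tab$species)
  }
  conv <- NULL
  if (!is.null(config$conversion)) {
    ct <- utils::read.csv(config$conversion)
    conv <- conversion_series(ct$year, ct$m_kt, ct$s_kt)
  }

  # stage 1: fits + assessment -----------------------------------------
  fits <- list()
  rows <- list()
  for (s in filtered) {
    sp <- species_cfg[[s$species]]
    if (is.null(sp)) stop("stage fit: no species config for series ",
                          s$colony_id)
    for (kind in models) {
      fit <- tryCatch(
        fit_state_space(s, model_spec(kind, sp), mcfg,
                        conversion = if (s$unit == "individuals") conv),
        error = function(e) stop("stage fit failed for series ",
                                 s$colony_id, " (", kind, "): ",
                                 conditionMessage(e)))
      if (!fit$converged) {
        msg <- sprintf("series %s model %s: max Rhat %.3f above %.2f",
                       s$colony_id, kind, max(fit$rhat, na.rm = TRUE),
                       fit$rhat_threshold)
        if (strict) stop(msg) else warning(msg)
      }
      fits[[paste(s$colony_id, kind, sep = ":")]] <- fit
      rows[[length(rows) + 1]] <- assess_fit(fit)
    }
  }
  assessment <- do.call(rbind, lapply(rows, function(r) {
    # align columns across M0 (no beta1 fields) and M1/M2 rows
    all_cols <- unique(unlist(lapply(rows, names)))
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  }))
  # delta DIC per series relative to M0 where present
  if ("M0" %in% models) {
    base <- assessment[assessment$model == "M0",
                       c("colony_id", "dic")]
    names(base)[2] <- "dic_m0"
    assessment <- merge(assessment, base, by = "colony_id", all.x = TRUE,
                        sort = FALSE)
    assessment$delta_dic <- assessment$dic_m0 - assessment$dic
  }
  assessment$config_hash <- meta$config_hash
  assessment$seed <- seed
  utils::write.csv(assessment, file.path(config$outdir, "assessment.csv"),
                   row.names = FALSE)

  # stage 2: environmental metrics -------------------------------------
  metrics <- NULL
  regression <- NULL
  if (!is.null(config$grids)) {
    grids <- lapply(config$grids, read_env_grid)
    csites <- utils::read.csv(config$colonies, stringsAsFactors = FALSE)
    mrows <- list()
    for (i in seq_len(nrow(csites))) {
      site <- colony_site(csites$colony_id[i], csites$lat[i], csites$lon[i],
                         csites$species[i])
      sp <- species_cfg[[site$species]]
      for (g in grids) {
        kind <- if (g$variable %in% c("SST", "SSH")) "temporal" else
          "spatiotemporal"
        m <- if (kind == "temporal")
          climate_temporal_variation(g, site, sp) else
            resource_spatiotemporal_variation(g, site, sp)
        mrows[[length(mrows) + 1]] <- m
      }
    }
    metrics <- do.call(rbind, mrows)
    metrics$config_hash <- meta$config_hash
    metrics$seed <- seed
    utils::write.csv(metrics, file.path(config$outdir, "env_metrics.csv"),
                     row.names = FALSE)

    # stage 3: regressions per species x variable ----------------------
    dd_model <- if ("M1" %in% models) "M1" else models[length(models)]
    est <- assessment[assessment$model == dd_model &
                        !is.na(assessment$beta1_mean),
                      c("colony_id", "species", "beta1_mean", "beta1_sd")]
    names(est)[3:4] <- c("D_est", "sd_D_est")
    rrows <- list()
    for (sp_name in unique(est$species)) {
      esp <- est[est$species == sp_name, ]
      if (nrow(esp) < 3) next
      for (g in grids) {
        msel <- metrics[metrics$variable == g$variable, ]
        env <- msel$value[match(esp$colony_id, msel$colony_id)]
        rfit <- fit_dd_env_model(esp, env, variable = g$variable,
                                 mcmc = mcmc_config(n_iter = 4000,
                                                    n_burnin = 1000,
                                                    thin = 2, seed = seed))
        row <- ddreg_report_row(rfit)
        row$species <- sp_name
        rrows[[length(rrows) + 1]] <- row
      }
    }
    if (length(rrows)) {
      regression <- do.call(rbind, rrows)
      regression$config_hash <- meta$config_hash
      regression$seed <- seed
      utils::write.csv(regression,
                       file.path(config$outdir, "dd_env_regression.csv"),
                       row.names = FALSE)
    }
  }

  meta$rhat_max <- max(vapply(fits, function(f) max(f$rhat, na.rm = TRUE),
                              1.0))
  meta$n_series <- length(filtered)
  jsonlite::write_json(meta, file.path(config$outdir, "pipeline_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(assessment = assessment, metrics = metrics,
                 regression = regression, fits = fits,
                 filtering_report = report, meta = meta))
}
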