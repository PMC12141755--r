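#' Load and validate a pipeline run configuration
#'
#' The pipeline is driven by a single YAML file. Recognized top-level
#' fields: `seed`, `out_dir`, `k` (sampling units per site, default 9),
#' `radii` (`min`/`max`/`step`, default 250/4500/250), `vif_threshold`
#' (default 3), `n_boot`, `ci_level`, `link` (only `"logit"` is
#' implemented), `tiepoint_model` (`"affine"` or `"similarity"`), a
#' `simulate` block describing the synthetic world, and an optional
#' `groups` map (species -> breeding-habitat group).
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @param base_dir directory against which relative paths resolve (default:
#'   the config file's directory, or the working directory for list input).
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (is.null(base_dir)) base_dir <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    if (is.null(base_dir)) base_dir <- getwd()
  }
  cfg$out_dir <- file.path(base_dir, cfg$out_dir %||% "out")
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$k <- as.integer(cfg$k %||% 9)
  r <- cfg$radii %||% list(min = 250, max = 4500, step = 250)
  if ((r$max - r$min) %% r$step != 0)
    stop("invalid config field 'radii': step must divide (max - min)")
  cfg$radii_grid <- seq(r$min, r$max, by = r$step)
  cfg$vif_threshold <- cfg$vif_threshold %||% 3
  cfg$n_boot <- as.integer(cfg$n_boot %||% 10000)
  cfg$ci_level <- cfg$ci_level %||% 0.95
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("invalid config field 'ci_level': must lie in (0, 1)")
  cfg$link <- cfg$link %||% "logit"
  if (cfg$link != "logit")
    stop("invalid config field 'link': only 'logit' is implemented")
  cfg$tiepoint_model <- cfg$tiepoint_model %||% "affine"
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages behind subcommands: `simulate`
#' (synthetic landscape, surveys and photo pairs), `align` (tie points ->
#' registration transforms -> aligned historical masks), `account`
#' (compositions, Shannon diversity, land cover change tests), `fit`
#' (multi-scale species distribution models), `backcast` (occurrence
#' predictions, per-species change tests, sensitivity analysis, community
#' diversity) and `report` (aggregate manifest). Every stage writes a
#' `manifest_<stage>.json` listing its outputs with MD5 checksums, the
#' seed, and the effective configuration, so identical config and seed
#' reproduce identical outputs.
#'
#' @param subcommand one of `"simulate"`, `"align"`, `"account"`, `"fit"`,
#'   `"backcast"`, `"report"`.
#' @param config YAML path or config list (see [load_config()]).
#' @return Invisibly, the character vector of files written.
#' @export
run_pipeline <- function(subcommand, config) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  stage <- match.arg(subcommand, c("simulate", "align", "account", "fit",
                                   "backcast", "report"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(stage,
    simulate = stage_simulate(cfg),
    align = stage_align(cfg),
    account = stage_account(cfg),
    fit = stage_fit(cfg),
    backcast = stage_backcast(cfg),
    report = stage_report(cfg))
  write_manifest(cfg, stage, outputs)
  invisible(outputs)
}

write_manifest <- function(cfg, stage, outputs) {
  man <- list(stage = stage, seed = cfg$seed,
              package_version = as.character(utils::packageVersion("photobackcast")),
              config = cfg[setdiff(names(cfg), c("out_dir"))],
              outputs = lapply(outputs, function(f)
                list(file = basename(f),
                     md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, file.path(cfg$out_dir,
                                      paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

config_scheme <- function(cfg) {
  if (is.null(cfg$scheme)) default_scheme()
  else landcover_scheme(unlist(cfg$scheme$categories),
                        merge_map = unlist(cfg$scheme$merge_map),
                        invalid_id = cfg$scheme$invalid_id %||% 255L)
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  if (is.null(sim)) stop("config has no 'simulate' block")
  scheme <- config_scheme(cfg)
  out <- cfg$out_dir
  comp <- unlist(sim$landscape$composition)
  land <- generate_landscape(scheme,
                             shape = c(sim$landscape$rows, sim$landscape$cols),
                             target_composition = comp,
                             autocorr_length = sim$landscape$autocorr_length %||% 5,
                             seed = cfg$seed,
                             cell_size = sim$landscape$cell_size %||% 100)
  files <- character(0)
  f <- file.path(out, "landscape.png")
  write_mask_png(classified_image(land$labels), f); files <- c(files, f)
  f <- file.path(out, "landscape_meta.json")
  jsonlite::write_json(list(cell_size = land$cell_size,
                            origin = land$origin), f,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  truths <- lapply(sim$truths, function(o)
    species_truth(o$species, o$scale_m, unlist(o$coefficients), o$intercept))
  f <- file.path(out, "truths.json")
  write_truths_json(truths, f); files <- c(files, f)
  ext_x <- ncol(land$labels) * land$cell_size
  ext_y <- nrow(land$labels) * land$cell_size
  margin <- min(max(cfg$radii_grid), ext_x / 4, ext_y / 4)
  sites <- with_seed(cfg$seed + 1, function()
    data.frame(site_id = sprintf("site_%03d", seq_len(sim$n_sites)),
               x = stats::runif(sim$n_sites, margin, ext_x - margin),
               y = stats::runif(sim$n_sites, land$origin[2] - ext_y + margin,
                                land$origin[2] - margin)))
  f <- file.path(out, "sites.csv")
  utils::write.csv(sites, f, row.names = FALSE); files <- c(files, f)
  surveys <- simulate_surveys(land, truths, sites, k = cfg$k,
                              seed = cfg$seed + 2, scheme = scheme)
  f <- file.path(out, "surveys.csv")
  write_surveys(surveys, f); files <- c(files, f)
  # photo pairs: independent small scenes with the configured transition
  transition <- if (!is.null(sim$transition)) {
    tr <- do.call(rbind, lapply(sim$transition, as.data.frame))
    tr$from <- id_for_name(scheme, as.character(tr$from))
    tr$to <- id_for_name(scheme, as.character(tr$to))
    tr
  } else NULL
  w <- sim$warp %||% list(angle_deg = 0, scale = 1, tx = 0, ty = 0)
  warp <- similarity_transform(angle = (w$angle_deg %||% 0) * pi / 180,
                               scale = w$scale %||% 1,
                               tx = w$tx %||% 0, ty = w$ty %||% 0)
  shape <- unlist(sim$pair_shape %||% c(80, 80))
  truth_rows <- list()
  for (i in seq_len(sim$n_pairs)) {
    scene <- generate_landscape(scheme, shape, comp,
                                autocorr_length = sim$landscape$autocorr_length %||% 5,
                                seed = cfg$seed + 100 + i,
                                cell_size = sim$landscape$cell_size %||% 100)
    base <- classified_image(scene$labels)
    gp <- generate_photo_pair(base, transition = transition, warp = warp,
                              tiepoint_noise_sd = sim$tiepoint_noise_sd %||% 0,
                              seed = cfg$seed + 200 + i,
                              station_id = sprintf("station_%02d", i))
    id <- gp$pair$station_id
    f1 <- file.path(out, paste0(id, "_hist.png"))
    f2 <- file.path(out, paste0(id, "_mod.png"))
    f3 <- file.path(out, paste0(id, "_tiepoints.csv"))
    write_mask_png(gp$pair$historical, f1)
    write_mask_png(gp$pair$modern, f2)
    write_tie_points(gp$tiepoints, f3, pair_id = id)
    files <- c(files, f1, f2, f3)
    gp$change$station_id <- id
    truth_rows[[i]] <- gp$change
  }
  f <- file.path(out, "pair_truth_change.csv")
  utils::write.csv(do.call(rbind, truth_rows), f, row.names = FALSE)
  c(files, f)
}

pair_stations <- function(out) {
  sort(unique(sub("_tiepoints\\.csv$", "",
                  basename(list.files(out, pattern = "_tiepoints\\.csv$")))))
}

stage_align <- function(cfg) {
  out <- cfg$out_dir
  stations <- pair_stations(out)
  if (!length(stations)) stop("no tie point files found in ", out)
  files <- character(0)
  for (id in stations) {
    tp <- read_tie_points(file.path(out, paste0(id, "_tiepoints.csv")))
    t <- estimate_affine(tp, kind = cfg$tiepoint_model)
    if (attr(t, "rms") > 3)
      warning("alignment for ", id, " has RMS ", round(attr(t, "rms"), 2),
              " px (flagged)")
    hist <- read_mask_png(file.path(out, paste0(id, "_hist.png")))
    mod <- read_mask_png(file.path(out, paste0(id, "_mod.png")))
    aligned <- apply_transform(hist, t, out_shape = dim(mod$labels))
    f1 <- file.path(out, paste0(id, "_transform.json"))
    f2 <- file.path(out, paste0(id, "_hist_aligned.png"))
    write_transform_json(t, f1)
    write_mask_png(aligned, f2)
    files <- c(files, f1, f2)
  }
  files
}

stage_account <- function(cfg) {
  out <- cfg$out_dir
  scheme <- config_scheme(cfg)
  stations <- pair_stations(out)
  if (!length(stations)) stop("no photo pairs found in ", out)
  comp_rows <- list()
  pairs <- list()
  for (id in stations) {
    fh <- file.path(out, paste0(id, "_hist_aligned.png"))
    fm <- file.path(out, paste0(id, "_mod.png"))
    ch <- tryCatch(composition(read_mask_png(fh), scheme),
                   error = function(e) stop("cannot account for ", fh, ": ",
                                            conditionMessage(e), call. = FALSE))
    cm <- tryCatch(composition(read_mask_png(fm), scheme),
                   error = function(e) stop("cannot account for ", fm, ": ",
                                            conditionMessage(e), call. = FALSE))
    if (!is.null(scheme$merge_map)) {
      ch <- merge_categories(ch, scheme)
      cm <- merge_categories(cm, scheme)
    }
    pairs[[id]] <- list(hist = ch, mod = cm)
    comp_rows[[length(comp_rows) + 1]] <- data.frame(
      station_id = id, epoch = c("historical", "modern"),
      rbind(as.numeric(ch), as.numeric(cm)),
      shannon = c(shannon_index(ch), shannon_index(cm)),
      n_valid = c(attr(ch, "n_valid"), attr(cm, "n_valid")),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  cats <- names(pairs[[1]]$hist)
  comps <- do.call(rbind, comp_rows)
  names(comps)[3:(2 + length(cats))] <- cats
  f1 <- file.path(out, "compositions.csv")
  utils::write.csv(comps, f1, row.names = FALSE)
  tests <- paired_change(pairs, n_boot = cfg$n_boot,
                         conf_level = cfg$ci_level, seed = cfg$seed)
  f2 <- file.path(out, "landcover_change.csv")
  write_change_tests(tests, f2)
  c(f1, f2)
}

stage_fit <- function(cfg) {
  out <- cfg$out_dir
  scheme <- config_scheme(cfg)
  meta <- jsonlite::read_json(file.path(out, "landscape_meta.json"),
                              simplifyVector = TRUE)
  land <- raster_map(read_mask_png(file.path(out, "landscape.png"))$labels,
                     cell_size = meta$cell_size, origin = meta$origin)
  surveys <- read_surveys(file.path(out, "surveys.csv"))
  sites <- unique(surveys[c("site_id", "x", "y")])
  covars <- build_covariate_table(land, sites, radii = cfg$radii_grid,
                                  scheme = scheme)
  f1 <- file.path(out, "covariates.csv")
  utils::write.csv(as.data.frame(covars), f1, row.names = FALSE)
  fits <- lapply(unique(surveys$species), function(sp) {
    det <- surveys[surveys$species == sp, c("site_id", "count")]
    fit <- select_scale(det, covars, k = cfg$k, species = sp,
                        vif_threshold = cfg$vif_threshold)
    validate_model(fit)
  })
  f2 <- file.path(out, "fits.json")
  write_sdm_fits(fits, f2)
  c(f1, f2)
}

stage_backcast <- function(cfg) {
  out <- cfg$out_dir
  fits <- read_sdm_fits(file.path(out, "fits.json"))
  comps <- utils::read.csv(file.path(out, "compositions.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  cats <- setdiff(names(comps), c("station_id", "epoch", "shannon", "n_valid"))
  pairs <- lapply(split(comps, comps$station_id), function(g) {
    mk <- function(epoch) {
      r <- g[g$epoch == epoch, ]
      composition_vector(stats::setNames(as.numeric(r[1, cats]), cats),
                         r$n_valid[1])
    }
    list(hist = mk("historical"), mod = mk("modern"))
  })
  res <- backcast_pairs(fits, pairs)
  f1 <- file.path(out, "backcast_predictions.csv")
  utils::write.csv(res, f1, row.names = FALSE)
  tests <- species_change_test(res, n_boot = cfg$n_boot,
                               conf_level = cfg$ci_level, seed = cfg$seed)
  f2 <- file.path(out, "species_change.csv")
  write_change_tests(tests, f2)
  sens <- sensitivity_analysis(fits, pairs)
  f3 <- file.path(out, "sensitivity.csv")
  utils::write.csv(sens, f3, row.names = FALSE)
  comm <- community_diversity_change(res, n_boot = cfg$n_boot,
                                     conf_level = cfg$ci_level,
                                     seed = cfg$seed)
  f4 <- file.path(out, "community_diversity.csv")
  write_change_tests(comm, f4)
  files <- c(f1, f2, f3, f4)
  if (!is.null(cfg$groups)) {
    grp <- summarize_by_group(tests, unlist(cfg$groups))
    f5 <- file.path(out, "group_summary.csv")
    utils::write.csv(grp, f5, row.names = FALSE)
    files <- c(files, f5)
  }
  files
}

stage_report <- function(cfg) {
  out <- cfg$out_dir
  mans <- list.files(out, pattern = "^manifest_.*\\.json$", full.names = TRUE)
  mans <- mans[!grepl("manifest_report", mans)]
  report <- lapply(mans, function(f)
    jsonlite::read_json(f, simplifyVector = TRUE))
  f <- file.path(out, "run_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       na = "null")
  f
}
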