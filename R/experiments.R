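#' Coefficient and characteristic-scale recovery experiment
#'
#' Simulation study of the full survey-to-model pipeline: a spatially
#' autocorrelated landscape is generated once, detection surveys are drawn
#' repeatedly from a known logistic truth at a known characteristic radius,
#' and each replicate is refitted. Two things are scored per replicate:
#' whether each coefficient of the generating model, refitted with the true
#' terms at the true scale, falls within 3 standard errors of truth; and
#' the characteristic scale selected by the full VIF + stepwise-AIC +
#' scale-selection pipeline.
#'
#' The default truth mirrors a conifer/shrub associate with intercept
#' -4.41 and slopes 0.04 (conifer) and 0.06 (shrub) per percentage point at
#' a 1250 m radius — magnitudes typical of the fitted models this package
#' is designed around.
#'
#' @param n_sites sites per replicate (default 500).
#' @param n_replicates number of survey replicates (default 200).
#' @param truth a `species_truth`; defaults as described above.
#' @param radii candidate radius grid (default 250--4500 by 250).
#' @param k sampling units per site (default 9).
#' @param seed integer seed governing landscape, sites and all replicates.
#' @param shape,cell_size,autocorr_length landscape geometry: grid
#'   dimensions, cell edge (meters) and smoothing half-width (cells).
#' @param composition named target composition of the landscape.
#' @return List with `coef_coverage` (per-coefficient fraction of
#'   replicates within 3 SE), `scale_within_one_step` (fraction with
#'   selected scale within one radius increment of truth),
#'   `scale_exact` (fraction selecting the true radius), `scales` (selected
#'   scale per replicate), `estimates` (replicate x coefficient matrix) and
#'   `truth`.
#' @export
recovery_experiment <- function(n_sites = 500, n_replicates = 200,
                                truth = NULL,
                                radii = seq(250, 4500, by = 250),
                                k = 9, seed = 1,
                                shape = c(200, 200), cell_size = 250,
                                autocorr_length = 6,
                                composition = c("coniferous forest" = 0.40,
                                                "shrubs" = 0.15,
                                                "herbaceous" = 0.20,
                                                "wetland" = 0.10,
                                                "barren land" = 0.15)) {
  scheme <- default_scheme()
  if (is.null(truth))
    truth <- species_truth("synthetic conifer associate", 1250,
                           c("coniferous forest" = 0.04, "shrubs" = 0.06),
                           intercept = -4.41)
  land <- generate_landscape(scheme, shape, composition,
                             autocorr_length = autocorr_length, seed = seed,
                             cell_size = cell_size)
  ext_x <- ncol(land$labels) * cell_size
  ext_y <- nrow(land$labels) * cell_size
  margin <- min(max(radii), ext_x / 4, ext_y / 4)
  sites <- with_seed(seed + 1, function()
    data.frame(site_id = sprintf("s%04d", seq_len(n_sites)),
               x = stats::runif(n_sites, margin, ext_x - margin),
               y = stats::runif(n_sites, land$origin[2] - ext_y + margin,
                                land$origin[2] - margin)))
  covars <- build_covariate_table(land, sites, radii = radii,
                                  scheme = scheme)
  cats <- attr(covars, "categories")
  true_terms <- names(truth$coefficients)
  at_truth <- covars[covars$radius_m == truth$scale_m, ]
  at_truth <- at_truth[match(sites$site_id, at_truth$site_id), ]
  X_true <- at_truth[true_terms]
  p_true <- stats::plogis(truth$intercept +
                            as.matrix(X_true) %*% truth$coefficients)
  beta_true <- c("(Intercept)" = truth$intercept, truth$coefficients)

  est <- matrix(NA_real_, n_replicates, length(beta_true),
                dimnames = list(NULL, names(beta_true)))
  within3 <- matrix(NA, n_replicates, length(beta_true),
                    dimnames = list(NULL, names(beta_true)))
  scales <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    counts <- with_seed(seed + 1000 + rep_i, function()
      stats::rbinom(n_sites, k, p_true))
    fit <- fit_glm_binomial(counts, k, X_true)
    est[rep_i, ] <- fit$beta[names(beta_true)]
    within3[rep_i, ] <- abs(fit$beta[names(beta_true)] - beta_true) <=
      3 * fit$se[names(beta_true)]
    sel <- select_scale(data.frame(site_id = sites$site_id, count = counts),
                        covars, k = k)
    scales[rep_i] <- sel$scale_m
  }
  step <- if (length(radii) > 1) min(diff(sort(radii))) else 0
  list(coef_coverage = colMeans(within3),
       scale_within_one_step = mean(abs(scales - truth$scale_m) <= step),
       scale_exact = mean(scales == truth$scale_m),
       scales = scales, estimates = est, truth = beta_true)
}

#' End-to-end backcast sign-recovery scenario
#'
#' Builds a synthetic world with a known herbaceous-to-conifer land cover
#' transition, runs the photo accounting and backcast stages with
#' ground-truth species models, and returns the per-species change
#' classifications next to the direction each truth implies (positive
#' conifer association should increase when conifer expands; herbaceous
#' associates should decline). Also returns the zero-change control: the
#' same backcast on pairs with identical historical and modern
#' compositions, whose deltas must be exactly zero.
#'
#' @param n_pairs number of photo pairs (default 20).
#' @param rate herbaceous-to-conifer transition rate (default 0.5).
#' @param seed integer seed.
#' @param shape scene dimensions in pixels (default 120 x 120).
#' @return List with `tests` (a `species_change` table plus column
#'   `expected_direction`), `all_correct` (logical), and
#'   `zero_change_max_abs_delta` (numeric, exact-zero control).
#' @export
sign_recovery_scenario <- function(n_pairs = 20, rate = 0.5, seed = 1,
                                   shape = c(120, 120)) {
  scheme <- default_scheme()
  comp <- c("coniferous forest" = 0.40, "shrubs" = 0.15,
            "herbaceous" = 0.25, "wetland" = 0.10, "barren land" = 0.10)
  transition <- data.frame(from = id_for_name(scheme, "herbaceous"),
                           to = id_for_name(scheme, "coniferous forest"),
                           rate = rate)
  fits <- list(
    conifer_up = coef_fit("conifer associate",
                          c("(Intercept)" = -4.41,
                            "coniferous forest" = 0.04, "shrubs" = 0.06)),
    conifer_up2 = coef_fit("conifer-wetland associate",
                           c("(Intercept)" = -5.0,
                             "coniferous forest" = 0.05, "wetland" = 0.04)),
    herb_down = coef_fit("meadow associate",
                         c("(Intercept)" = -2.0, "herbaceous" = 0.08)),
    herb_down2 = coef_fit("meadow-shrub associate",
                          c("(Intercept)" = -2.5, "herbaceous" = 0.12,
                            "shrubs" = 0.02)))
  expected <- c("increased", "increased", "declined", "declined")
  pairs <- list()
  for (i in seq_len(n_pairs)) {
    scene <- generate_landscape(scheme, shape, comp, autocorr_length = 4,
                                seed = seed + i, cell_size = 100)
    base <- classified_image(scene$labels)
    gp <- generate_photo_pair(base, transition = transition,
                              seed = seed + 500 + i,
                              station_id = sprintf("st%02d", i))
    pairs[[gp$pair$station_id]] <- list(
      hist = composition(base, scheme),
      mod = composition(gp$pair$modern, scheme))
  }
  res <- backcast_pairs(fits, pairs)
  tests <- species_change_test(res, n_boot = 2000, seed = seed)
  tests$expected_direction <- expected[match(tests$species,
    vapply(fits, function(f) f$species, character(1)))]
  zero_pairs <- lapply(pairs, function(p) list(hist = p$hist, mod = p$hist))
  zero_res <- backcast_pairs(fits, zero_pairs)
  list(tests = tests,
       all_correct = all(tests$classification == tests$expected_direction),
       zero_change_max_abs_delta = max(abs(zero_res$delta)))
}

# a bare coefficient-only fit (same shape read_coefficient_table produces)
coef_fit <- function(species, beta, se = NULL, scale_m = NA_real_) {
  if (is.null(se)) se <- stats::setNames(rep(0, length(beta)), names(beta))
  structure(list(species = species, scale_m = scale_m,
                 terms = setdiff(names(beta), "(Intercept)"),
                 beta = beta, se = se, t_values = beta / se,
                 p_values = rep(NA_real_, length(beta)),
                 aic = NA_real_, loglik = NA_real_, deviance = NA_real_,
                 df_residual = NA_integer_, n_sites = NA_integer_,
                 k = NA_integer_,
                 diagnostics = list(converged = NA, iterations = NA,
                                    separation = NA, dispersion = NA,
                                    degenerate_terms = character(0),
                                    validated = NA, reasons = character(0))),
            class = "sdm_fit")
}

#' Reproduce the headline change analysis from a deposited-data directory
#'
#' Given a directory holding the study's deposited classifications —
#' `<station>_hist.png` / `<station>_mod.png` aligned label masks for each
#' photo station and a `coefficients.csv` coefficient table (columns
#' `species`, `scale_m`, `term`, `beta`, `se`) — recomputes the land cover
#' change tests, mean Shannon diversity per epoch, the per-species
#' occurrence change classifications and the sensitivity
#' direction-consistency count.
#'
#' @param dir directory containing the deposited masks and coefficient
#'   table.
#' @param scheme the `landcover_scheme` of the masks.
#' @param n_boot,seed bootstrap settings.
#' @return List with `landcover` (a `change_tests` table), `shannon_hist`
#'   and `shannon_mod` (means across pairs), `species` (a `species_change`
#'   table), `n_increased`, `n_declined`, `n_unchanged`, and
#'   `n_direction_consistent` from the sensitivity analysis.
#' @export
reproduce_deposited <- function(dir, scheme = default_scheme(),
                                n_boot = 10000, seed = 1) {
  if (!dir.exists(dir)) stop("deposited-data directory not found: ", dir)
  stations <- sort(unique(sub("_hist\\.png$", "",
    basename(list.files(dir, pattern = "_hist\\.png$")))))
  if (!length(stations)) stop("no *_hist.png masks found in ", dir)
  pairs <- lapply(stations, function(id) {
    list(hist = composition(read_mask_png(file.path(dir, paste0(id, "_hist.png"))),
                            scheme),
         mod = composition(read_mask_png(file.path(dir, paste0(id, "_mod.png"))),
                           scheme))
  })
  names(pairs) <- stations
  landcover <- paired_change(pairs, n_boot = n_boot, seed = seed)
  fits <- read_coefficient_table(file.path(dir, "coefficients.csv"))
  res <- backcast_pairs(fits, pairs)
  species <- species_change_test(res, n_boot = n_boot, seed = seed)
  sens <- sensitivity_analysis(fits, pairs)
  list(landcover = landcover,
       shannon_hist = mean(vapply(pairs, function(p)
         shannon_index(p$hist), numeric(1))),
       shannon_mod = mean(vapply(pairs, function(p)
         shannon_index(p$mod), numeric(1))),
       species = species,
       n_increased = sum(species$classification == "increased"),
       n_declined = sum(species$classification == "declined"),
       n_unchanged = sum(species$classification == "no substantial change"),
       n_direction_consistent = sum(sensitivity_consistency(sens)))
}

sensitivity_consistency <- function(sens) {
  tapply(sens$consistent, sens$species, all)
}
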