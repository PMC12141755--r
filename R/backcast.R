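#' Predict occurrence probability from a composition
#'
#' Back-transforms a fitted model from the log-odds scale to a probability:
#' `P = plogis(intercept + sum_j beta_j * x_j)` with `x_j` the percent cover
#' of term `j` in the composition. Categories missing from the composition
#' contribute 0%.
#'
#' @param fit an `sdm_fit` (from [fit_glm_binomial()], [select_scale()] or
#'   [read_coefficient_table()]).
#' @param comp a `composition_vector` (values in percent).
#' @return Occurrence probability in `(0, 1)`.
#' @export
predict_occurrence <- function(fit, comp) {
  beta <- fit$beta
  terms <- setdiff(names(beta), "(Intercept)")
  x <- as.numeric(comp)[match(terms, names(comp))]
  x[is.na(x)] <- 0
  if (any(x < 0 | x > 100))
    stop("composition percentages must lie in [0, 100]")
  if (anyNA(beta[terms]))
    stop("fit carries NA coefficients for: ",
         paste(terms[is.na(beta[terms])], collapse = ", "))
  stats::plogis(unname(beta["(Intercept)"]) + sum(beta[terms] * x))
}

#' Backcast occurrence probabilities over photo pairs
#'
#' Applies each validated species model to the historical and modern land
#' cover composition of every photo pair, yielding per-pair past and
#' current occurrence probabilities and their difference
#' `delta = P_mod - P_hist`. Fits that failed validation are excluded with
#' a message.
#'
#' @param fits list of `sdm_fit`s (fits whose `diagnostics$validated` is
#'   `FALSE` are skipped; `NA`, e.g. for coefficient-table fits, counts as
#'   usable).
#' @param pairs named list; each element a list `(hist, mod)` of
#'   `composition_vector`s for one photo station. Element names are used as
#'   station ids.
#' @return Data frame of class `backcast_results`: `species`, `station_id`,
#'   `p_hist`, `p_mod`, `delta`.
#' @export
backcast_pairs <- function(fits, pairs) {
  if (!length(pairs)) stop("at least one photo pair is required")
  usable <- vapply(fits, function(f) !isFALSE(f$diagnostics$validated),
                   logical(1))
  if (!any(usable)) stop("no validated fits to backcast")
  skipped <- vapply(fits[!usable], function(f)
    if (is.null(f$species)) "<unnamed>" else f$species, character(1))
  if (length(skipped))
    message("excluding unvalidated species: ", paste(skipped, collapse = ", "))
  ids <- names(pairs)
  if (is.null(ids)) ids <- as.character(seq_along(pairs))
  rows <- lapply(fits[usable], function(f) {
    ph <- vapply(pairs, function(p) predict_occurrence(f, p[[1]]), numeric(1))
    pm <- vapply(pairs, function(p) predict_occurrence(f, p[[2]]), numeric(1))
    data.frame(species = f$species, station_id = ids,
               p_hist = unname(ph), p_mod = unname(pm),
               delta = unname(pm - ph), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("backcast_results", "data.frame")
  out
}

#' Per-species occurrence change tests
#'
#' For every species in a backcast, runs a two-sided Wilcoxon signed-rank
#' test on the paired past and current occurrence probabilities across
#' photo stations, reports the mean change with a bootstrap percentile
#' confidence interval over pairs, and classifies the species as
#' `"increased"` (CI entirely above 0), `"declined"` (entirely below 0) or
#' `"no substantial change"`.
#'
#' @param results a `backcast_results` data frame.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf_level CI level (default 0.95).
#' @param seed bootstrap seed.
#' @return Data frame of class `species_change`: `species`, `n_pairs`,
#'   `mean_p_hist`, `mean_p_mod`, `mean_delta`, `statistic`, `p_value`,
#'   `ci_low`, `ci_high`, `classification`, `note`.
#' @export
species_change_test <- function(results, n_boot = 10000, conf_level = 0.95,
                                seed = NULL) {
  sp <- unique(results$species)
  rows <- lapply(sp, function(s) {
    r <- results[results$species == s, ]
    if (nrow(r) < 2) stop("at least 2 pairs are required per species")
    d <- r$delta
    if (all(d == 0)) {
      w <- list(statistic = NA_real_, p_value = NA_real_)
      note <- "undefined: all differences zero"
    } else {
      w <- wilcoxon_signed_rank(r$p_hist, r$p_mod)
      note <- ""
    }
    ci <- bootstrap_mean_ci(d, n_boot, conf_level, seed)
    cls <- if (all(d == 0)) "no substantial change"
           else if (ci[1] > 0) "increased"
           else if (ci[2] < 0) "declined"
           else "no substantial change"
    data.frame(species = s, n_pairs = nrow(r),
               mean_p_hist = mean(r$p_hist), mean_p_mod = mean(r$p_mod),
               mean_delta = mean(d), statistic = w$statistic,
               p_value = w$p_value, ci_low = ci[1], ci_high = ci[2],
               classification = cls, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_change", "data.frame")
  out
}

#' Coefficient-perturbation sensitivity analysis
#'
#' Re-runs the backcast under three scenarios per species: every
#' coefficient (including the intercept) shifted simultaneously to
#' `beta - se`, left at `beta`, and shifted to `beta + se`. The sign of the
#' mean occurrence change under each scenario is recorded; a species is
#' direction-consistent when all three signs agree. A one-at-a-time mode
#' perturbs a single coefficient per scenario instead.
#'
#' @param fits list of `sdm_fit`s carrying standard errors.
#' @param pairs photo-pair compositions as in [backcast_pairs()].
#' @param mode `"simultaneous"` (default) or `"one-at-a-time"`.
#' @return Data frame of class `sensitivity_results`: `species`,
#'   `dir_lower`, `dir_central`, `dir_upper` (each in -1/0/+1),
#'   `consistent`. In one-at-a-time mode, one row per species and perturbed
#'   term (column `term`), with `consistent` summarizing all scenarios of
#'   that species.
#' @export
sensitivity_analysis <- function(fits, pairs,
                                 mode = c("simultaneous", "one-at-a-time")) {
  mode <- match.arg(mode)
  shift_fit <- function(f, shift) { f$beta <- f$beta + shift; f }
  mean_delta_sign <- function(f) {
    res <- backcast_pairs(list(f), pairs)
    sign(mean(res$delta))
  }
  rows <- lapply(fits, function(f) {
    if (anyNA(f$se))
      stop("fit for ", f$species, " is missing standard errors")
    if (mode == "simultaneous") {
      dirs <- vapply(c(-1, 0, 1), function(s)
        mean_delta_sign(shift_fit(f, s * f$se)), numeric(1))
      data.frame(species = f$species, dir_lower = dirs[1],
                 dir_central = dirs[2], dir_upper = dirs[3],
                 consistent = length(unique(dirs)) == 1,
                 stringsAsFactors = FALSE)
    } else {
      per_term <- lapply(names(f$beta), function(tm) {
        dirs <- vapply(c(-1, 0, 1), function(s) {
          shift <- stats::setNames(rep(0, length(f$beta)), names(f$beta))
          shift[tm] <- s * f$se[tm]
          mean_delta_sign(shift_fit(f, shift))
        }, numeric(1))
        data.frame(species = f$species, term = tm, dir_lower = dirs[1],
                   dir_central = dirs[2], dir_upper = dirs[3],
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, per_term)
      tab$consistent <- length(unique(unlist(
        tab[c("dir_lower", "dir_central", "dir_upper")]))) == 1
      tab
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_results", "data.frame")
  out
}

#' Community diversity change from backcast probabilities
#'
#' Summarizes the modeled bird community per photo pair and epoch in two
#' ways: (a) Shannon diversity of the renormalized occurrence probabilities
#' `q_s = P_s / sum(P)` across species, treating relative occurrence
#' probability as a proportional abundance; and (b) expected species
#' richness `sum(P_s)`. Each summary is compared between epochs with a
#' paired Wilcoxon signed-rank test and a bootstrap CI on the mean change.
#'
#' @param results a `backcast_results` data frame covering `>= 2` species.
#' @param n_boot,conf_level,seed bootstrap settings as in
#'   [species_change_test()].
#' @return A `change_tests` data frame with rows `community_shannon` and
#'   `expected_richness`.
#' @export
community_diversity_change <- function(results, n_boot = 10000,
                                       conf_level = 0.95, seed = NULL) {
  if (length(unique(results$species)) < 2)
    stop("community diversity requires at least 2 species")
  stations <- unique(results$station_id)
  shannon_p <- function(p) {
    tot <- sum(p)
    if (tot <= 0) stop("all occurrence probabilities are zero in a pair")
    q <- p[p > 0] / tot
    -sum(q * log(q))
  }
  per_station <- lapply(stations, function(st) {
    r <- results[results$station_id == st, ]
    c(h_hist = shannon_p(r$p_hist), h_mod = shannon_p(r$p_mod),
      rich_hist = sum(r$p_hist), rich_mod = sum(r$p_mod))
  })
  tab <- do.call(rbind, per_station)
  one_test <- function(before, after, label) {
    d <- after - before
    if (all(d == 0)) {
      w <- list(statistic = NA_real_, p_value = NA_real_)
      note <- "undefined: all differences zero"
    } else {
      w <- wilcoxon_signed_rank(before, after)
      note <- ""
    }
    ci <- bootstrap_mean_ci(d, n_boot, conf_level, seed)
    data.frame(target = label, n_pairs = length(d),
               mean_before = mean(before), se_before = stats::sd(before) / sqrt(length(d)),
               mean_after = mean(after), se_after = stats::sd(after) / sqrt(length(d)),
               mean_change = mean(d), statistic = w$statistic,
               p_value = w$p_value, ci_low = ci[1], ci_high = ci[2],
               note = note, stringsAsFactors = FALSE)
  }
  out <- rbind(one_test(tab[, "h_hist"], tab[, "h_mod"], "community_shannon"),
               one_test(tab[, "rich_hist"], tab[, "rich_mod"],
                        "expected_richness"))
  rownames(out) <- NULL
  class(out) <- c("change_tests", "data.frame")
  out
}

#' Summarize occurrence change by breeding-habitat group
#'
#' Groups per-species change classifications by major breeding habitat
#' (supplied as a lookup, e.g. from a published habitat-group report) and
#' tallies increases, declines and mean change per group.
#'
#' @param tests a `species_change` data frame from [species_change_test()].
#' @param groups named character vector: species name -> group label; must
#'   cover every species in `tests`.
#' @return Data frame: `group`, `n_species`, `n_increased`, `n_declined`,
#'   `n_unchanged`, `mean_delta`, `species`.
#' @export
summarize_by_group <- function(tests, groups) {
  g <- groups[tests$species]
  if (anyNA(g))
    stop("habitat group missing for: ",
         paste(tests$species[is.na(g)], collapse = ", "))
  rows <- lapply(unique(unname(g)), function(lab) {
    t <- tests[g == lab, ]
    data.frame(group = lab, n_species = nrow(t),
               n_increased = sum(t$classification == "increased"),
               n_declined = sum(t$classification == "declined"),
               n_unchanged = sum(t$classification == "no substantial change"),
               mean_delta = mean(t$mean_delta),
               species = paste(t$species, collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load fitted species models from a coefficient table
#'
#' Reads a CSV of published model coefficients — one row per species and
#' term, columns `species`, `scale_m`, `term`, `beta`, `se` — into a list
#' of `sdm_fit`s ready for [backcast_pairs()]. The term `"Intercept"` (or
#' `"(Intercept)"`) names the intercept.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return Named list of `sdm_fit`s (one per species, in file order).
#' @export
read_coefficient_table <- function(path) {
  tab <- if (is.data.frame(path)) path
         else utils::read.csv(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  stopifnot(all(c("species", "scale_m", "term", "beta", "se") %in% names(tab)))
  tab$term[tab$term %in% c("Intercept", "intercept")] <- "(Intercept)"
  fits <- lapply(unique(tab$species), function(s) {
    r <- tab[tab$species == s, ]
    if (!"(Intercept)" %in% r$term)
      stop("no intercept row for species ", s)
    beta <- stats::setNames(r$beta, r$term)
    se <- stats::setNames(r$se, r$term)
    ord <- c("(Intercept)", setdiff(names(beta), "(Intercept)"))
    structure(list(species = s, scale_m = unique(r$scale_m)[1],
                   terms = setdiff(ord, "(Intercept)"),
                   beta = beta[ord], se = se[ord],
                   t_values = (beta / se)[ord],
                   p_values = 2 * stats::pnorm(-abs(beta / se))[ord],
                   aic = NA_real_, loglik = NA_real_,
                   deviance = NA_real_, df_residual = NA_integer_,
                   n_sites = NA_integer_, k = NA_integer_,
                   diagnostics = list(converged = NA, iterations = NA,
                                      separation = NA, dispersion = NA,
                                      degenerate_terms = character(0),
                                      validated = NA,
                                      reasons = character(0))),
              class = "sdm_fit")
  })
  stats::setNames(fits, unique(tab$species))
}
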