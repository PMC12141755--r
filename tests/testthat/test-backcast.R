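canada_jay <- function() {
  make_coef_fit("Canada Jay",
                c("(Intercept)" = -4.42, "coniferous forest" = 0.04,
                  "shrubs" = 0.06),
                se = c(0.83, 0.01, 0.03))
}

comp_cf_sh <- function(cf, sh) {
  composition_vector(c("coniferous forest" = cf, "shrubs" = sh,
                       "herbaceous" = 100 - cf - sh), 1000)
}

test_that("logistic back-transform reproduces the worked equation", {
  jay <- canada_jay()
  expect_equal(predict_occurrence(jay, comp_cf_sh(0, 0)),
               1 / (1 + exp(4.42)), tolerance = 1e-12)
  expect_equal(round(predict_occurrence(jay, comp_cf_sh(0, 0)), 4), 0.0119)
  expect_equal(predict_occurrence(jay, comp_cf_sh(100, 0)),
               1 / (1 + exp(0.42)), tolerance = 1e-12)
  expect_equal(round(predict_occurrence(jay, comp_cf_sh(100, 0)), 4), 0.3965)
  expect_equal(predict_occurrence(jay, comp_cf_sh(50, 10)),
               plogis(-4.42 + 0.04 * 50 + 0.06 * 10), tolerance = 1e-12)
})

test_that("categories absent from the composition contribute zero percent", {
  jay <- canada_jay()
  only_herb <- composition_vector(c(herbaceous = 100), 10)
  expect_equal(predict_occurrence(jay, only_herb), 1 / (1 + exp(4.42)),
               tolerance = 1e-12)
})

test_that("predictions stay strictly inside (0, 1)", {
  withr::with_seed(3, {
    for (i in 1:20) {
      beta <- setNames(c(rnorm(1, 0, 3), rnorm(2, 0, 0.1)),
                       c("(Intercept)", "coniferous forest", "shrubs"))
      fit <- make_coef_fit("x", beta)
      p <- predict_occurrence(fit, comp_cf_sh(runif(1, 0, 60),
                                              runif(1, 0, 40)))
      expect_true(p > 0 && p < 1)
    }
  })
})

test_that("zero land cover change backcasts to exactly zero delta", {
  jay <- canada_jay()
  pairs <- list(st1 = list(hist = comp_cf_sh(40, 10),
                           mod = comp_cf_sh(40, 10)),
                st2 = list(hist = comp_cf_sh(20, 5),
                           mod = comp_cf_sh(20, 5)))
  res <- backcast_pairs(list(jay), pairs)
  expect_equal(res$delta, c(0, 0))
  expect_equal(nrow(res), 2)
})

test_that("rising conifer raises occurrence for positive conifer effects", {
  jay <- canada_jay()
  pairs <- lapply(1:5, function(i)
    list(hist = comp_cf_sh(30 + i, 10), mod = comp_cf_sh(40 + i, 10)))
  names(pairs) <- paste0("st", 1:5)
  res <- backcast_pairs(list(jay), pairs)
  expect_true(all(res$delta > 0))
})

test_that("unvalidated fits are excluded, and none left is an error", {
  jay <- canada_jay()
  bad <- canada_jay()
  bad$species <- "Broken"
  bad$diagnostics$validated <- FALSE
  pairs <- list(st1 = list(hist = comp_cf_sh(40, 10),
                           mod = comp_cf_sh(50, 10)))
  expect_message(res <- backcast_pairs(list(jay, bad), pairs), "Broken")
  expect_equal(unique(res$species), "Canada Jay")
  expect_error(suppressMessages(backcast_pairs(list(bad), pairs)),
               "no validated fits")
})

test_that("species change tests classify by bootstrap CI", {
  jay <- canada_jay()
  up <- lapply(1:8, function(i)
    list(hist = comp_cf_sh(30 + i, 10), mod = comp_cf_sh(45 + i, 10)))
  names(up) <- paste0("st", 1:8)
  res <- backcast_pairs(list(jay), up)
  tests <- species_change_test(res, n_boot = 500, seed = 1)
  expect_equal(tests$classification, "increased")
  expect_true(tests$ci_low <= tests$mean_delta &
                tests$mean_delta <= tests$ci_high)
  # flat pairs are an explicit non-result
  flat <- lapply(up, function(p) list(hist = p$hist, mod = p$hist))
  tests0 <- species_change_test(backcast_pairs(list(jay), flat),
                                n_boot = 100, seed = 1)
  expect_equal(tests0$classification, "no substantial change")
  expect_equal(tests0$note, "undefined: all differences zero")
})

test_that("classification is stable across bootstrap seeds", {
  jay <- canada_jay()
  up <- lapply(1:10, function(i)
    list(hist = comp_cf_sh(30 + i, 10), mod = comp_cf_sh(42 + i, 10)))
  names(up) <- paste0("st", 1:10)
  res <- backcast_pairs(list(jay), up)
  cls <- vapply(c(1, 99, 12345), function(s)
    species_change_test(res, n_boot = 500, seed = s)$classification,
    character(1))
  expect_equal(length(unique(cls)), 1)
})

test_that("sensitivity scenarios bracket and agree when SEs vanish", {
  sure <- make_coef_fit("sure",
                        c("(Intercept)" = -4, "coniferous forest" = 0.05),
                        se = c(0, 0))
  pairs <- lapply(1:4, function(i)
    list(hist = comp_cf_sh(30, 10), mod = comp_cf_sh(50, 10)))
  names(pairs) <- paste0("st", 1:4)
  sens <- sensitivity_analysis(list(sure), pairs)
  expect_true(sens$consistent)
  expect_equal(sens$dir_lower, sens$dir_upper)

  jay <- canada_jay()
  comp <- comp_cf_sh(40, 10)
  shift <- function(s) {
    f <- jay; f$beta <- f$beta + s * f$se
    predict_occurrence(f, comp)
  }
  # percents are non-negative, so P is monotone in the shifted coefficients
  expect_lt(shift(-1), shift(0))
  expect_lt(shift(0), shift(1))
})

test_that("sensitivity requires standard errors and offers one-at-a-time", {
  nose <- make_coef_fit("no se", c("(Intercept)" = -1))
  nose$se[] <- NA_real_
  pairs <- list(st1 = list(hist = comp_cf_sh(30, 10),
                           mod = comp_cf_sh(50, 10)))
  expect_error(sensitivity_analysis(list(nose), pairs), "standard errors")
  jay <- canada_jay()
  one <- sensitivity_analysis(list(jay), c(pairs, list(st2 = pairs$st1)),
                              mode = "one-at-a-time")
  expect_equal(nrow(one), 3)  # intercept + 2 terms
  expect_true(all(one$consistent))
})

test_that("community Shannon behaves like a diversity index", {
  two <- list(make_coef_fit("a", c("(Intercept)" = 0)),
              make_coef_fit("b", c("(Intercept)" = 0)))
  pairs <- list(st1 = list(hist = comp_cf_sh(40, 10),
                           mod = comp_cf_sh(40, 10)),
                st2 = list(hist = comp_cf_sh(30, 10),
                           mod = comp_cf_sh(30, 10)))
  res <- backcast_pairs(two, pairs)
  out <- community_diversity_change(res, n_boot = 100, seed = 1)
  sh <- out[out$target == "community_shannon", ]
  # both species at P = 0.5: evenness is maximal, no change across epochs
  expect_equal(sh$mean_before, log(2), tolerance = 1e-12)
  expect_equal(sh$mean_change, 0)
  rich <- out[out$target == "expected_richness", ]
  expect_equal(rich$mean_before, 1, tolerance = 1e-12)

  # concentrating relative probability mass lowers H
  conc <- data.frame(species = rep(c("a", "b"), each = 2),
                     station_id = rep(c("s1", "s2"), 2),
                     p_hist = c(0.5, 0.5, 0.5, 0.5),
                     p_mod = c(0.9, 0.9, 0.1, 0.1))
  conc$delta <- conc$p_mod - conc$p_hist
  class(conc) <- c("backcast_results", "data.frame")
  out2 <- community_diversity_change(conc, n_boot = 100, seed = 1)
  expect_lt(out2$mean_change[out2$target == "community_shannon"], 0)
})

test_that("group summaries partition the species totals", {
  jay <- canada_jay()
  pipit <- make_coef_fit("Pipit", c("(Intercept)" = 0, "herbaceous" = 0.08),
                         se = c(0.1, 0.01))
  pairs <- lapply(1:6, function(i)
    list(hist = composition_vector(c("coniferous forest" = 30, shrubs = 10,
                                     herbaceous = 30, wetland = 30), 100),
         mod = composition_vector(c("coniferous forest" = 45, shrubs = 10,
                                    herbaceous = 15, wetland = 30), 100)))
  names(pairs) <- paste0("st", 1:6)
  tests <- species_change_test(backcast_pairs(list(jay, pipit), pairs),
                               n_boot = 200, seed = 1)
  groups <- c("Canada Jay" = "forest", "Pipit" = "alpine")
  grp <- summarize_by_group(tests, groups)
  expect_equal(sum(grp$n_species), nrow(tests))
  expect_equal(sum(grp$n_increased),
               sum(tests$classification == "increased"))
  expect_gt(grp$mean_delta[grp$group == "forest"], 0)
  expect_lt(grp$mean_delta[grp$group == "alpine"], 0)
  expect_error(summarize_by_group(tests, groups["Canada Jay"]), "missing")
})

test_that("the published coefficient table loads into usable fits", {
  path <- system.file("extdata", "songbird_coefficients.csv",
                      package = "photobackcast")
  fits <- read_coefficient_table(path)
  expect_length(fits, 15)
  jay <- fits[["Canada Jay"]]
  expect_equal(jay$scale_m, 1250)
  expect_equal(unname(jay$beta["(Intercept)"]), -4.41)
  expect_equal(unname(jay$beta["coniferous forest"]), 0.04)
  expect_equal(unname(jay$se["shrubs"]), 0.03)
  # every fit predicts a probability from a generic composition
  comp <- composition_vector(c("coniferous forest" = 40,
                               "broadleaf forest" = 2, shrubs = 10,
                               herbaceous = 15, wetland = 5,
                               "barren land" = 28), 100)
  for (f in fits) {
    p <- predict_occurrence(f, comp)
    expect_true(p > 0 && p < 1)
  }
})
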