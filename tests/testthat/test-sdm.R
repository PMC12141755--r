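test_that("buffer composition is exact on uniform and single-cell buffers", {
  land <- generate_landscape(scheme10, c(40, 40), c("coniferous forest" = 1),
                             seed = 1)
  b <- buffer_proportions(land, c(2000, 2000), 700, scheme10)
  expect_equal(unname(b["coniferous forest"]), 100)
  expect_equal(sum(b), 100, tolerance = 1e-9)
  expect_equal(attr(b, "truncation"), 0)
  # radius under half a cell at a cell center selects that cell alone
  land$labels[20, 20] <- 6L   # center at (1950, 2050)
  b1 <- buffer_proportions(land, c(1950, 2050), 40, scheme10)
  expect_equal(unname(b1["herbaceous"]), 100)
  expect_equal(attr(b1, "n_valid"), 1L)
})

test_that("checkerboard buffers split 50/50 within discretization error", {
  labs <- matrix(ifelse((row(matrix(0, 100, 100)) +
                           col(matrix(0, 100, 100))) %% 2 == 0, 1L, 6L),
                 100, 100)
  land <- raster_map(labs, cell_size = 1, origin = c(0, 100))
  b <- buffer_proportions(land, c(50, 50), 50, scheme10)
  expect_lt(abs(b["coniferous forest"] - 50), 2)
  expect_lt(abs(b["herbaceous"] - 50), 2)
})

test_that("points outside the raster and empty buffers error", {
  land <- generate_landscape(scheme10, c(10, 10), c("coniferous forest" = 1),
                             seed = 1)
  expect_error(buffer_proportions(land, c(-50, 500), 100, scheme10),
               "outside")
})

test_that("covariate table covers the site-by-radius grid and closes to 100", {
  land <- generate_landscape(scheme10, c(60, 60),
                             c("coniferous forest" = 0.5, "herbaceous" = 0.5),
                             autocorr_length = 3, seed = 2)
  sites <- data.frame(site_id = c("a", "b", "c"),
                      x = c(2000, 3000, 4000), y = c(2000, 3000, 4000))
  radii <- seq(250, 1500, by = 250)
  tab <- build_covariate_table(land, sites, radii, scheme10)
  expect_equal(nrow(tab), length(radii) * 3)
  cats <- attr(tab, "categories")
  expect_equal(unname(rowSums(tab[cats])), rep(100, nrow(tab)),
               tolerance = 1e-9)
})

test_that("a conifer disc dilutes monotonically once the radius passes it", {
  labs <- matrix(6L, 81, 81)
  ctr <- c(41, 41)
  for (r in 1:81) for (c in 1:81)
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 10^2) labs[r, c] <- 1L
  land <- raster_map(labs, cell_size = 100, origin = c(0, 8100))
  pt <- c((ctr[2] - 0.5) * 100, 8100 - (ctr[1] - 0.5) * 100)
  radii <- seq(1000, 4000, by = 500)
  conif <- vapply(radii, function(r)
    buffer_proportions(land, pt, r, scheme10)["coniferous forest"],
    numeric(1))
  expect_true(all(diff(conif) <= 1e-9))
})

test_that("VIF screening matches the closed form and drops collinear copies", {
  withr::with_seed(7, {
    x1 <- rnorm(500); x2 <- rnorm(500)
    ortho <- vif_screen(data.frame(x1 = x1, x2 = x2))
    expect_true(all(abs(ortho$vif - 1) < 0.05))
    expect_setequal(ortho$retained, c("x1", "x2"))

    r <- 0.95
    x3 <- r * x1 + sqrt(1 - r^2) * rnorm(500)
    cor95 <- vif_screen(data.frame(x1 = x1, x3 = x3))
    expect_equal(max(cor95$history[[1]]), 1 / (1 - r^2), tolerance = 0.3)
    expect_length(cor95$retained, 1)

    dup <- vif_screen(data.frame(x1 = x1, x2 = x2, x1copy = x1))
    expect_true(is.infinite(max(dup$history[[1]])))
    expect_length(intersect(dup$retained, c("x1", "x1copy")), 1)
  })
})

test_that("intercept-only binomial fit has the closed-form solution", {
  fit <- fit_glm_binomial(c(rep(5, 9), 0), k = 9, covariates = NULL)
  expect_equal(unname(fit$beta["(Intercept)"]), qlogis(45 / 90),
               tolerance = 1e-8)
})

test_that("IRLS agrees with stats::glm on random instances", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(30:80, 1)
      x1 <- runif(n, 0, 100); x2 <- runif(n, 0, 100)
      y <- rbinom(n, 9, plogis(-2 + 0.03 * x1 - 0.02 * x2))
      mine <- fit_glm_binomial(y, 9, data.frame(x1 = x1, x2 = x2))
      ref <- glm(cbind(y, 9 - y) ~ x1 + x2, family = binomial,
                 control = glm.control(epsilon = 1e-12))
      expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(mine$se),
                   unname(summary(ref)$coefficients[, 2]), tolerance = 1e-6)
      expect_equal(mine$aic, AIC(ref), tolerance = 1e-6)
      expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    }
  })
})

test_that("quasi-separation and degenerate designs are flagged", {
  x <- c(rep(0, 10), rep(100, 10))
  y <- c(rep(0, 10), rep(9, 10))
  fit <- fit_glm_binomial(y, 9, data.frame(x = x))
  expect_true(fit$diagnostics$separation)
  expect_false(validate_model(fit)$diagnostics$validated)

  const <- data.frame(x = rnorm(20), z = rep(5, 20))
  withr::with_seed(2, y2 <- rbinom(20, 9, 0.4))
  fit2 <- fit_glm_binomial(y2, 9, const)
  expect_true("z" %in% fit2$diagnostics$degenerate_terms)
  expect_true(is.na(fit2$beta["z"]))
  v <- validate_model(fit2)
  expect_false(v$diagnostics$validated)
  expect_true("degenerate design" %in% v$diagnostics$reasons)
})

test_that("invalid responses and designs are rejected", {
  expect_error(fit_glm_binomial(c(1, 2), k = 0, NULL), "positive")
  expect_error(fit_glm_binomial(c(10, 2), k = 9, NULL), "\\[0, k\\]")
  x <- rnorm(20)
  expect_error(fit_glm_binomial(rbinom(20, 9, 0.5), 9,
                                data.frame(a = x, b = 2 * x)),
               "rank-deficient")
})

test_that("a well-specified simulated fit validates with dispersion near 1", {
  withr::with_seed(19, {
    x <- runif(400, 0, 100)
    y <- rbinom(400, 9, plogis(-2 + 0.03 * x))
  })
  fit <- validate_model(fit_glm_binomial(y, 9, data.frame(x = x)))
  expect_true(fit$diagnostics$validated)
  expect_lt(abs(fit$diagnostics$dispersion - 1), 0.3)
})

test_that("stepwise AIC keeps real effects, prunes noise, never beats itself", {
  withr::with_seed(37, {
    n <- 500
    X <- data.frame(signal = runif(n, 0, 100), noise1 = runif(n, 0, 100),
                    noise2 = runif(n, 0, 100), noise3 = runif(n, 0, 100))
    y <- rbinom(n, 9, plogis(-3 + 0.04 * X$signal))
  })
  full <- fit_glm_binomial(y, 9, X)
  sel <- stepwise_aic(y, 9, X)
  expect_true("signal" %in% sel$terms)
  expect_lte(sel$aic, full$aic)
  # strong single candidate is retained
  single <- stepwise_aic(y, 9, X["signal"])
  expect_equal(single$terms, "signal")
})

test_that("stepwise is a fixed point when the start model is AIC-minimal", {
  withr::with_seed(41, {
    x <- runif(400, 0, 100)
    y <- rbinom(400, 9, plogis(-3 + 0.05 * x))
  })
  sel <- stepwise_aic(y, 9, data.frame(x = x), start = "x")
  path <- attr(sel, "path")
  expect_equal(nrow(path), 1)
  expect_equal(sel$terms, "x")
})

test_that("a uniform landscape yields a flat profile and the smallest radius", {
  land <- generate_landscape(scheme10, c(80, 80), c("coniferous forest" = 1),
                             seed = 3)
  sites <- data.frame(site_id = sprintf("s%02d", 1:30),
                      x = runif(30, 2000, 6000), y = runif(30, 2000, 6000))
  withr::with_seed(5, counts <- rbinom(30, 9, 0.4))
  radii <- seq(250, 1000, by = 250)
  covars <- build_covariate_table(land, sites, radii, scheme10)
  fit <- select_scale(data.frame(site_id = sites$site_id, count = counts),
                      covars, k = 9)
  prof <- attr(fit, "profile")
  expect_equal(fit$scale_m, 250)
  expect_lt(diff(range(prof$aic)), 1e-6)
})

test_that("the characteristic scale is recovered on simulated surveys", {
  sch <- scheme10
  land <- generate_landscape(sch, c(120, 120),
                             c("coniferous forest" = 0.4, "shrubs" = 0.15,
                               "herbaceous" = 0.25, "wetland" = 0.1,
                               "barren land" = 0.1),
                             autocorr_length = 5, seed = 11, cell_size = 250)
  withr::with_seed(12, {
    sites <- data.frame(site_id = sprintf("s%03d", 1:300),
                        x = runif(300, 5000, 25000),
                        y = runif(300, 5000, 25000))
  })
  truth <- species_truth("jay", 1250,
                         c("coniferous forest" = 0.04, "shrubs" = 0.06),
                         -4.41)
  sv <- simulate_surveys(land, list(truth), sites, seed = 13, scheme = sch)
  covars <- build_covariate_table(land, sites, seq(250, 2500, 250), sch)
  fit <- select_scale(data.frame(site_id = sv$site_id, count = sv$count),
                      covars, k = 9, species = "jay")
  expect_lte(abs(fit$scale_m - 1250), 250)
  expect_equal(fit$species, "jay")
})

test_that("PFA follows (1-p)^k and is monotone in p and k", {
  expect_equal(pfa(0, 9)$pfa, 1)
  expect_equal(pfa(1, 9)$pfa, 0)
  expect_equal(pfa(0.5, 9)$pfa, 0.5^9)
  expect_true(pfa(0.5, 9)$reliable)
  expect_false(pfa(0.05, 9)$reliable)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(pfa(p, 9)$pfa) < 0))
  expect_true(all(vapply(2:10, function(k) pfa(0.3, k)$pfa, numeric(1))
                  == (1 - 0.3)^(2:10)))
  expect_error(pfa(1.2, 9), "\\[0, 1\\]")
})
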