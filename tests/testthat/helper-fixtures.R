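# shared fixtures and independent oracles

scheme10 <- default_scheme()

# random invertible affine with moderate rotation/scale/shear/translation
random_affine <- function() {
  repeat {
    t <- try(affine_transform(a = runif(1, 0.7, 1.3), b = runif(1, -0.3, 0.3),
                              c = runif(1, -0.3, 0.3), d = runif(1, 0.7, 1.3),
                              tx = runif(1, -20, 20), ty = runif(1, -20, 20)),
             silent = TRUE)
    if (!inherits(t, "try-error")) return(t)
  }
}

# brute-force signed-rank oracle: enumerate all 2^n sign assignments
wilcoxon_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  p_low <- mean(Ws <= W)
  p_high <- mean(Ws >= W)
  list(statistic = W, p_value = min(1, 2 * min(p_low, p_high)))
}

# random composition over m named categories, in percent
random_composition <- function(m = 6) {
  x <- rexp(m)
  composition_vector(setNames(100 * x / sum(x), paste0("cat", seq_len(m))),
                     n_valid = 100)
}

# a coefficient-only fit, mirroring what read_coefficient_table() yields
make_coef_fit <- function(species, beta, se = NULL) {
  tab <- data.frame(species = species, scale_m = 1000,
                    term = names(beta), beta = unname(beta),
                    se = if (is.null(se)) 0 else unname(se))
  read_coefficient_table(tab)[[1]]
}

# tiny pipeline configuration rooted in `dir`
small_config <- function(dir, seed = 42) {
  load_config(list(
    seed = seed, out_dir = "out", k = 9,
    radii = list(min = 250, max = 1000, step = 250),
    n_boot = 200, ci_level = 0.95,
    simulate = list(
      landscape = list(rows = 80, cols = 80, cell_size = 100,
                       autocorr_length = 4,
                       composition = list(`coniferous forest` = 0.4,
                                          shrubs = 0.15, herbaceous = 0.25,
                                          wetland = 0.1, `barren land` = 0.1)),
      n_sites = 40, n_pairs = 4, pair_shape = c(60, 60),
      tiepoint_noise_sd = 0,
      transition = list(list(from = "herbaceous",
                             to = "coniferous forest", rate = 0.4)),
      warp = list(angle_deg = 2, scale = 1, tx = 1, ty = -1),
      truths = list(
        list(species = "conifer associate", scale_m = 500, intercept = -4,
             coefficients = list(`coniferous forest` = 0.05, shrubs = 0.05)),
        list(species = "meadow associate", scale_m = 500, intercept = -2.5,
             coefficients = list(herbaceous = 0.08)))),
    groups = list(`conifer associate` = "forest",
                  `meadow associate` = "alpine")),
    base_dir = dir)
}
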