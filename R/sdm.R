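#' Land cover composition within a circular buffer
#'
#' Computes the composition over all raster cells whose centers lie within
#' Euclidean distance `radius_m` of `point` (map units). Cells falling
#' outside the raster are excluded from the denominator (edge-truncated
#' buffer); the fraction of the ideal buffer that was truncated is reported
#' so downstream analyses can filter heavily truncated sites.
#'
#' @param raster a `raster_map`.
#' @param point numeric `(x, y)` in map units; must lie inside the raster.
#' @param radius_m buffer radius in meters, positive.
#' @param scheme a `landcover_scheme` naming the categories.
#' @return A `composition_vector` with additional attribute
#'   `truncation` (fraction of in-radius cell centers outside the raster).
#' @export
buffer_proportions <- function(raster, point, radius_m, scheme) {
  stopifnot(radius_m > 0, length(point) == 2)
  cs <- raster$cell_size
  nr <- nrow(raster$labels); nc <- ncol(raster$labels)
  ox <- raster$origin[1]; oy <- raster$origin[2]
  if (point[1] < ox || point[1] > ox + nc * cs ||
      point[2] > oy || point[2] < oy - nr * cs)
    stop("point lies outside the raster extent")
  # candidate lattice indices whose centers could be within the radius
  cmin <- floor((point[1] - radius_m - ox) / cs + 0.5)
  cmax <- ceiling((point[1] + radius_m - ox) / cs + 0.5)
  rmin <- floor((oy - point[2] - radius_m) / cs + 0.5)
  rmax <- ceiling((oy - point[2] + radius_m) / cs + 0.5)
  cols <- cmin:cmax; rows <- rmin:rmax
  cx <- ox + (cols - 0.5) * cs
  cy <- oy - (rows - 0.5) * cs
  dx2 <- (cx - point[1])^2
  dy2 <- (cy - point[2])^2
  inrad <- outer(dy2, dx2, "+") <= radius_m^2  # rows x cols
  n_ideal <- sum(inrad)
  if (n_ideal == 0) stop("buffer contains no cell centers")
  ingrid <- outer(rows >= 1 & rows <= nr, cols >= 1 & cols <= nc, "&")
  sel <- inrad & ingrid
  if (!any(sel)) stop("buffer contains no cell centers inside the raster")
  ij <- which(sel, arr.ind = TRUE)
  labs <- raster$labels[cbind(rows[ij[, 1]], cols[ij[, 2]])]
  labs <- labs[labs != 255L]  # reserved invalid cells excluded
  if (length(labs) == 0) stop("buffer covers only invalid raster cells")
  counts <- tabulate(match(labs, scheme_ids(scheme)),
                     nbins = nrow(scheme$categories))
  comp <- composition_vector(
    stats::setNames(100 * counts / length(labs), scheme_names(scheme)),
    length(labs))
  attr(comp, "truncation") <- 1 - sum(sel) / n_ideal
  comp
}

#' Buffer covariate table over a site-by-radius grid
#'
#' Extracts [buffer_proportions()] for every site at every radius of the
#' analysis grid (default 250--4500 m in 250-m steps), merging to coarse
#' categories when the scheme carries a merge map. The result is the
#' covariate table behind all multi-scale model fits.
#'
#' @param raster a `raster_map`.
#' @param sites data frame with columns `site_id`, `x`, `y` (map units).
#' @param radii numeric vector of buffer radii in meters.
#' @param scheme a `landcover_scheme`.
#' @return Data frame of class `scaled_covariates`: columns `site_id`,
#'   `radius_m`, `truncation`, then one percent column per category.
#' @export
build_covariate_table <- function(raster, sites,
                                  radii = seq(250, 4500, by = 250),
                                  scheme = default_scheme()) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  rows <- vector("list", nrow(sites) * length(radii))
  i <- 0L
  for (s in seq_len(nrow(sites))) {
    for (r in radii) {
      comp <- buffer_proportions(raster, c(sites$x[s], sites$y[s]), r, scheme)
      if (!is.null(scheme$merge_map)) comp <- merge_categories(comp, scheme)
      i <- i + 1L
      rows[[i]] <- data.frame(site_id = sites$site_id[s], radius_m = r,
                              truncation = attr(comp, "truncation"),
                              as.list(stats::setNames(as.numeric(comp),
                                                      names(comp))),
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "categories") <- setdiff(names(out),
                                     c("site_id", "radius_m", "truncation"))
  class(out) <- c("scaled_covariates", "data.frame")
  out
}

#' Variance inflation factor screening
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary
#' least-squares regression of covariate `j` on all the others (with
#' intercept), then iteratively removes the largest-VIF covariate until all
#' remaining VIFs fall below the threshold. Constant columns and exact
#' collinearity yield infinite VIFs and are removed first; the drop order is
#' recorded.
#'
#' @param covariates data frame or matrix of numeric covariate columns
#'   (at least 2).
#' @param threshold retain only covariates with VIF strictly below this
#'   (default 3).
#' @return List with `retained` (names), `dropped` (names in drop order),
#'   `vif` (final VIFs of retained covariates) and `history` (VIF table at
#'   each elimination step).
#' @export
vif_screen <- function(covariates, threshold = 3) {
  X <- as.data.frame(covariates)
  if (ncol(X) < 2) stop("VIF screening requires at least 2 covariates")
  if (nrow(X) < ncol(X) + 1)
    stop("need more rows than covariates to estimate VIFs")
  dropped <- character(0)
  history <- list()
  repeat {
    vifs <- vapply(names(X), function(j) {
      y <- X[[j]]
      if (stats::sd(y) == 0) return(Inf)
      D <- cbind(1, as.matrix(X[setdiff(names(X), j)]))
      rss <- sum(stats::lm.fit(D, y)$residuals^2)
      tss <- sum((y - mean(y))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    history[[length(history) + 1]] <- vifs
    if (all(vifs < threshold) || ncol(X) == 1) break
    worst <- names(vifs)[which.max(vifs)]
    dropped <- c(dropped, worst)
    X <- X[setdiff(names(X), worst)]
    if (ncol(X) == 1) {
      history[[length(history) + 1]] <-
        stats::setNames(1, names(X))
      break
    }
  }
  final <- history[[length(history)]]
  list(retained = names(final)[final < threshold | length(final) == 1],
       dropped = dropped, vif = final, history = history)
}

#' Fit a binomial (logit link) GLM of detection counts on land cover
#'
#' Maximum-likelihood logistic regression of per-site detection counts out
#' of `k` sampling units on covariate percentages, fitted by iteratively
#' reweighted least squares. Each sampling unit is treated as a Bernoulli
#' trial, so the response per site is `(successes, k - successes)`.
#' Standard errors come from the inverse Fisher information at the optimum;
#' AIC is `-2 loglik + 2 (number of parameters)`. Quasi-separation is
#' flagged when any coefficient magnitude exceeds `separation_bound` or any
#' site's linear predictor runs away (|eta| > 20, i.e., a fitted
#' probability numerically at 0 or 1).
#' Zero-variance covariate columns cannot be estimated alongside the
#' intercept; they are recorded as degenerate terms with `NA` coefficients
#' and fail later validation.
#'
#' @param successes integer vector of detection counts per site, in `[0, k]`.
#' @param k number of sampling units per site (scalar or per-site vector),
#'   all positive.
#' @param covariates data frame of covariate percent columns (one row per
#'   site); may be `NULL` or zero-column for an intercept-only model.
#' @param species optional species label carried into the fit.
#' @param max_iter,tol IRLS iteration cap and relative coefficient-change
#'   tolerance.
#' @param separation_bound coefficient magnitude beyond which
#'   quasi-separation is flagged (default 50).
#' @return An object of class `sdm_fit`: coefficients `beta`, `se`,
#'   `t_values`, `p_values`, `aic`, `loglik`, `deviance`, `df_residual`,
#'   `n_sites`, `k`, `terms`, `scale_m` (`NA` until scale selection) and a
#'   `diagnostics` list (`converged`, `iterations`, `separation`,
#'   `dispersion`, `degenerate_terms`, `validated`, `reasons`).
#' @export
fit_glm_binomial <- function(successes, k, covariates = NULL, species = NULL,
                             max_iter = 100, tol = 1e-10,
                             separation_bound = 50) {
  successes <- as.numeric(successes)
  n <- length(successes)
  m <- rep_len(as.numeric(k), n)
  if (any(m <= 0)) stop("k must be positive for every site")
  if (any(successes < 0 | successes > m))
    stop("counts must lie in [0, k]")
  if (is.null(covariates)) covariates <- data.frame()[seq_len(n), , drop = FALSE]
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) == 0 && ncol(covariates) == 0)
    covariates <- data.frame(row.names = seq_len(n))
  if (nrow(covariates) != n)
    stop("covariates must have one row per site")
  degenerate <- names(covariates)[vapply(covariates, function(x)
    stats::sd(x) == 0, logical(1))]
  active <- setdiff(names(covariates), degenerate)
  X <- cbind("(Intercept)" = 1, as.matrix(covariates[active]))
  p <- ncol(X)
  if (n < p + 1) stop("need at least one more site than parameters")
  if (qr(X)$rank < p) stop("rank-deficient design matrix")

  beta <- rep(0, p)
  beta[1] <- stats::qlogis((sum(successes) + 0.5) / (sum(m) + 1))
  converged <- FALSE; it <- 0
  repeat {
    it <- it + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- m * mu * (1 - mu)
    z <- eta + (successes - m * mu) / w
    sw <- sqrt(w)
    fit <- qr(X * sw)
    beta_new <- qr.coef(fit, z * sw)
    step <- max(abs(beta_new - beta) / (abs(beta) + 0.1))
    beta <- beta_new
    if (step < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  dev <- binomial_deviance(successes, m, mu)
  w <- m * mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  cov_beta <- tryCatch(chol2inv(chol(XtWX)),
                       error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov_beta))
  names(beta) <- names(se) <- colnames(X)
  loglik <- sum(stats::dbinom(successes, m, mu, log = TRUE))
  aic <- -2 * loglik + 2 * p
  # quasi-separation: runaway coefficients, or a data point fit so
  # perfectly that its linear predictor is numerically at 0 or 1
  separation <- any(abs(beta) > separation_bound) || any(abs(eta) > 20)
  df_res <- n - p
  dispersion <- if (df_res > 0) dev / df_res else NA_real_
  if (length(degenerate)) {
    beta <- c(beta, stats::setNames(rep(NA_real_, length(degenerate)),
                                    degenerate))
    se <- c(se, stats::setNames(rep(NA_real_, length(degenerate)),
                                degenerate))
  }
  tval <- beta / se
  structure(list(
    species = species, scale_m = NA_real_,
    terms = c(active, degenerate),
    beta = beta, se = se, t_values = tval,
    p_values = 2 * stats::pnorm(-abs(tval)),
    aic = aic, loglik = loglik, deviance = dev,
    df_residual = df_res, n_sites = n, k = m,
    fitted = mu,
    diagnostics = list(converged = converged, iterations = it,
                       separation = separation, dispersion = dispersion,
                       degenerate_terms = degenerate,
                       validated = NA, reasons = character(0))),
    class = "sdm_fit")
}

binomial_deviance <- function(y, m, mu) {
  # 2 * (saturated loglik - model loglik), with 0 log 0 = 0
  term <- function(obs, fit) ifelse(obs > 0, obs * log(obs / fit), 0)
  2 * sum(term(y, m * mu) + term(m - y, m - m * mu))
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat("Binomial GLM",
      if (!is.null(x$species)) paste0("for ", x$species), "\n")
  if (!is.na(x$scale_m)) cat("  characteristic scale:", x$scale_m, "m\n")
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t_values,
                    p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("  AIC %.2f | loglik %.2f | n = %d | dispersion %.2f\n",
              x$aic, x$loglik, x$n_sites, x$diagnostics$dispersion))
  invisible(x)
}

#' Bidirectional stepwise AIC covariate selection
#'
#' Starting from the model containing `start` (default: all candidates), at
#' each step every single-term deletion and addition is evaluated and the
#' move with the lowest AIC is taken; selection stops when no move lowers
#' the AIC. The intercept is never removed. Ties are broken
#' deterministically: deletion is preferred over addition, then terms are
#' taken in alphabetical order.
#'
#' @param successes,k,covariates,species,... as in [fit_glm_binomial()];
#'   `covariates` must contain every candidate column.
#' @param candidates character vector of candidate term names (default: all
#'   columns of `covariates`).
#' @param start terms of the initial model (default: the full candidate
#'   set).
#' @return The selected `sdm_fit`, with attribute `"path"` logging each
#'   move (`action`, `term`, `aic`).
#' @export
stepwise_aic <- function(successes, k, covariates,
                         candidates = colnames(covariates),
                         start = candidates, species = NULL, ...) {
  covariates <- as.data.frame(covariates)
  current <- sort(start)
  fit <- fit_glm_binomial(successes, k, covariates[current],
                          species = species, ...)
  path <- data.frame(action = "start", term = "", aic = fit$aic,
                     stringsAsFactors = FALSE)
  repeat {
    moves <- list()
    for (tm in sort(intersect(current, candidates)))
      moves[[length(moves) + 1]] <- list(action = "drop", term = tm,
                                         terms = setdiff(current, tm))
    for (tm in sort(setdiff(candidates, current)))
      moves[[length(moves) + 1]] <- list(action = "add", term = tm,
                                         terms = sort(c(current, tm)))
    if (!length(moves)) break
    aics <- vapply(moves, function(mv) {
      f <- tryCatch(fit_glm_binomial(successes, k, covariates[mv$terms],
                                     species = species, ...),
                    error = function(e) NULL)
      if (is.null(f)) Inf else f$aic
    }, numeric(1))
    # deterministic preference: lowest AIC, then deletion, then alphabetical
    kind <- vapply(moves, function(mv) mv$action == "add", logical(1))
    term <- vapply(moves, function(mv) mv$term, character(1))
    ord <- order(aics, kind, term)
    best <- ord[1]
    if (aics[best] >= fit$aic - 1e-8) break
    current <- moves[[best]]$terms
    fit <- fit_glm_binomial(successes, k, covariates[current],
                            species = species, ...)
    path <- rbind(path, data.frame(action = moves[[best]]$action,
                                   term = moves[[best]]$term,
                                   aic = fit$aic, stringsAsFactors = FALSE))
  }
  attr(fit, "path") <- path
  fit
}

#' Select a species' characteristic scale across the radius grid
#'
#' For every radius in the covariate table, screens covariates by VIF, runs
#' bidirectional stepwise AIC from the full screened model, and fits the
#' selected model; the radius whose selected model attains the minimum AIC
#' is the species' characteristic scale of selection. Ties are broken
#' toward the smaller radius. The per-radius AIC profile is retained.
#'
#' @param detections data frame with columns `site_id` and `count`
#'   (detections out of `k`), one row per site.
#' @param covariates a `scaled_covariates` table from
#'   [build_covariate_table()].
#' @param k sampling units per site (default 9).
#' @param species optional species label.
#' @param vif_threshold VIF retention threshold (default 3).
#' @param ... passed to [fit_glm_binomial()].
#' @return The winning `sdm_fit` with `scale_m` set and attribute
#'   `"profile"`: a data frame `(radius_m, aic, n_terms, error)`.
#' @export
select_scale <- function(detections, covariates, k = 9, species = NULL,
                         vif_threshold = 3, ...) {
  stopifnot(all(c("site_id", "count") %in% names(detections)))
  cats <- attr(covariates, "categories")
  radii <- sort(unique(covariates$radius_m))
  fits <- vector("list", length(radii))
  profile <- data.frame(radius_m = radii, aic = NA_real_,
                        n_terms = NA_integer_, error = NA_character_)
  for (i in seq_along(radii)) {
    sub <- covariates[covariates$radius_m == radii[i], ]
    sub <- sub[match(detections$site_id, sub$site_id), ]
    if (anyNA(sub$site_id)) {
      profile$error[i] <- "missing covariate rows for some sites"
      next
    }
    res <- tryCatch({
      X <- sub[cats]
      X <- X[vapply(X, function(x) stats::sd(x) > 0, logical(1))]
      keep <- if (ncol(X) >= 2)
        vif_screen(X, threshold = vif_threshold)$retained else colnames(X)
      stepwise_aic(detections$count, k, X[keep], species = species, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      profile$error[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      profile$aic[i] <- res$aic
      profile$n_terms[i] <- length(res$terms)
    }
  }
  if (all(is.na(profile$aic)))
    stop("species is unmodelable: model fitting failed at every radius")
  best <- which.min(profile$aic)  # first minimum = smaller radius on ties
  fit <- fits[[best]]
  fit$scale_m <- radii[best]
  attr(fit, "profile") <- profile
  fit
}

#' Probability of false absence
#'
#' The probability that a species present at a site goes undetected in all
#' `k` sampling occasions, given per-occasion detection probability `p`:
#' `PFA = (1 - p)^k`. Estimates below `reliable_threshold` are flagged
#' reliable (the study's detectability benchmark was a worst case near
#' 0.15).
#'
#' @param p per-occasion detection probability in `[0, 1]` (vectorized).
#' @param k number of sampling occasions, `>= 1`.
#' @param reliable_threshold PFA below which detection is deemed reliable
#'   (default 0.15).
#' @return List with `p`, `k`, `pfa` and logical `reliable`.
#' @export
pfa <- function(p, k = 9, reliable_threshold = 0.15) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (k < 1) stop("k must be at least 1")
  val <- (1 - p)^k
  list(p = p, k = k, pfa = val, reliable = val < reliable_threshold)
}

#' Validate a fitted species distribution model
#'
#' A fit passes validation when the IRLS converged, no quasi-separation was
#' flagged, the dispersion (residual deviance over residual degrees of
#' freedom) lies within `dispersion_band`, and every term's design column
#' was non-constant. Failure reasons are recorded on the fit.
#'
#' @param fit an `sdm_fit`.
#' @param dispersion_band acceptable dispersion range (default `c(0.3, 3)`).
#' @return The fit with `diagnostics$validated` and
#'   `diagnostics$reasons` filled in.
#' @export
validate_model <- function(fit, dispersion_band = c(0.3, 3)) {
  reasons <- character(0)
  d <- fit$diagnostics
  if (!isTRUE(d$converged)) reasons <- c(reasons, "non-convergence")
  if (isTRUE(d$separation)) reasons <- c(reasons, "separation")
  if (length(d$degenerate_terms)) reasons <- c(reasons, "degenerate design")
  if (is.na(d$dispersion) || d$dispersion < dispersion_band[1] ||
      d$dispersion > dispersion_band[2])
    reasons <- c(reasons, "dispersion outside band")
  fit$diagnostics$validated <- length(reasons) == 0
  fit$diagnostics$reasons <- reasons
  fit
}
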