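#' Ground-truth species-habitat association
#'
#' The generative analogue of a fitted species model: a characteristic
#' radius and log-odds-per-percentage-point coefficients on land cover
#' categories, used to simulate detection surveys with known truth.
#'
#' @param species species label.
#' @param scale_m characteristic buffer radius in meters.
#' @param coefficients named numeric vector: log-odds change per percentage
#'   point of each named category.
#' @param intercept log-odds at 0% of every covariate category.
#' @return An object of class `species_truth`.
#' @export
species_truth <- function(species, scale_m, coefficients, intercept) {
  if (length(coefficients) && (is.null(names(coefficients)) ||
                               any(!nzchar(names(coefficients)))))
    stop("coefficients must be named by category")
  structure(list(species = species, scale_m = scale_m,
                 coefficients = coefficients, intercept = intercept),
            class = "species_truth")
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' Emulates a Landsat-like thematic map: a Gaussian white-noise field is
#' smoothed with a separable boxcar of half-width `autocorr_length` cells
#' (circular boundaries) and the smoothed values are sliced at the
#' composition-matching quantiles, so each category occupies contiguous
#' level sets of a smooth field and the realized pixel fractions match the
#' target composition to within one cell each.
#'
#' @param scheme a `landcover_scheme`.
#' @param shape integer `(rows, cols)` of the grid.
#' @param target_composition named numeric vector of target proportions
#'   (fractions summing to 1) over a subset of the scheme's categories.
#' @param autocorr_length smoothing half-width in cells (`>= 0`; 0 gives
#'   spatially independent labels).
#' @param seed integer seed; the result is reproducible given the seed.
#' @param cell_size cell edge length in meters (default 100).
#' @return A `raster_map` whose origin puts the bottom-left corner at
#'   `(0, 0)`.
#' @export
generate_landscape <- function(scheme, shape, target_composition,
                               autocorr_length = 5, seed = NULL,
                               cell_size = 100) {
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be (rows, cols)")
  if (abs(sum(target_composition) - 1) > 1e-6)
    stop("target_composition must sum to 1")
  if (any(target_composition < 0)) stop("proportions must be non-negative")
  if (autocorr_length < 0) stop("autocorr_length must be >= 0")
  unknown <- setdiff(names(target_composition), scheme_names(scheme))
  if (length(unknown))
    stop("unknown categories in target_composition: ",
         paste(unknown, collapse = ", "))
  nr <- shape[1]; nc <- shape[2]
  field <- with_seed(seed, function() {
    f <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (autocorr_length > 0) {
      w <- 2 * round(autocorr_length) + 1
      w <- min(w, 2 * floor((min(nr, nc) - 1) / 2) + 1)  # fit small grids
      kern <- rep(1 / w, w)
      f <- apply(f, 2, function(col) stats::filter(col, kern, circular = TRUE))
      f <- t(apply(f, 1, function(row) stats::filter(row, kern, circular = TRUE)))
    }
    # infinitesimal deterministic jitter breaks rank ties from smoothing
    f + seq_along(f) * 1e-12
  })
  props <- target_composition[target_composition > 0]
  ids <- id_for_name(scheme, names(props))
  # exact-count assignment: cells ranked by field value, split at the
  # cumulative composition boundaries
  n <- nr * nc
  bounds <- round(cumsum(props) * n)
  bounds[length(bounds)] <- n
  sizes <- diff(c(0, bounds))
  labels <- matrix(rep(ids, sizes)[rank(field, ties.method = "first")],
                   nr, nc)
  raster_map(labels, cell_size = cell_size, origin = c(0, nr * cell_size))
}

#' Simulate detection surveys from ground-truth species models
#'
#' For every site and species, the land cover composition within the
#' species' characteristic radius is extracted with [buffer_proportions()]
#' (in percent), turned into an occurrence probability `P` by the logistic
#' of the truth's linear predictor, and the site's detection count is drawn
#' as `k` independent Bernoulli trials with success probability
#' `P * detection_p`. The default `detection_p = 1` reflects the convention
#' that non-detections are treated as temporary emigration rather than
#' false absences; set `detection_p < 1` to emulate imperfect detectability
#' and exercise [pfa()].
#'
#' @param raster a `raster_map`.
#' @param truths list of `species_truth` objects.
#' @param sites data frame with columns `site_id`, `x`, `y` (map units,
#'   inside the raster).
#' @param k sampling units per site (default 9).
#' @param seed integer seed.
#' @param scheme the `landcover_scheme` of the raster.
#' @param detection_p per-trial detection probability given presence
#'   (default 1).
#' @return Data frame of class `site_surveys`: `site_id`, `x`, `y`,
#'   `species`, `count`, `k`, and the generating probability `p_true`.
#' @export
simulate_surveys <- function(raster, truths, sites, k = 9, seed = NULL,
                             scheme = default_scheme(), detection_p = 1) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  scales <- unique(vapply(truths, function(t) t$scale_m, numeric(1)))
  # buffer composition per site at each distinct characteristic scale
  comp_cache <- lapply(scales, function(r) {
    lapply(seq_len(nrow(sites)), function(s) {
      comp <- buffer_proportions(raster, c(sites$x[s], sites$y[s]), r, scheme)
      if (!is.null(scheme$merge_map)) comp <- merge_categories(comp, scheme)
      comp
    })
  })
  names(comp_cache) <- as.character(scales)
  rows <- list()
  for (tr in truths) {
    comps <- comp_cache[[as.character(tr$scale_m)]]
    p <- vapply(comps, function(cm) {
      x <- as.numeric(cm[names(tr$coefficients)])
      x[is.na(x)] <- 0
      stats::plogis(tr$intercept + sum(tr$coefficients * x))
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      site_id = sites$site_id, x = sites$x, y = sites$y,
      species = tr$species, count = NA_integer_, k = k, p_true = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$count <- with_seed(seed, function()
    stats::rbinom(nrow(out), size = k, prob = out$p_true * detection_p))
  rownames(out) <- NULL
  class(out) <- c("site_surveys", "data.frame")
  out
}

#' Generate a synthetic historical/repeat photo pair with known truth
#'
#' Starting from a classified base image (the "repeat" scene), the modern
#' mask is produced by independently flipping each pixel of every
#' transitioning category to its target category with the given rate, and
#' the historical mask is the base warped by the inverse of `warp` — so
#' `warp` is exactly the registration transform that downstream alignment
#' must recover. Tie points are true correspondences between the two
#' geometries with Gaussian noise of `tiepoint_noise_sd` pixels added to
#' the historical coordinates (emulating digitization error). The realized
#' per-category pixel change is recorded as ground truth.
#'
#' @param base a `classified_image` (repeat-photo geometry).
#' @param transition data frame with columns `from`, `to` (category ids) and
#'   `rate` in `[0, 1]`: each valid pixel of `from` flips to `to`
#'   independently with probability `rate`.
#' @param warp invertible `affine_transform` mapping historical pixel
#'   coordinates onto the repeat grid.
#' @param tiepoint_noise_sd per-coordinate Gaussian noise (pixels) on the
#'   historical tie point coordinates (default 0).
#' @param n_tiepoints number of tie points emitted (default 12).
#' @param seed integer seed.
#' @param station_id identifier carried into the pair.
#' @param invalid_id invalid-pixel sentinel (default 255).
#' @return List with `pair` (a `photo_pair`; historical in its own warped
#'   geometry), `tiepoints` (a `tie_points` set), `warp` (the ground-truth
#'   registration transform), and `change` (data frame `category_id`,
#'   `pixels_before`, `pixels_after`, `change` on the base geometry).
#' @export
generate_photo_pair <- function(base, transition = NULL, warp = NULL,
                                tiepoint_noise_sd = 0, n_tiepoints = 12,
                                seed = NULL, station_id = "synthetic",
                                invalid_id = 255L) {
  if (is.null(warp)) warp <- affine_transform()
  if (!is.null(transition)) {
    stopifnot(all(c("from", "to", "rate") %in% names(transition)))
    if (any(transition$rate < 0 | transition$rate > 1))
      stop("transition rates must lie in [0, 1]")
  }
  modern_labels <- base$labels
  with_seed(seed, function() {
    if (!is.null(transition)) {
      for (i in seq_len(nrow(transition))) {
        idx <- which(modern_labels == transition$from[i] & base$valid)
        if (length(idx)) {
          flip <- stats::runif(length(idx)) < transition$rate[i]
          modern_labels[idx[flip]] <<- as.integer(transition$to[i])
        }
      }
    }
    modern <- classified_image(modern_labels, base$valid)
    historical <- apply_transform(base, invert_transform(warp),
                                  invalid_id = invalid_id)
    # tie points in the interior of the repeat grid; their historical
    # counterparts are the same features under the inverse warp
    nr <- nrow(base$labels); nc <- ncol(base$labels)
    px <- stats::runif(n_tiepoints, 0.1 * (nc - 1), 0.9 * (nc - 1))
    py <- stats::runif(n_tiepoints, 0.1 * (nr - 1), 0.9 * (nr - 1))
    rep_pts <- cbind(px, py)
    hist_pts <- transform_points(invert_transform(warp), rep_pts)
    if (tiepoint_noise_sd > 0)
      hist_pts <- hist_pts +
        matrix(stats::rnorm(2 * n_tiepoints, sd = tiepoint_noise_sd),
               ncol = 2)
    cats <- sort(unique(c(base$labels[base$valid],
                          modern_labels[base$valid])))
    before <- vapply(cats, function(cc) sum(base$labels[base$valid] == cc),
                     numeric(1))
    after <- vapply(cats, function(cc) sum(modern_labels[base$valid] == cc),
                    numeric(1))
    list(pair = photo_pair(station_id, historical = historical,
                           modern = modern),
         tiepoints = tie_points(hist_pts, rep_pts),
         warp = warp,
         change = data.frame(category_id = cats, pixels_before = before,
                             pixels_after = after,
                             change = after - before))
  })
}
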