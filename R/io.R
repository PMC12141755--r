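#' Read and write classified masks as 8-bit PNG
#'
#' Label masks travel as single-channel 8-bit PNG: the gray value is the
#' category id and 255 marks invalid pixels. This keeps fixtures and
#' pipeline artifacts plain, compact, and viewable.
#'
#' @param image a `classified_image`.
#' @param path file path ending in `.png`.
#' @param invalid_id invalid sentinel written for invalid pixels
#'   (default 255).
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a `classified_image`.
#' @export
write_mask_png <- function(image, path, invalid_id = 255L) {
  labs <- image$labels
  labs[!image$valid] <- as.integer(invalid_id)
  png::writePNG(labs / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, invalid_id = 255L) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  labs <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  classified_image(labs, valid = labs != as.integer(invalid_id))
}

#' Tie point CSV interchange
#'
#' Tie points are exchanged as CSV with columns `pair_id`, `x_hist`,
#' `y_hist`, `x_rep`, `y_rep` (0-based pixel coordinates).
#'
#' @param points a `tie_points` object.
#' @param path CSV file path.
#' @param pair_id identifier written in the `pair_id` column.
#' @return `write_tie_points` returns `path` invisibly; `read_tie_points`
#'   returns a `tie_points` object.
#' @export
write_tie_points <- function(points, path, pair_id = "pair") {
  utils::write.csv(data.frame(pair_id = pair_id,
                              x_hist = points$hist[, 1],
                              y_hist = points$hist[, 2],
                              x_rep = points$rep[, 1],
                              y_rep = points$rep[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tie_points
#' @export
read_tie_points <- function(path) {
  tab <- utils::read.csv(path)
  tie_points(cbind(tab$x_hist, tab$y_hist), cbind(tab$x_rep, tab$y_rep))
}

#' Affine transform JSON interchange
#'
#' Transforms are serialized as a JSON object of the six parameters plus
#' the tie point RMS when available.
#'
#' @param t an `affine_transform`.
#' @param path JSON file path.
#' @return `write_transform_json` returns `path` invisibly;
#'   `read_transform_json` returns an `affine_transform` (with attribute
#'   `rms` when stored).
#' @export
write_transform_json <- function(t, path) {
  obj <- as.list(unclass(t))
  obj$rms <- attr(t, "rms")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- affine_transform(obj$a, obj$b, obj$c, obj$d, obj$tx, obj$ty)
  if (!is.null(obj$rms)) attr(t, "rms") <- obj$rms
  t
}

#' Survey CSV interchange
#'
#' Surveys travel as CSV with columns `site_id`, `x`, `y`, `species`,
#' `count`, `k` (one row per site and species).
#'
#' @param surveys a `site_surveys` data frame.
#' @param path CSV file path.
#' @return `write_surveys` returns `path` invisibly; `read_surveys` a
#'   `site_surveys` data frame.
#' @export
write_surveys <- function(surveys, path) {
  cols <- intersect(c("site_id", "x", "y", "species", "count", "k"),
                    names(surveys))
  utils::write.csv(surveys[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("site_surveys", "data.frame")
  out
}

#' Species truth JSON interchange
#'
#' @param truths list of `species_truth` objects.
#' @param path JSON file path.
#' @return `write_truths_json` returns `path` invisibly;
#'   `read_truths_json` a list of `species_truth`s.
#' @export
write_truths_json <- function(truths, path) {
  jsonlite::write_json(lapply(truths, function(tr)
    list(species = tr$species, scale_m = tr$scale_m,
         coefficients = as.list(tr$coefficients),
         intercept = tr$intercept)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truths_json
#' @export
read_truths_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = FALSE), function(o)
    species_truth(o$species, o$scale_m, unlist(o$coefficients),
                  o$intercept))
}

#' Fitted model JSON interchange
#'
#' Each species' fit is stored with its scale, terms, coefficients,
#' standard errors, AIC, diagnostics and (when present) the per-radius AIC
#' profile.
#'
#' @param fits list of `sdm_fit`s.
#' @param path JSON file path.
#' @return `write_sdm_fits` returns `path` invisibly; `read_sdm_fits` a
#'   named list of `sdm_fit`s.
#' @export
write_sdm_fits <- function(fits, path) {
  jsonlite::write_json(lapply(fits, function(f) {
    prof <- attr(f, "profile")
    list(species = f$species, scale_m = f$scale_m,
         terms = as.list(f$terms),
         beta = as.list(f$beta), se = as.list(f$se),
         aic = f$aic, loglik = f$loglik, n_sites = f$n_sites,
         diagnostics = f$diagnostics,
         aic_profile = if (!is.null(prof)) prof else NULL)
  }), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_sdm_fits
#' @export
read_sdm_fits <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(objs, function(o) {
    beta <- unlist(lapply(o$beta, function(v) if (is.null(v)) NA_real_ else v))
    se <- unlist(lapply(o$se, function(v) if (is.null(v)) NA_real_ else v))
    nn <- function(v, default = NA) if (is.null(v)) default else v
    d <- o$diagnostics
    structure(list(species = o$species,
                   scale_m = nn(o$scale_m, NA_real_),
                   terms = unlist(o$terms),
                   beta = beta, se = se,
                   t_values = beta / se,
                   p_values = 2 * stats::pnorm(-abs(beta / se)),
                   aic = nn(o$aic, NA_real_), loglik = nn(o$loglik, NA_real_),
                   deviance = NA_real_, df_residual = NA_integer_,
                   n_sites = nn(o$n_sites, NA_integer_), k = NA_integer_,
                   diagnostics = list(
                     converged = nn(d$converged), iterations = nn(d$iterations),
                     separation = nn(d$separation),
                     dispersion = nn(d$dispersion, NA_real_),
                     degenerate_terms = unlist(d$degenerate_terms) %||% character(0),
                     validated = nn(d$validated),
                     reasons = unlist(d$reasons) %||% character(0))),
              class = "sdm_fit")
  })
  stats::setNames(fits, vapply(fits, function(f) f$species, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write change-test tables as CSV
#'
#' @param tests a `change_tests` or `species_change` data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_change_tests <- function(tests, path) {
  utils::write.csv(as.data.frame(tests), path, row.names = FALSE)
  invisible(path)
}
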