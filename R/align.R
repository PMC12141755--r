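#' Affine transforms on pixel coordinates
#'
#' An affine transform maps pixel coordinates `(x, y)` to
#' `(a*x + b*y + tx, c*x + d*y + ty)`. Pixel coordinates are 0-based,
#' `x` = column and `y` = row, origin at the top-left corner of the image.
#' The transform must be invertible (`a*d - b*c != 0`).
#'
#' @param a,b,c,d,tx,ty the six parameters.
#' @return An object of class `affine_transform` (named numeric of length 6).
#' @export
affine_transform <- function(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0) {
  t <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         tx = unname(tx), ty = unname(ty))
  if (!all(is.finite(t))) stop("affine parameters must be finite")
  if (abs(t["a"] * t["d"] - t["b"] * t["c"]) < 1e-12)
    stop("affine transform is not invertible (zero determinant)")
  structure(t, class = "affine_transform")
}

#' Similarity (rotation + isotropic scale + translation) transform
#'
#' Convenience constructor for the 4-parameter subfamily of affine maps:
#' rotation by `angle` radians, uniform scaling, then translation.
#'
#' @param angle rotation in radians, counterclockwise in `(x, y)`.
#' @param scale isotropic scale factor, nonzero.
#' @param tx,ty translation in pixels.
#' @return An `affine_transform`.
#' @export
similarity_transform <- function(angle = 0, scale = 1, tx = 0, ty = 0) {
  affine_transform(a = scale * cos(angle), b = -scale * sin(angle),
                   c = scale * sin(angle), d = scale * cos(angle),
                   tx = tx, ty = ty)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("Affine transform: (x, y) -> (%.6g x + %.6g y + %.6g, %.6g x + %.6g y + %.6g)\n",
              x["a"], x["b"], x["tx"], x["c"], x["d"], x["ty"]))
  invisible(x)
}

#' Apply an affine transform to point coordinates
#'
#' @param t an `affine_transform`.
#' @param xy two-column matrix (or length-2 vector) of `(x, y)` coordinates.
#' @return Matrix of transformed coordinates, same shape as the input.
#' @export
transform_points <- function(t, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  cbind(t["a"] * xy[, 1] + t["b"] * xy[, 2] + t["tx"],
        t["c"] * xy[, 1] + t["d"] * xy[, 2] + t["ty"],
        deparse.level = 0)
}

#' Invert an affine transform
#'
#' @param t an `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_transform <- function(t) {
  det <- t["a"] * t["d"] - t["b"] * t["c"]
  ai <- t["d"] / det; bi <- -t["b"] / det
  ci <- -t["c"] / det; di <- t["a"] / det
  affine_transform(a = unname(ai), b = unname(bi), c = unname(ci),
                   d = unname(di),
                   tx = unname(-(ai * t["tx"] + bi * t["ty"])),
                   ty = unname(-(ci * t["tx"] + di * t["ty"])))
}

#' Tie points between a historical and a repeat photograph
#'
#' Manually selected corresponding pixel coordinates of unchanging landscape
#' features (summits, stable boulders) in the two images of a pair, used to
#' estimate the registration transform.
#'
#' @param hist,rep two-column matrices of `(x, y)` pixel coordinates; row i of
#'   `hist` corresponds to row i of `rep`.
#' @return An object of class `tie_points`.
#' @export
tie_points <- function(hist, rep) {
  hist <- as.matrix(hist); rep <- as.matrix(rep)
  if (ncol(hist) != 2 || ncol(rep) != 2 || nrow(hist) != nrow(rep))
    stop("hist and rep must be two-column matrices with equal row counts")
  if (!all(is.finite(hist)) || !all(is.finite(rep)))
    stop("tie point coordinates must be finite")
  structure(list(hist = unname(hist), rep = unname(rep)),
            class = "tie_points")
}

#' Estimate the registration transform from tie points
#'
#' Solves, in the least-squares sense, for the affine (default) or
#' similarity transform mapping historical tie-point coordinates onto their
#' repeat-image counterparts. With exactly three non-collinear pairs the
#' affine solution interpolates the points exactly.
#'
#' @param points a `tie_points` object with at least 3 pairs.
#' @param kind `"affine"` (6 parameters, default) or `"similarity"`
#'   (rotation, isotropic scale, translation; 4 parameters).
#' @return An `affine_transform` with attribute `rms`, the root-mean-square
#'   residual distance in pixels.
#' @export
estimate_affine <- function(points, kind = c("affine", "similarity")) {
  kind <- match.arg(kind)
  n <- nrow(points$hist)
  if (n < 3) stop("at least 3 tie point pairs are required")
  x <- points$hist[, 1]; y <- points$hist[, 2]
  u <- points$rep[, 1]; v <- points$rep[, 2]
  if (kind == "affine") {
    X <- cbind(x, y, 1)
    qrX <- qr(X)
    if (qrX$rank < 3)
      stop("degenerate tie point geometry: points are collinear")
    cx <- qr.coef(qrX, u)  # (a, b, tx)
    cy <- qr.coef(qrX, v)  # (c, d, ty)
    t <- affine_transform(a = cx[1], b = cx[2], c = cy[1], d = cy[2],
                          tx = cx[3], ty = cy[3])
  } else {
    # similarity: u = s(x cosT - y sinT) + tx, v = s(x sinT + y cosT) + ty
    # linear in (p, q, tx, ty) with p = s cosT, q = s sinT:
    #   u = p x - q y + tx ; v = q x + p y + ty
    X <- rbind(cbind(x, -y, 1, 0), cbind(y, x, 0, 1))
    qrX <- qr(X)
    if (qrX$rank < 4)
      stop("degenerate tie point geometry: points are collinear or coincident")
    cf <- qr.coef(qrX, c(u, v))
    t <- affine_transform(a = cf[1], b = -cf[2], c = cf[2], d = cf[1],
                          tx = cf[3], ty = cf[4])
  }
  res <- alignment_residuals(t, points)
  attr(t, "rms") <- res$rms
  t
}

#' Residuals of a transform on tie points
#'
#' Euclidean distances between transformed historical points and their repeat
#' counterparts, summarized as the root-mean-square and the maximum. Pairs
#' whose residual exceeds `flag_threshold` pixels are flagged; the study
#' convention is that pairs should align to within a few pixels.
#'
#' @param t an `affine_transform`.
#' @param points a `tie_points` object.
#' @param flag_threshold distance in pixels above which a pair is flagged
#'   (default 3).
#' @return List with `distances` (per pair), `rms`, `max`, and `flagged`
#'   (logical per pair).
#' @export
alignment_residuals <- function(t, points, flag_threshold = 3) {
  mapped <- transform_points(t, points$hist)
  d <- sqrt(rowSums((mapped - points$rep)^2))
  list(distances = d, rms = sqrt(mean(d^2)), max = max(d),
       flagged = d > flag_threshold)
}

#' Warp a classified image with an affine transform
#'
#' Resamples the labels of `image` onto a new grid so that a feature at input
#' coordinate `p` appears at `transform_points(t, p)` in the output. Labels
#' are categorical, so resampling is strictly nearest-neighbour (the label of
#' the nearest source pixel center); no interpolation between categories ever
#' occurs. Output pixels whose source location falls outside the input grid
#' become invalid, and the validity mask is transported alongside the labels.
#'
#' @param image a `classified_image`.
#' @param t an invertible `affine_transform` (input -> output coordinates).
#' @param out_shape integer `(rows, cols)` of the output grid; defaults to
#'   the input shape.
#' @param invalid_id label value assigned to invalid output pixels
#'   (default 255).
#' @return A `classified_image` on the output grid.
#' @export
apply_transform <- function(image, t, out_shape = dim(image$labels),
                            invalid_id = 255L) {
  ti <- invert_transform(t)
  nr <- out_shape[1]; nc <- out_shape[2]
  # output pixel centers, 0-based (x = col, y = row)
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  src <- transform_points(ti, cbind(xs, ys))
  sc <- round(src[, 1]) + 1  # source column, 1-based
  sr <- round(src[, 2]) + 1  # source row, 1-based
  inside <- sc >= 1 & sc <= ncol(image$labels) &
            sr >= 1 & sr <= nrow(image$labels)
  labels <- matrix(as.integer(invalid_id), nr, nc)
  valid <- matrix(FALSE, nr, nc)
  if (!any(inside)) {
    warning("transform maps the entire output grid outside the source image")
  } else {
    idx_src <- cbind(sr[inside], sc[inside])
    idx_out <- cbind(ys[inside] + 1, xs[inside] + 1)
    labels[idx_out] <- image$labels[idx_src]
    valid[idx_out] <- image$valid[idx_src]
    labels[idx_out][!valid[idx_out]] <- as.integer(invalid_id)
  }
  classified_image(labels, valid)
}

#' Bundle a registered photo pair
#'
#' @param station_id identifier of the photo station.
#' @param historical,modern `classified_image`s on a shared pixel grid (the
#'   historical image is conventionally warped onto the repeat image's grid).
#' @param year_hist,year_mod capture years; must be ordered.
#' @param alignment_rms root-mean-square tie point residual in pixels.
#' @return An object of class `photo_pair`.
#' @export
photo_pair <- function(station_id, historical, modern,
                       year_hist = NA_integer_, year_mod = NA_integer_,
                       alignment_rms = NA_real_) {
  if (!identical(dim(historical$labels), dim(modern$labels)))
    stop("historical and modern images must share one pixel grid")
  if (!is.na(year_hist) && !is.na(year_mod) && year_hist > year_mod)
    stop("year_hist must not exceed year_mod")
  structure(list(station_id = station_id, historical = historical,
                 modern = modern, year_hist = year_hist,
                 year_mod = year_mod, alignment_rms = alignment_rms),
            class = "photo_pair")
}
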