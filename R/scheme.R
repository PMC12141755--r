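#' Define a categorical land cover scheme
#'
#' A scheme lists the land cover categories that classified images and
#' thematic rasters may contain, an optional merge map collapsing fine
#' categories into coarse ones (e.g., crown-cover density classes of conifer
#' into a single conifer class), and a reserved integer id marking invalid
#' (unclassified, foreground, out-of-frame) pixels.
#'
#' @param categories data frame with columns `id` (unique small integers) and
#'   `name` (unique character labels), or a named integer vector
#'   (names = category names, values = ids).
#' @param merge_map optional named character vector mapping every fine
#'   category name to a coarse category name. Must be total over the fine
#'   names when present.
#' @param invalid_id integer reserved for excluded pixels; must not collide
#'   with any category id. Default 255, the conventional palette sentinel.
#' @return An object of class `landcover_scheme`.
#' @seealso [default_scheme()] for the standard 10-category mountain scheme.
#' @export
landcover_scheme <- function(categories, merge_map = NULL, invalid_id = 255L) {
  if (is.numeric(categories) && !is.null(names(categories))) {
    categories <- data.frame(id = as.integer(unname(categories)),
                             name = names(categories),
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(categories),
            all(c("id", "name") %in% names(categories)))
  categories$id <- as.integer(categories$id)
  if (anyDuplicated(categories$id))
    stop("category ids must be unique")
  if (anyDuplicated(categories$name))
    stop("category names must be unique")
  invalid_id <- as.integer(invalid_id)
  if (invalid_id %in% categories$id)
    stop("invalid_id collides with a category id")
  if (!is.null(merge_map)) {
    if (is.null(names(merge_map)) || any(!nzchar(names(merge_map))))
      stop("merge_map must be a named vector (fine name -> coarse name)")
    missing_fine <- setdiff(categories$name, names(merge_map))
    if (length(missing_fine))
      stop("merge_map is not total; unmapped fine categories: ",
           paste(missing_fine, collapse = ", "))
  }
  structure(list(categories = categories, merge_map = merge_map,
                 invalid_id = invalid_id),
            class = "landcover_scheme")
}

#' Standard 10-category mountain land cover scheme
#'
#' The ten thematic categories used throughout: coniferous forest, mixedwood
#' forest, broadleaf forest, wetland, shrubs, herbaceous, regenerating area,
#' barren land, water, and ice/snow. Ids run 1--10; 255 marks invalid pixels.
#'
#' @return A `landcover_scheme` with ten categories.
#' @export
default_scheme <- function() {
  landcover_scheme(c(
    "coniferous forest" = 1L, "mixedwood forest" = 2L,
    "broadleaf forest" = 3L, "wetland" = 4L, "shrubs" = 5L,
    "herbaceous" = 6L, "regenerating area" = 7L, "barren land" = 8L,
    "water" = 9L, "ice/snow" = 10L))
}

#' @export
print.landcover_scheme <- function(x, ...) {
  cat("Land cover scheme:", nrow(x$categories), "categories",
      if (!is.null(x$merge_map)) "(with merge map)" else "", "\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}

scheme_names <- function(scheme) scheme$categories$name

scheme_ids <- function(scheme) scheme$categories$id

id_for_name <- function(scheme, name) {
  i <- match(name, scheme$categories$name)
  if (anyNA(i)) stop("unknown category name: ",
                     paste(name[is.na(i)], collapse = ", "))
  scheme$categories$id[i]
}

#' Construct a classified image
#'
#' A classified image is an integer label grid plus a logical validity mask of
#' the same shape. Invalid pixels (foreground, high-uncertainty areas,
#' out-of-frame after warping) are excluded from all composition accounting.
#'
#' @param labels integer matrix of category ids (rows = y, columns = x).
#' @param valid logical matrix of the same shape; `FALSE` marks excluded
#'   pixels. Default: all pixels valid.
#' @param scheme optional `landcover_scheme`; when given, labels on valid
#'   pixels are checked against it.
#' @return An object of class `classified_image`.
#' @export
classified_image <- function(labels, valid = NULL, scheme = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(labels), ncol(labels))
  valid <- as.matrix(valid)
  if (!identical(dim(labels), dim(valid)))
    stop("labels and valid mask must have identical shape")
  storage.mode(valid) <- "logical"
  if (!is.null(scheme)) {
    bad <- setdiff(unique(labels[valid]), scheme_ids(scheme))
    if (length(bad))
      stop("labels outside scheme on valid pixels: ",
           paste(bad, collapse = ", "))
  }
  structure(list(labels = labels, valid = valid), class = "classified_image")
}

#' @export
print.classified_image <- function(x, ...) {
  cat(sprintf("Classified image %d x %d, %d/%d valid pixels\n",
              nrow(x$labels), ncol(x$labels), sum(x$valid),
              length(x$valid)))
  invisible(x)
}

#' Construct a thematic raster map
#'
#' A categorical raster in map units: a label grid, the cell edge length in
#' meters, and the map coordinates of the top-left corner. Cell centers are at
#' `origin + (col - 0.5) * cell_size` in x and `origin - (row - 0.5) *
#' cell_size` in y (y increases upward, rows run downward from the top edge).
#'
#' @param labels integer matrix of category ids.
#' @param cell_size cell edge length in meters; must be positive.
#' @param origin numeric `(x, y)` of the top-left corner in map units.
#' @return An object of class `raster_map`.
#' @export
raster_map <- function(labels, cell_size, origin = c(0, 0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  cell_size <- as.numeric(cell_size)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number of meters")
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  structure(list(labels = labels, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "raster_map")
}

#' @export
print.raster_map <- function(x, ...) {
  cat(sprintf("Raster map %d x %d cells, %.6g m cells, origin (%g, %g)\n",
              nrow(x$labels), ncol(x$labels), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# Run `fun` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations take explicit seeds;
# no function leaves a trace in the global RNG.
with_seed <- function(seed, fun) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  fun()
}
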