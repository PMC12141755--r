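#' Composition vectors
#'
#' A composition vector stores, for each category of a scheme, the percent of
#' valid pixels (or buffer cells) it covers. Values are percentages in
#' 0--100 and sum to 100; `n_valid` records how many pixels the percentages
#' are based on. Percent (not fraction) is the convention shared by every
#' module: model coefficients are log-odds per percentage point.
#'
#' @param values named numeric vector of percentages.
#' @param n_valid number of valid pixels/cells behind the percentages.
#' @return An object of class `composition_vector` (a named numeric vector
#'   with attribute `n_valid`).
#' @export
composition_vector <- function(values, n_valid) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("composition values must be named by category")
  if (any(values < -1e-9)) stop("composition values must be non-negative")
  if (abs(sum(values) - 100) > 1e-6)
    stop("composition must sum to 100 (percent), got ", sum(values))
  if (n_valid <= 0) stop("n_valid must be positive")
  structure(as.numeric(values), names = names(values),
            n_valid = as.integer(n_valid), class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("Composition (% of", attr(x, "n_valid"), "valid pixels):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Land cover composition of a classified image
#'
#' Counts the proportion of valid pixels in each category of the scheme,
#' expressed in percent. Categories absent from the image are reported with
#' value 0; invalid pixels are excluded from the denominator.
#'
#' @param image a `classified_image`.
#' @param scheme a `landcover_scheme`.
#' @return A `composition_vector` over the scheme's categories.
#' @export
composition <- function(image, scheme) {
  n_valid <- sum(image$valid)
  if (n_valid == 0)
    stop("image has no valid pixels; composition is undefined")
  labs <- image$labels[image$valid]
  counts <- tabulate(match(labs, scheme_ids(scheme)),
                     nbins = nrow(scheme$categories))
  unknown <- sum(is.na(match(labs, scheme_ids(scheme))))
  if (unknown > 0)
    stop(unknown, " valid pixels carry labels outside the scheme")
  composition_vector(stats::setNames(100 * counts / n_valid,
                                     scheme_names(scheme)), n_valid)
}

#' Merge fine categories into coarse ones
#'
#' Applies the scheme's merge map to a composition vector: each coarse
#' category's percentage is the sum of its fine categories'. The total is
#' conserved.
#'
#' @param comp a `composition_vector` over fine categories.
#' @param scheme a `landcover_scheme` whose `merge_map` is defined.
#' @return A `composition_vector` over the coarse categories.
#' @export
merge_categories <- function(comp, scheme) {
  if (is.null(scheme$merge_map))
    stop("scheme has no merge_map")
  coarse <- scheme$merge_map[names(comp)]
  if (anyNA(coarse))
    stop("merge_map does not cover: ",
         paste(names(comp)[is.na(coarse)], collapse = ", "))
  merged <- tapply(as.numeric(comp), coarse, sum)
  # keep first-appearance order of coarse categories
  ord <- unique(unname(coarse))
  composition_vector(stats::setNames(as.numeric(merged[ord]), ord),
                     attr(comp, "n_valid"))
}

#' Shannon diversity index of a composition
#'
#' `H = -sum p_i log(p_i)` over categories with positive share, with
#' `p_i = percent_i / 100`. The natural logarithm is the default (the
#' convention of the vegan package); other bases are available through
#' `base`. Zero-share categories contribute nothing, so `H` is invariant to
#' padding the composition with absent categories.
#'
#' @param comp a `composition_vector`, or any non-negative numeric vector of
#'   percentages summing to 100.
#' @param base logarithm base; default `exp(1)` (nats).
#' @return Shannon index `H >= 0`.
#' @export
shannon_index <- function(comp, base = exp(1)) {
  p <- as.numeric(comp) / 100
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided signed-rank test, implemented from first principles.
#' Zero differences are dropped (the Wilcoxon convention); absolute
#' differences are ranked with midranks for ties; the statistic `W` is the
#' sum of ranks of positive differences. The p-value is exact — computed by
#' enumerating the distribution of `W` over all `2^n` equiprobable sign
#' assignments — when `n <= exact_max` and there are no ties among the
#' absolute differences; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param before,after equal-length numeric vectors of paired observations,
#'   differences taken as `after - before`; alternatively pass the
#'   differences directly as `before` and leave `after` `NULL`.
#' @param exact_max largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return List with `statistic` (W), `p_value`, `n` (non-zero differences),
#'   and `method` ("exact" or "normal approximation").
#' @export
wilcoxon_signed_rank <- function(before, after = NULL, exact_max = 25) {
  d <- if (is.null(after)) as.numeric(before) else {
    if (length(before) != length(after))
      stop("before and after must have equal length")
    as.numeric(after) - as.numeric(before)
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("all differences are zero; the signed-rank test is undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    p <- signed_rank_exact_p(W, n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tab^3 - tab) / 48)
    z <- W - mu
    p <- if (z > 0) 2 * stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE)
         else if (z < 0) 2 * stats::pnorm((z + 0.5) / sigma)
         else 1
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

# Exact two-sided p-value of the signed-rank statistic for n untied ranks.
# The distribution of W over the 2^n sign assignments is built by the
# generating-polynomial recursion prod_k (1 + z^k); counts are kept as
# doubles (exact for n <= 25 since 2^25 << 2^53).
signed_rank_exact_p <- function(W, n) {
  counts <- c(1, rep(0, n * (n + 1) / 2))  # counts[w + 1] = #assignments
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts[seq_len(length(counts) - k)])
    counts <- counts + shifted
  }
  total <- 2^n
  lower <- sum(counts[seq_len(W + 1)]) / total       # P(W <= w)
  upper <- sum(counts[(W + 1):length(counts)]) / total  # P(W >= w)
  min(1, 2 * min(lower, upper))
}

#' Paired land cover change tests across photo pairs
#'
#' For every category of the composition vectors, and for the Shannon
#' diversity index, compares historical and modern values across pairs:
#' means with standard errors, the mean change in percentage points (or in
#' nats for Shannon), a two-sided Wilcoxon signed-rank test, and a bootstrap
#' percentile confidence interval for the mean change obtained by resampling
#' pairs.
#'
#' @param pairs list; each element a list/pair `(before, after)` of
#'   `composition_vector`s sharing category names (e.g. historical and
#'   modern composition of one photo station).
#' @param n_boot bootstrap resamples for the CI (default 10000).
#' @param conf_level CI level (default 0.95).
#' @param seed seed for the bootstrap resampling.
#' @param relative if `TRUE` test relative change `(after - before)/before`
#'   instead of the default change in percentage points.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the unadjusted convention; `"holm"`
#'   available).
#' @return Data frame of class `change_tests`: one row per category plus one
#'   for `"shannon"`, with columns `target`, `n_pairs`, `mean_before`,
#'   `se_before`, `mean_after`, `se_after`, `mean_change`, `statistic`,
#'   `p_value`, `ci_low`, `ci_high`, `note`.
#' @export
paired_change <- function(pairs, n_boot = 10000, conf_level = 0.95,
                          seed = NULL, relative = FALSE, adjust = "none") {
  if (length(pairs) < 2) stop("at least 2 pairs are required")
  before <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[[1]])))
  after <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[[2]])))
  cats <- names(pairs[[1]][[1]])
  colnames(before) <- colnames(after) <- cats
  before <- cbind(before, shannon = apply(before[, cats, drop = FALSE], 1,
                                          shannon_index))
  after <- cbind(after, shannon = apply(after[, cats, drop = FALSE], 1,
                                        shannon_index))
  targets <- colnames(before)
  n <- length(pairs)
  rows <- lapply(targets, function(tg) {
    b <- before[, tg]; a <- after[, tg]
    ch <- if (relative) ifelse(b == 0, NA_real_, (a - b) / b) else a - b
    chc <- ch[!is.na(ch)]
    undefined <- all(chc == 0) || length(chc) == 0
    if (undefined) {
      w <- list(statistic = NA_real_, p_value = NA_real_)
      note <- "undefined: all differences zero"
    } else {
      w <- wilcoxon_signed_rank(chc)
      note <- ""
    }
    ci <- bootstrap_mean_ci(chc, n_boot, conf_level, seed)
    data.frame(target = tg, n_pairs = n,
               mean_before = mean(b), se_before = stats::sd(b) / sqrt(n),
               mean_after = mean(a), se_after = stats::sd(a) / sqrt(n),
               mean_change = mean(chc),
               statistic = w$statistic, p_value = w$p_value,
               ci_low = ci[1], ci_high = ci[2], note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  class(out) <- c("change_tests", "data.frame")
  out
}

# Percentile bootstrap CI for a mean, resampling observations with
# replacement. Degenerate inputs give a zero-width interval at the mean.
bootstrap_mean_ci <- function(x, n_boot, conf_level, seed = NULL) {
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  if (all(x == x[1])) return(c(x[1], x[1]))
  alpha <- (1 - conf_level) / 2
  with_seed(seed, function() {
    means <- vapply(seq_len(n_boot), function(i)
      mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    unname(stats::quantile(means, c(alpha, 1 - alpha)))
  })
}
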