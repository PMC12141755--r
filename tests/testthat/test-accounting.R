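test_that("composition counts valid pixels only and pads absent categories", {
  labs <- matrix(1L, 10, 10)
  labs[, 6:10] <- 6L
  valid <- matrix(TRUE, 10, 10)
  labs[1, 1:5] <- 6L   # 45 conifer, 55 herbaceous before masking
  valid[1, 6:10] <- FALSE
  valid[2, 6:10] <- FALSE  # drop 10 herbaceous -> 45/45 split
  comp <- composition(classified_image(labs, valid), scheme10)
  expect_equal(unname(comp["coniferous forest"]), 50)
  expect_equal(unname(comp["herbaceous"]), 50)
  expect_equal(unname(comp["wetland"]), 0)
  expect_equal(attr(comp, "n_valid"), 90L)
  expect_equal(sum(comp), 100, tolerance = 1e-9)
})

test_that("an all-invalid image is an error", {
  img <- classified_image(matrix(1L, 5, 5), matrix(FALSE, 5, 5))
  expect_error(composition(img, scheme10), "no valid pixels")
})

test_that("category merging is additive and conserves the total", {
  fine <- landcover_scheme(c("dense conifer" = 1, "moderate conifer" = 2,
                             "open conifer" = 3, "herbaceous" = 4),
                           merge_map = c("dense conifer" = "conifer",
                                         "moderate conifer" = "conifer",
                                         "open conifer" = "conifer",
                                         "herbaceous" = "herbaceous"))
  comp <- composition_vector(c("dense conifer" = 30, "moderate conifer" = 20,
                               "open conifer" = 10, "herbaceous" = 40), 100)
  merged <- merge_categories(comp, fine)
  expect_equal(unname(merged["conifer"]), 60)
  expect_equal(sum(merged), 100, tolerance = 1e-9)
  ident <- landcover_scheme(c(a = 1, b = 2),
                            merge_map = c(a = "a", b = "b"))
  comp2 <- composition_vector(c(a = 70, b = 30), 10)
  expect_equal(as.numeric(merge_categories(comp2, ident)),
               as.numeric(comp2))
})

test_that("Shannon index matches closed forms and the vegan oracle", {
  expect_equal(shannon_index(composition_vector(c(a = 100), 1)), 0)
  expect_equal(shannon_index(composition_vector(c(a = 50, b = 50), 2)),
               log(2))
  ten <- composition_vector(setNames(rep(10, 10), letters[1:10]), 10)
  expect_equal(shannon_index(ten), log(10))
  # zero-share categories do not move H
  padded <- composition_vector(c(a = 50, b = 50, c = 0, d = 0), 4)
  expect_equal(shannon_index(padded), log(2))
  skip_if_not_installed("vegan")
  withr::with_seed(5, {
    for (i in 1:200) {
      comp <- random_composition(sample(2:10, 1))
      expect_equal(shannon_index(comp),
                   unname(vegan::diversity(as.numeric(comp) / 100)),
                   tolerance = 1e-12)
    }
  })
})

test_that("Shannon decreases when share moves from rarer to more abundant", {
  comp <- c(a = 60, b = 30, c = 10)
  for (delta in c(2, 5, 9)) {
    shifted <- comp + c(delta, 0, -delta)
    expect_lt(shannon_index(composition_vector(shifted, 10)),
              shannon_index(composition_vector(comp, 10)))
  }
})

test_that("signed-rank statistic and exact p match the frozen example", {
  w <- wilcoxon_signed_rank(c(0, 0, 0, 0, 0), c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 15)
  expect_equal(w$p_value, 2 / 32)
  expect_equal(w$method, "exact")
})

test_that("exact p equals 2^n brute-force enumeration for n <= 12", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- sample(3:12, 1)
      d <- round(rnorm(n, sd = 5), 3)
      d <- d[d != 0]
      if (length(d) < 2 || any(duplicated(abs(d)))) next
      mine <- wilcoxon_signed_rank(d)
      oracle <- wilcoxon_brute_force(d)
      expect_equal(mine$statistic, oracle$statistic)
      expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
    }
  })
})

test_that("signed-rank test agrees with stats::wilcox.test on both branches", {
  withr::with_seed(23, {
    # exact branch
    for (i in 1:10) {
      d <- rnorm(10)
      ref <- wilcox.test(d, exact = TRUE)
      mine <- wilcoxon_signed_rank(d)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
    # tied / large-n normal-approximation branch
    for (i in 1:10) {
      d <- sample(c(-3:-1, 1:4), 30, replace = TRUE)
      ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
      mine <- wilcoxon_signed_rank(d)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(mine$method, "normal approximation")
    }
  })
})

test_that("positive and negative rank sums partition n(n+1)/2", {
  withr::with_seed(29, {
    for (i in 1:20) {
      n <- sample(4:15, 1)
      d <- rnorm(n)
      w_pos <- wilcoxon_signed_rank(d)$statistic
      w_neg <- wilcoxon_signed_rank(-d)$statistic
      expect_equal(w_pos + w_neg, n * (n + 1) / 2)
    }
  })
})

test_that("all-zero differences are an undefined test", {
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "undefined")
})

test_that("paired change flags identical pairs and closes over categories", {
  comp <- composition_vector(c(a = 60, b = 40), 100)
  same <- replicate(4, list(before = comp, after = comp), simplify = FALSE)
  out <- paired_change(same, n_boot = 100, seed = 1)
  expect_true(all(out$mean_change == 0))
  expect_true(all(out$note == "undefined: all differences zero"))
  expect_true(all(is.na(out$p_value)))
})

test_that("paired change recovers generator transition directions", {
  withr::with_seed(31, {
    pairs <- lapply(1:8, function(i) {
      land <- generate_landscape(scheme10, c(60, 60),
                                 c("herbaceous" = 0.3,
                                   "coniferous forest" = 0.7),
                                 seed = 100 + i)
      base <- classified_image(land$labels)
      gp <- generate_photo_pair(base,
                                transition = data.frame(from = 6L, to = 1L,
                                                        rate = 0.5),
                                seed = 200 + i)
      list(before = composition(base, scheme10),
           after = composition(gp$pair$modern, scheme10))
    })
  })
  out <- paired_change(pairs, n_boot = 500, seed = 2)
  conif <- out[out$target == "coniferous forest", ]
  herb <- out[out$target == "herbaceous", ]
  expect_gt(conif$mean_change, 0)
  expect_lt(herb$mean_change, 0)
  expect_true(conif$ci_low <= conif$mean_change &
                conif$mean_change <= conif$ci_high)
  # compositions are closed: changes sum to zero over categories
  cats <- setdiff(out$target, "shannon")
  expect_equal(sum(out$mean_change[out$target %in% cats]), 0,
               tolerance = 1e-6)
  # conifer was already dominant, so homogenization lowers Shannon
  expect_lt(out$mean_change[out$target == "shannon"], 0)
})

test_that("Holm adjustment and relative change are available", {
  comp_a <- composition_vector(c(a = 60, b = 40), 100)
  comp_b <- composition_vector(c(a = 70, b = 30), 100)
  pairs <- lapply(1:5, function(i) {
    jit <- composition_vector(c(a = 70 + i * 0.1,
                                b = 30 - i * 0.1), 100)
    list(before = comp_a, after = jit)
  })
  raw <- paired_change(pairs, n_boot = 100, seed = 3)
  holm <- paired_change(pairs, n_boot = 100, seed = 3, adjust = "holm")
  expect_true(all(holm$p_value >= raw$p_value, na.rm = TRUE))
  rel <- paired_change(pairs, n_boot = 100, seed = 3, relative = TRUE)
  expect_equal(rel$mean_change[rel$target == "a"],
               mean(sapply(1:5, function(i) (10 + i * 0.1) / 60)),
               tolerance = 1e-9)
})
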