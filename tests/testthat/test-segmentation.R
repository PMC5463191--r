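test_that("Dice matches direct counting and its defining properties", {
  expect_equal(dice(1:4, c(3, 4, 9, 10)), 0.5)   # |a|=4, |b|=4, overlap 2
  expect_equal(dice(1:5, 1:5), 1)
  expect_equal(dice(1:3, 4:6), 0)
  expect_error(dice(integer(0), integer(0)), "empty")
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:60, sample(1:30, 1))
    b <- sample(1:60, sample(1:30, 1))
    oracle <- 2 * sum(a %in% b) / (length(a) + length(b))
    expect_equal(dice(a, b), oracle, tolerance = 1e-12)
    expect_equal(dice(b, a), dice(a, b))
    expect_gte(dice(a, b), 0); expect_lte(dice(a, b), 1)
    expect_equal(dice(a, b) == 1, setequal(a, b))
  }
})

test_that("the mixture fit is deterministic and recovers known densities", {
  set.seed(5)
  x <- rnorm(3000, 0.5, 0.1)
  f1 <- fit_layer_gmm(x, seed = 3)
  f2 <- fit_layer_gmm(x, seed = 3)
  expect_identical(f1[c("weights", "means", "vars", "loglik")],
                   f2[c("weights", "means", "vars", "loglik")])
  # held-out average log-likelihood close to the generating density's
  xh <- rnorm(2000, 0.5, 0.1)
  ll_fit <- mean(gmm_density(f1, xh, log = TRUE))
  ll_true <- mean(dnorm(xh, 0.5, 0.1, log = TRUE))
  expect_equal(ll_fit, ll_true, tolerance = 0.02)
})

test_that("a well-separated three-component mixture is recovered", {
  set.seed(21)
  x <- c(rnorm(700, 0.2, 0.02), rnorm(700, 0.5, 0.02), rnorm(700, 0.8, 0.02))
  fit <- fit_layer_gmm(x, seed = 4)
  expect_equal(fit$k, 3L)
  expect_lt(max(abs(fit$means - c(0.2, 0.5, 0.8))), 0.02)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$vars >= 1e-8))
})

test_that("small and constant samples fall back to flagged single models", {
  small <- rnorm(10, 0.3, 0.05)
  f <- fit_layer_gmm(small, seed = 1)
  expect_equal(f$k, 1L)
  expect_true(f$fallback_single)
  fc <- fit_layer_gmm(rep(0.25, 100), seed = 1)
  expect_true(fc$degenerate)
  expect_equal(fc$means, 0.25)
  expect_error(fit_layer_gmm(0.4), "at least 2")
})

test_that("classification is maximum likelihood with upper tie-break", {
  set.seed(31)
  img <- matrix(runif(100), 10, 10)
  region <- seq_len(100)
  models <- list(
    A = fit_layer_gmm(rnorm(500, 0.2, 0.05), seed = 1),
    B = fit_layer_gmm(rnorm(500, 0.5, 0.05), seed = 2),
    C = fit_layer_gmm(rnorm(500, 0.8, 0.05), seed = 3))
  got <- classify_region(img, region, models)
  # exhaustive per-pixel oracle: sum the component densities by hand
  dens1 <- function(m, v) sum(m$weights * dnorm(v, m$means, sqrt(m$vars)))
  oracle <- vapply(region, function(i) {
    d3 <- vapply(models, dens1, 0, v = img[i])
    names(models)[which.max(d3)]
  }, "")
  expect_identical(got, oracle)
  # identical models everywhere -> exact ties -> everything goes upper
  same <- list(A = models$B, B = models$B, C = models$B)
  expect_true(all(classify_region(img, region, same) == "A"))
})

test_that("noise-free distinct layers segment perfectly", {
  sc <- flat_scene()
  cs <- generate_clean_scan(sc)
  mask <- rasterize_mask(cs$boundaries, sc$depth, sc$band)
  res <- image_dice(cs$scan, mask, seed = 8)
  expect_true(all(res$dice[c("GCL_IPL", "INL", "OPL")] == 1))
  expect_equal(res$dice_image, mean(res$dice))
  # reproducible bit-exactly under the same seed
  res2 <- image_dice(cs$scan, mask, seed = 8)
  expect_identical(res$dice, res2$dice)
})

test_that("identical intensity distributions give only chance-level Dice", {
  sc <- flat_scene(layer_means = rep(0.5, 5), vitreous_mean = 0.5,
                   sub_elm_mean = 0.5)
  cs <- generate_clean_scan(sc)
  mask <- rasterize_mask(cs$boundaries, sc$depth, sc$band)
  noisy <- as.matrix(cs$scan) +
    matrix(rnorm(sc$depth * sc$width, 0, 0.05), sc$depth)
  res <- segment_layer(noisy, mask, "INL", seed = 2)
  # the manual region is a third of the classification region; chance-level
  # overlap stays far from 1
  expect_lt(res$dice, 0.75)
  expect_true(all(res$auto %in% res$region))
})

test_that("per-layer and image Dice are self-consistent", {
  sc <- flat_scene()
  cs <- generate_clean_scan(sc)
  mask <- rasterize_mask(cs$boundaries, sc$depth, sc$band)
  avg <- average_frames(generate_frames(cs$scan, 8,
                                        uncorrelated_noise(0.04), seed = 6))
  res <- image_dice(avg, mask, seed = 12)
  redone <- vapply(seq_along(layer_labels()), function(i) {
    segment_layer(avg, mask, layer_labels()[i],
                  seed = 12 + 10L * (i - 1L))$dice
  }, 0)
  expect_equal(unname(res$dice), redone)
  expect_equal(res$dice_image, mean(res$dice))
})

test_that("layers with degenerate neighbours are flagged, not fatal", {
  # collapse the INL to zero height: INL itself and both adjacent layers
  # lose a usable neighbour and must come back as flagged NA
  bs <- boundary_set(matrix(c(10L, 20L, 30L, 30L, 50L, 60L), 6, 20))
  mask <- rasterize_mask(bs, 80L, band = 20L)
  means_by_code <- c(0.02, 0.1, 0.3, 0.5, 0.7, 0.9, 0.6, 0.6)
  clean <- matrix(means_by_code[unclass(mask) + 1L], 80L, 20L)
  set.seed(9)
  avg <- clean + matrix(rnorm(80 * 20, 0, 0.02), 80L, 20L)
  w <- capture_warnings(res <- image_dice(avg, mask, seed = 3))
  expect_true(any(grepl("INL", w)))
  expect_true(is.na(res$dice[["INL"]]))
  got <- res$dice[!is.na(res$dice)]
  expect_equal(res$dice_image, mean(got))
})

test_that("own EM matches an established mixture fitter on loglik", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(77)
  x <- c(rnorm(600, 0.3, 0.04), rnorm(900, 0.55, 0.06), rnorm(500, 0.8, 0.03))
  ours <- fit_layer_gmm(x, seed = 5)
  ref <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
})
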