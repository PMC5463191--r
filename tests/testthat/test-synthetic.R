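test_that("clean scans are piecewise-constant at the configured means", {
  sc <- flat_scene()
  cs <- generate_clean_scan(sc)
  img <- as.matrix(cs$scan)
  # rows between boundary i and i+1 all equal layer_means[i]
  expect_true(all(img[12, ] == 0.1))   # 0-based row 11 in [10, 20) -> NFL
  expect_true(all(img[25, ] == 0.3))
  expect_true(all(img[1, ] == 0.02))   # vitreous
  configured <- c(0.02, 0.1, 0.3, 0.5, 0.7, 0.9, 0.6)
  expect_true(all(img %in% configured))
  # identical geometry out of the same config
  cs2 <- generate_clean_scan(sc)
  expect_identical(as.matrix(cs2$scan), img)
  expect_identical(cs2$boundaries$boundaries, cs$boundaries$boundaries)
})

test_that("invalid scene configurations are rejected", {
  expect_error(flat_scene(rows = c(10, 20, 15, 40, 50, 60)),
               "strictly ordered")
  expect_error(flat_scene(rows = c(10, 20, 30, 40, 50, 90)),
               "leave")
  expect_error(scene_config(layer_means = c(0.1, 0.2, 0.3, 0.4, 1.4)),
               "layer_means")
})

test_that("zero-noise limit reproduces the clean scan for any M", {
  sc <- flat_scene()
  cs <- generate_clean_scan(sc)
  noise <- noise_config(sigma_u = 1e-12, sigma_c = 0)
  for (M in c(1L, 3L)) {
    stack <- generate_frames(cs$scan, M, noise, seed = 1)
    for (i in seq_len(M)) {
      expect_equal(stack[, , i], as.matrix(cs$scan), tolerance = 1e-9)
    }
  }
  expect_error(generate_frames(cs$scan, 0, noise), "M must be >= 1")
})

test_that("per-frame noise has the configured scale and seeded determinism", {
  sc <- flat_scene(width = 12L, depth = 40L, rows = c(5, 10, 15, 20, 25, 30),
                   layer_means = rep(0.5, 5), vitreous_mean = 0.5,
                   sub_elm_mean = 0.5, band = 10L)
  cs <- generate_clean_scan(sc)
  noise <- uncorrelated_noise(sigma_u = 0.05)
  stack <- generate_frames(cs$scan, 1000L, noise, seed = 42)
  px_sd <- apply(stack, c(1, 2), sd)
  # all pixels sit at 0.5, ~10 sd from the clip boundaries
  expect_equal(mean(px_sd), 0.05, tolerance = 0.01)
  expect_lt(max(abs(px_sd - 0.05)), 0.012)
  stack2 <- generate_frames(cs$scan, 1000L, noise, seed = 42)
  expect_identical(stack, stack2)
})

test_that("frame averaging is the arithmetic mean with recorded M", {
  f1 <- matrix(0.2, 4, 5)
  f2 <- matrix(0.4, 4, 5)
  avg <- average_frames(list(f1, f2))
  expect_equal(as.matrix(avg), matrix(0.3, 4, 5))
  expect_equal(scan_meta(avg)$frames, 2L)
  same <- average_frames(list(f1, f1, f1))
  expect_equal(as.matrix(same), f1)
  expect_error(average_frames(list(f1, matrix(0.4, 5, 4))), "same shape")
  expect_error(average_frames(list()), "empty")
})

test_that("jitter smooths boundary gradients as M grows", {
  sc <- flat_scene()
  cs <- generate_clean_scan(sc)
  noise <- noise_config(sigma_u = 0.01, sigma_c = 0, jitter_px = 1.5)
  # peak axial gradient in a window around the NFL/GCL boundary: a sharp
  # edge concentrates the step in one row, jitter blur spreads it out
  grad_at_boundaries <- function(avg) {
    img <- as.matrix(avg)
    g <- abs(diff(img))
    b <- cs$boundaries$boundaries[2, 1]
    mean(apply(g[(b - 3):(b + 4), ], 2, max))
  }
  g <- vapply(c(1, 8, 64), function(M) {
    mean(vapply(1:5, function(r) {
      grad_at_boundaries(average_frames(
        generate_frames(cs$scan, M, noise, seed = 100 * M + r)))
    }, 0))
  }, 0)
  expect_true(all(diff(g) <= 1e-6))
})

test_that("the simulated study has the full design grid and shared geometry", {
  design <- study_design(n_eyes = 3L)
  ds <- simulate_study(design, small_scene(width = 48L, depth = 120L),
                       seed = 9)
  expect_equal(length(ds$scans), 3 * 2 * 7)
  grid <- do.call(rbind, lapply(ds$scans, function(r) {
    data.frame(eye = r$eye, condition = r$condition, M = r$frames)
  }))
  expect_equal(nrow(unique(grid)), 42)
  # one shared boundary set per eye across all of its 14 scans
  expect_equal(length(ds$eyes), 3L)
  for (e in ds$eyes) {
    expect_s3_class(e$boundaries, "boundary_set")
    expect_setequal(e$acquisition_order$pre, design$settings)
  }
  # eye-level heterogeneity: perturbed scenes differ between eyes
  expect_false(identical(ds$eyes[[1]]$scene$layer_means,
                         ds$eyes[[2]]$scene$layer_means))
  ds2 <- simulate_study(design, small_scene(width = 48L, depth = 120L),
                        seed = 9)
  expect_identical(lapply(ds$scans, function(r) as.matrix(r$scan)),
                   lapply(ds2$scans, function(r) as.matrix(r$scan)))
})

test_that("condition-config preconditions are enforced", {
  expect_error(simulate_study(study_design(n_eyes = 1),
                              noise_pre = default_noise_config("post")),
               "opacity < 1")
  expect_error(simulate_study(study_design(n_eyes = 1),
                              noise_post = default_noise_config("pre")),
               "opacity = 1")
  expect_error(study_design(settings = c(4, 2)), "strictly increasing")
  expect_error(noise_config(sigma_u = 0), "sigma_u")
  expect_error(noise_config(opacity = 0), "opacity")
})
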