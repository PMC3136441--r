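p20_fractions <- function() estimate_fraction(c(-0.3, -0.5, -0.8))

test_that("the forward model matches its closed forms", {
  full <- simulate_profile(data.frame(length_bp = 4000, fraction = 1),
                           noise_sd = 0, seed = 1)
  expect_true(all(full$log2_ratio == -1))
  none <- simulate_profile(data.frame(length_bp = 4000, fraction = 0),
                           noise_sd = 0, seed = 1)
  expect_true(all(none$log2_ratio == 0))
  part <- simulate_profile(data.frame(length_bp = 4000, fraction = 0.3),
                           noise_sd = 0, seed = 1)
  expect_equal(unique(part$log2_ratio), log2(0.85))
  expect_true(!is.unsorted(part$position, strictly = TRUE))
})

test_that("estimate_fraction inverts the forward model exactly", {
  f <- seq(0, 1, by = 0.1)
  expect_equal(estimate_fraction(log2((2 - f) / 2)), f)
  expect_identical(estimate_fraction(0), 0)
  expect_identical(estimate_fraction(-1), 1)
  expect_equal(estimate_fraction(-0.3), 0.37550, tolerance = 1e-4)
  # clipping
  expect_identical(estimate_fraction(-2), 1)
  expect_identical(estimate_fraction(0.5), 0)
})

test_that("DLR spread estimates i.i.d. probe noise and gates QC", {
  flat <- simulate_profile(data.frame(length_bp = 4000, fraction = 0),
                           noise_sd = 0, seed = 1)
  expect_identical(dlr_spread(flat), 0)
  expect_error(dlr_spread(flat[1:2, ]), "too few probes")

  big <- simulate_profile(data.frame(length_bp = 4e6, fraction = 0),
                          spacing = 400, noise_sd = 0.2, seed = 2)
  expect_equal(dlr_spread(big), 0.2, tolerance = 0.01)
  expect_true(qc_pass(big))
  noisy <- simulate_profile(data.frame(length_bp = 4e6, fraction = 0),
                            spacing = 400, noise_sd = 0.5, seed = 3)
  expect_false(qc_pass(noisy))
  expect_true(qc_pass(noisy, threshold = 0.8))
})

test_that("segmentation recovers flat, single-step and stepped profiles", {
  flat <- simulate_profile(data.frame(length_bp = 2e5, fraction = 0),
                           noise_sd = 0.1, seed = 4)
  expect_identical(nrow(segment_profile(flat)), 1L)

  one <- simulate_profile(data.frame(length_bp = c(1e5, 1e5),
                                     fraction = c(0, 1)),
                          noise_sd = 0.1, seed = 5)
  segs <- segment_profile(one)
  expect_identical(nrow(segs), 2L)
  expect_lte(abs(segs$start_idx[2] - 250L), 2L)

  fr <- p20_fractions()
  p20 <- simulate_profile(data.frame(length_bp = rep(1e5, 4),
                                     fraction = c(0, fr)),
                          noise_sd = 0.1, seed = 6)
  segs <- segment_profile(p20)
  expect_identical(nrow(segs), 4L)
  expect_true(all(abs(segs$mean_log2 - c(0, -0.3, -0.5, -0.8)) < 0.05))
  expect_true(all(abs(segs$start_idx[-1] - c(250L, 500L, 750L)) <= 2L))
})

test_that("segment means are sufficient: permuting within segments is inert", {
  fr <- p20_fractions()
  prof <- simulate_profile(data.frame(length_bp = rep(4e4, 2),
                                      fraction = c(0, fr[1])),
                           noise_sd = 0, seed = 7)
  segs <- segment_profile(prof)
  perm <- prof
  withr::with_seed(8, {
    idx <- 1:100
    perm$log2_ratio[idx] <- perm$log2_ratio[sample(idx)]
  })
  expect_identical(segment_profile(perm)$mean_log2, segs$mean_log2)
})

test_that("stepped-mosaic calls are monotone or rejected", {
  fr <- p20_fractions()
  p20 <- simulate_profile(data.frame(length_bp = rep(1e5, 4),
                                     fraction = c(0, fr)),
                          noise_sd = 0.1, seed = 9)
  call <- call_stepped_mosaic(segment_profile(p20))
  expect_true(call$monotone)
  expect_length(call$breakpoint_idx, 3L)
  expect_true(all(diff(call$fractions) > 0))
  # the intermediate step is a plausible mosaic fraction
  expect_lt(abs(call$fractions[1] - 0.375), 0.1)

  single <- simulate_profile(data.frame(length_bp = c(1e5, 1e5),
                                        fraction = c(0, 1)),
                             noise_sd = 0.1, seed = 10)
  expect_length(call_stepped_mosaic(segment_profile(single))$breakpoint_idx, 1L)

  bumpy <- simulate_profile(data.frame(length_bp = rep(1e5, 3),
                                       fraction = c(0, 0.8, 0.3)),
                            noise_sd = 0.05, seed = 11)
  bad <- call_stepped_mosaic(segment_profile(bumpy))
  expect_false(bad$monotone)
  expect_length(bad$breakpoint_idx, 0L)

  flatcall <- call_stepped_mosaic(
    segment_profile(simulate_profile(data.frame(length_bp = 2e5, fraction = 0),
                                     noise_sd = 0.1, seed = 12)))
  expect_true(flatcall$monotone)
  expect_length(flatcall$breakpoint_idx, 0L)
})

test_that("profiles round-trip through TSV", {
  prof <- simulate_profile(data.frame(length_bp = 2e4, fraction = 0.5),
                           noise_sd = 0.1, seed = 13)
  td <- withr::local_tempdir()
  path <- file.path(td, "profile.tsv")
  write_profile_tsv(prof, path)
  back <- read_profile_tsv(path)
  expect_equal(back$log2_ratio, prof$log2_ratio, tolerance = 1e-10)
  expect_identical(back$position, prof$position)
})
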