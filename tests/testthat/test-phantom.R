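test_that("baseline anatomy has the designed HU at landmarks and analytic volume", {
  spec <- phantom_spec()
  an <- generate_anatomy(spec)
  dm <- spec$dim
  centre <- an$volume$values[dm[1] / 2, dm[2] / 2, dm[3] / 2]
  expect_equal(centre, spec$soft_tissue_hu, tolerance = 1e-3)
  expect_equal(an$volume$values[1, 1, 1], -1000, tolerance = 1e-3)
  # external voxel count vs analytic elliptical-cylinder volume
  vox_vol <- prod(spec$spacing)
  analytic <- pi * spec$neck_semi_axes[1] * spec$neck_semi_axes[2] *
    (dm[3] * spec$spacing[3])
  expect_lt(abs(sum(an$external$values) * vox_vol - analytic) / analytic, 0.05)
  # CTV z-extent is exactly the configured slice range
  kz <- which(apply(an$ctv$values, 3, any))
  expect_equal(range(kz), spec$ctv_slices)
})

test_that("weight loss is zero before and at onset and erodes laterally after", {
  spec <- phantom_spec()
  base <- generate_anatomy(spec)
  expect_identical(apply_weight_loss(spec, 10, onset = 15, rate = 2)$values,
                   base$volume$values)
  expect_identical(apply_weight_loss(spec, 15, onset = 15, rate = 2)$values,
                   base$volume$values)
  expect_identical(apply_weight_loss(spec, 30, onset = 15, rate = 0)$values,
                   base$volume$values)
  # depth 10 mm: per-side lateral extent of the body reduced by 10 mm
  er <- generate_anatomy(spec, erosion = 10)
  xmax <- function(m) {
    org <- m$origin[1]; sp <- m$spacing[1]
    max(org + (which(apply(m$values, 1, any)) - 1) * sp)
  }
  reduction <- xmax(base$external) - xmax(er$external)
  expect_lt(abs(reduction - 10), spec$spacing[1] + 1e-9)
  # erosion deep enough to reach internal structures is an error
  expect_error(generate_anatomy(spec, erosion = 58), "internal structures")
})

test_that("degradation is the identity at zero settings and reproducible from seed", {
  spec <- tiny_spec()
  an <- generate_anatomy(spec)
  same <- degrade(an$volume, noise_sigma = 0, jitter_sigma = 0, seed = 5)
  expect_identical(same$values, an$volume$values)
  a <- degrade(an$volume, noise_sigma = 20, jitter_sigma = 0.3,
               ring_amplitude = 50, seed = 42)
  b <- degrade(an$volume, noise_sigma = 20, jitter_sigma = 0.3,
               ring_amplitude = 50, seed = 42)
  expect_identical(a$values, b$values)
  c <- degrade(an$volume, noise_sigma = 20, jitter_sigma = 0.3, seed = 43)
  expect_false(identical(a$values, c$values))
  expect_error(degrade(an$volume, ring_amplitude = 150), "100")
})

test_that("noise has the requested standard deviation in a uniform region", {
  spec <- phantom_spec()
  an <- generate_anatomy(spec)
  noisy <- degrade(an$volume, noise_sigma = 20, jitter_sigma = 0, seed = 99)
  # within the body no voxel sits near the [-1024, 3071] clamp, so the
  # added noise is recovered exactly by subtraction
  region <- (noisy$values - an$volume$values)[an$external$values]
  expect_gt(length(region), 1e4)
  expect_lt(abs(sd(region) - 20) / 20, 0.05)
  expect_lt(abs(mean(region)), 1)
  expect_true(all(noisy$values >= -1024 & noisy$values <= 3071))
})

test_that("the simulated order fraction follows the 10 mm cumulative-erosion rule", {
  spec <- phantom_spec()
  fr <- c(1, 4, 8, 11, 15, 18, 22, 25, 29, 32)
  cs <- course_spec(n_fractions = 32, cbct_fractions = fr, onset = 15,
                    rate = 2, noise_sigma = 0, seed = 3)
  co <- generate_course(spec, cs)
  gt <- attr(co, "ground_truth")
  # (18-15)*2 = 6 < 10; (22-15)*2 = 14 >= 10 -> order at 22
  expect_equal(gt$order_fraction, 22)
  expect_equal(gt$depths$depth, pmax(0, (fr - 15) * 2))
  expect_equal(co$segments[[1]]$rect_order_fraction, 22L)

  stable <- generate_course(spec, course_spec(seed = 4))
  expect_true(is.na(attr(stable, "ground_truth")$order_fraction))
})

test_that("courses are bit-reproducible from their seed", {
  spec <- tiny_spec()
  cs <- course_spec(n_fractions = 9, cbct_fractions = c(1, 3, 5, 7, 9),
                    onset = 5, rate = 2, noise_sigma = 20,
                    ring_amplitude = 60, seed = 1234)
  a <- generate_course(spec, cs)
  b <- generate_course(spec, cs)
  for (i in seq_along(a$segments[[1]]$volumes))
    expect_identical(a$segments[[1]]$volumes[[i]]$values,
                     b$segments[[1]]$volumes[[i]]$values)
})

test_that("gamma failure count grows monotonically on a noise-free eroding course", {
  spec <- tiny_spec()
  cs <- course_spec(n_fractions = 13, cbct_fractions = seq(1, 13, 2),
                    onset = 3, rate = 2, noise_sigma = 0, seed = 8)
  co <- generate_course(spec, cs)
  s <- suppressWarnings(
    build_mqp_series(co, gamma_criteria(3, 30), x = 80))[[1]]
  expect_true(all(diff(s$records$n_failed) >= 0))
})

test_that("cohort generation is reproducible and labelled correctly", {
  spec <- tiny_spec()
  ch <- generate_cohort(3, 2, spec = spec, n_fractions = 13,
                        cbct_fractions = seq(1, 13, 2),
                        onset_range = c(3, 5), master_seed = 7)
  expect_length(ch$courses, 5)
  expect_equal(sum(ch$labels$changer), 3)
  expect_equal(sum(!is.na(ch$labels$order_fraction)), 3)
  expect_true(all(is.na(ch$labels$order_fraction[!ch$labels$changer])))
  ch2 <- generate_cohort(3, 2, spec = spec, n_fractions = 13,
                         cbct_fractions = seq(1, 13, 2),
                         onset_range = c(3, 5), master_seed = 7)
  expect_equal(ch$labels, ch2$labels)
  expect_identical(ch$courses[[1]]$segments[[1]]$volumes[[2]]$values,
                   ch2$courses[[1]]$segments[[1]]$volumes[[2]]$values)
})

test_that("per-scan streak artifacts perturb the MQP far more than course-fixed rings", {
  # streak patterns vary scan to scan, so unlike fixed-pattern rings they
  # inject genuine HU differences between reference and evaluated scans;
  # the resulting MQP excursions reach the decision-threshold scale, which
  # is exactly why streak-affected scans can confound the alert
  spec <- phantom_spec()
  deltas <- sapply(1:2, function(s) {
    plain_cs <- course_spec(n_fractions = 9, cbct_fractions = seq(1, 9, 2),
                            noise_sigma = 20, seed = 900 + s)
    stk_cs <- course_spec(n_fractions = 9, cbct_fractions = seq(1, 9, 2),
                          noise_sigma = 20, streak_amplitude = 80,
                          n_streaks = 9, seed = 900 + s)
    p <- build_mqp_series(generate_course(spec, plain_cs),
                          gamma_criteria(3, 30), x = 80)[[1]]
    k <- build_mqp_series(generate_course(spec, stk_cs),
                          gamma_criteria(3, 30), x = 80)[[1]]
    max(abs(k$records$mqp - p$records$mqp))
  })
  expect_true(all(deltas > 0.1))  # well above the stable noise floor
  expect_true(all(deltas < 2))    # but bounded: not a runaway failure
})

test_that("course and phantom specifications validate their inputs", {
  expect_error(course_spec(n_fractions = 10, onset = 40), "onset")
  expect_error(course_spec(ring_amplitude = 101), "100")
  expect_error(phantom_spec(neck_semi_axes = c(200, 55)), "fit")
  expect_error(phantom_spec(ctv_slices = c(40, 60)), "ctv_slices")
})
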