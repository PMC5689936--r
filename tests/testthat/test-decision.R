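test_that("the three-consecutive rule fires at the record completing the run", {
  cfg <- decision_config(-0.11, run_length = 3)
  s <- fake_series(c(-0.05, -0.12, -0.13, -0.115), fractions = c(5, 8, 11, 13))
  tr <- evaluate_trigger(s, cfg)
  expect_true(tr$triggered)
  expect_equal(tr$trigger_fraction, 13)

  flat <- fake_series(rep(0, 8))
  expect_false(evaluate_trigger(flat, decision_config(-0.001))$triggered)
})

test_that("a record above threshold breaks the run and the count restarts", {
  cfg <- decision_config(-0.11, run_length = 3)
  s <- fake_series(c(-0.12, -0.12, -0.05, -0.12, -0.12, -0.12))
  tr <- evaluate_trigger(s, cfg)
  expect_equal(tr$trigger_fraction, 6)
  expect_equal(tr$trigger_fractions, 6)
})

test_that("boundary semantics: MQP equal to the threshold satisfies the rule", {
  cfg <- decision_config(-0.11, run_length = 3)
  s <- fake_series(rep(-0.11, 3))
  expect_true(evaluate_trigger(s, cfg)$triggered)
})

test_that("prepending records above threshold does not change the trigger", {
  cfg <- decision_config(-0.1, run_length = 3)
  core <- c(-0.2, -0.2, -0.2)
  s1 <- fake_series(core, fractions = 10:12)
  s2 <- fake_series(c(0, -0.05, 0.01, core), fractions = c(2, 4, 6, 10:12))
  expect_equal(evaluate_trigger(s1, cfg)$trigger_fraction,
               evaluate_trigger(s2, cfg)$trigger_fraction)
})

test_that("gaps in fraction numbering do not break a run", {
  cfg <- decision_config(-0.1, run_length = 3)
  s <- fake_series(c(-0.2, -0.2, -0.2), fractions = c(3, 11, 29))
  expect_equal(evaluate_trigger(s, cfg)$trigger_fraction, 29)
})

test_that("evaluability requires run_length comparisons beyond the reference", {
  cfg3 <- decision_config(-0.1, run_length = 3)
  cfg2 <- decision_config(-0.1, run_length = 2)
  # n CBCTs -> n - 1 comparisons, first of which is the reference
  expect_false(is_evaluable(fake_series(0), cfg3))            # 2 CBCTs
  expect_false(is_evaluable(fake_series(rep(0, 3)), cfg3))    # 4 CBCTs
  expect_true(is_evaluable(fake_series(rep(0, 4)), cfg3))     # 5 CBCTs
  expect_true(is_evaluable(fake_series(rep(0, 3)), cfg2))
})

test_that("outcomes classify against the order date with a +/-3 window", {
  cfg <- decision_config(-0.11, window = 3)
  trig_at <- function(fr) structure(
    list(triggered = length(fr) > 0,
         trigger_fraction = if (length(fr)) fr[1] else NA_integer_,
         trigger_fractions = fr, segment_id = 1L), class = "trigger_result")
  # the worked relationship: order at 22, trigger at 21 -> within 3 days
  expect_equal(classify_outcome(trig_at(21), 22, cfg), "TP")
  expect_equal(classify_outcome(trig_at(12), 22, cfg), "FP")  # premature
  expect_equal(classify_outcome(trig_at(integer()), NA, cfg), "TN")
  expect_equal(classify_outcome(trig_at(integer()), 22, cfg), "FN")
  expect_equal(classify_outcome(trig_at(28), 22, cfg), "FN")  # too late
  expect_equal(classify_outcome(trig_at(9), NA, cfg), "FP")
  # a persistently met condition: early first event but in-window event too
  expect_equal(classify_outcome(trig_at(c(12, 15, 20, 25)), 22, cfg), "TP")
  expect_equal(classify_outcome(trig_at(21), 22, cfg, evaluable = FALSE),
               "non-evaluable")
})

test_that("cohort scoring reproduces the training-tally arithmetic", {
  labels <- c(rep("TP", 9), rep("FN", 2), rep("TN", 8))
  sc <- score_cohort(labels)
  expect_equal(sc$tpf, 9 / 11)
  expect_equal(sc$fpf, 0)
  one <- score_cohort("TP")
  expect_equal(one$tpf, 1)
  expect_true(is.na(one$fpf))
  none <- score_cohort(character())
  expect_equal(none$tp + none$tn + none$fp + none$fn, 0)
  expect_true(is.na(none$tpf) && is.na(none$fpf))
  mixed <- score_cohort(c("TP", "non-evaluable", "FP", "TN"))
  expect_equal(mixed$n_non_evaluable, 1L)
})

test_that("the threshold grid is the 500-step sweep including -0.11", {
  g <- threshold_grid()
  expect_length(g, 500)
  expect_equal(g[1], -0.001)
  expect_equal(g[500], -0.5)
  expect_true(all(diff(g) < 0))
  expect_true(all(g < 0))
  expect_equal(g[110], -0.110)
})

test_that("optimum selection maximises Youden and applies the stated tie-breaks", {
  row <- function(tpf, fpf, thr = -0.1, dta = 3, dhu = 30, x = 80)
    data.frame(dta = dta, dhu = dhu, x = x, threshold = thr, tp = 0, tn = 0,
               fp = 0, fn = 0, tpf = tpf, fpf = fpf, n_non_evaluable = 0)
  # the two published operating points: (0.89, 0.20) beats (0.82, 0.25)
  tab <- rbind(row(0.89, 0.20, dta = 6), row(0.82, 0.25, dta = 3))
  opt <- select_optimum(tab)
  expect_equal(opt$tpf, 0.89)
  expect_equal(opt$youden, 0.69)

  tie <- rbind(row(0.9, 0.2, thr = -0.10), row(0.9, 0.2, thr = -0.20))
  expect_equal(select_optimum(tie)$threshold, -0.20)

  single <- row(0.5, 0.1)
  expect_equal(select_optimum(single)$tpf, 0.5)

  # permutation invariance
  set.seed(4)
  tab2 <- rbind(row(0.7, 0.1), row(0.9, 0.4, dhu = 60), row(0.8, 0.2, x = 75),
                row(0.6, 0.0, thr = -0.3))
  o1 <- select_optimum(tab2)
  o2 <- select_optimum(tab2[sample(nrow(tab2)), ])
  expect_equal(o1, o2)

  allna <- row(NA_real_, NA_real_)
  expect_error(select_optimum(allna), "defined")
})

test_that("the sweep's cached trigger bookkeeping matches evaluate_trigger", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    mqp <- round(rnorm(n, -0.1, 0.15), 3)
    s <- fake_series(mqp, fractions = sort(sample(1:35, n)))
    thr <- c(-0.01, -0.1, -0.25, -0.5)
    hits <- anatgamma:::trigger_fractions_by_threshold(s$records, thr, 3)
    for (ti in seq_along(thr)) {
      tr <- evaluate_trigger(s, decision_config(thr[ti], 3))
      expect_identical(hits[[ti]], tr$trigger_fractions)
    }
  }
})

test_that("roc_sweep on a small cohort is monotone in threshold and conserves counts", {
  spec <- tiny_spec()
  mk_course <- function(onset, seed, id) {
    cs <- course_spec(n_fractions = 17, cbct_fractions = seq(1, 17, 2),
                      onset = onset, rate = if (is.na(onset)) 0 else 2,
                      noise_sigma = 20, seed = seed)
    generate_course(spec, cs, patient_id = id)
  }
  cohort <- list(mk_course(7, 1, "c1"), mk_course(9, 2, "c2"),
                 mk_course(NA, 3, "s1"), mk_course(NA, 4, "s2"))
  thr <- seq(-0.01, -0.5, by = -0.01)
  tab <- suppressWarnings(
    roc_sweep(cohort, dta_grid = 3, dhu_grid = 30, percentile_grid = c(70, 80),
              thresholds = thr))
  expect_equal(nrow(tab), 2 * length(thr))
  for (x in c(70, 80)) {
    sub <- tab[tab$x == x, ]
    expect_false(is.unsorted(rev(sub$tpf)))  # non-increasing as thr decreases
    expect_false(is.unsorted(rev(sub$fpf)))
  }
  # conservation: every evaluable segment is counted exactly once
  expect_true(all(tab$tp + tab$tn + tab$fp + tab$fn + tab$n_non_evaluable == 4))
})
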