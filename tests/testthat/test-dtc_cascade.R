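test_that("fit_dtc matches the worked examples", {
  d <- fit_dtc(c(0, 1), c(3, 4), theta = 0)
  expect_equal(d$interval$lower, 1)
  expect_equal(d$interval$upper, 3)
  expect_equal(d$interval$point, 2)
  # boundary convention: x >= tau goes right
  expect_identical(dtc_classify(d, 3), "right")
  expect_identical(dtc_classify(d, 1.99), "left")
  # one misclassification allowed per side at theta = 1/3
  d2 <- fit_dtc(c(0, 1, 2.5), c(2, 3, 4), theta = 1 / 3)
  expect_equal(d2$interval$lower, 1)
  expect_equal(d2$interval$upper, 3)
  # full overlap rejects
  expect_null(fit_dtc(c(0, 1, 2), c(0, 1, 2), theta = 0))
  expect_error(fit_dtc(numeric(0), 1, 0), "empty")
  expect_error(fit_dtc(0, 1, theta = 0.7), "theta")
})

test_that("fit_dtc feasible interval equals the exhaustive sweep oracle", {
  set.seed(31)
  for (rep in 1:40) {
    theta <- sample(c(0, 0.1, 0.2), 1)
    nl <- sample(3:15, 1); nr <- sample(3:15, 1)
    left <- round(runif(nl, 0, 10), 1)   # rounding provokes ties
    right <- round(runif(nr, 2, 12), 1)
    d <- fit_dtc(left, right, theta)
    grid <- dtc_candidate_grid(left, right)
    feas <- vapply(grid, dtc_feasible_at, logical(1), left, right, theta)
    if (is.null(d)) {
      expect_false(any(feas))
    } else {
      inside <- grid > d$interval$lower & grid <= d$interval$upper
      expect_identical(feas, inside)
      # maximality at the endpoints
      expect_false(dtc_feasible_at(d$interval$lower, left, right, theta))
      expect_true(dtc_feasible_at(d$interval$upper, left, right, theta))
      # training sensitivities at the point respect the budget
      expect_gte(d$left_sens, 1 - theta)
      expect_gte(d$right_sens, 1 - theta)
    }
  }
})

test_that("cascades fit, reject, and respect monotone thresholds", {
  fx <- make_figure4_fixture(20, seed = 12)
  proj <- fit_projection(fx$dataset, c("l0", "l5"))
  cas <- fit_cascade(proj, paste0("l", 0:5), theta = 0)
  expect_s3_class(cas, "cascade")
  expect_true(all(diff(cas$thresholds) > 0))
  expect_true(all(cas$sensitivities == 1))
  # overlapping adjacent pair rejects at position 1
  rej <- fit_cascade(proj, c("l2", "l7", "l3"), theta = 0)
  expect_s3_class(rej, "cascade_reject")
  expect_equal(rej$position, 1L)
  # length-2 cascade on disjoint classes has one threshold
  cas2 <- fit_cascade(proj, c("l0", "l1"), theta = 0)
  expect_length(cas2$thresholds, 1L)
  expect_error(fit_cascade(proj, c("l0", "ghost")), "unknown")
  expect_error(fit_cascade(proj, "l0"), "two labels")
})

test_that("non-monotone threshold points are rejected", {
  # at theta = 0 consecutive feasible intervals are automatically ordered,
  # so a violation needs theta > 0: trimmed order statistics can put the
  # second point below the first
  pj <- projected_from_values(c(4.9, 4.95, 4, 5, -10, 4.5),
                              c("a", "a", "b", "b", "c", "c"))
  rej <- fit_cascade(pj, c("a", "b", "c"), theta = 0.5)
  expect_s3_class(rej, "cascade_reject")
  expect_identical(rej$reason, "non-monotone")
  expect_equal(rej$position, 2L)
})

test_that("sequential walk and interval lookup agree everywhere", {
  pj <- projected_from_values(c(0, 1, 3, 4, 6, 7),
                              c("a", "a", "b", "b", "c", "c"))
  cas <- fit_cascade(pj, c("a", "b", "c"), 0)
  expect_equal(cas$thresholds, c(2, 5))
  expect_identical(cascade_predict(cas, c(1, 2, 7)), c("a", "b", "c"))
  set.seed(77)
  x <- c(runif(2e4, -5, 12), cas$thresholds, cas$thresholds - 1e-12)
  expect_identical(cascade_predict(cas, x, "interval"),
                   cascade_predict(cas, x, "sequential"))
  # single-classifier cascade behaves as its DTC
  cas2 <- fit_cascade(pj, c("a", "b"), 0)
  d <- cas2$classifiers[[1]]
  expect_identical(cascade_predict(cas2, x), dtc_classify(d, x))
})

test_that("class-wise sensitivity counts per-class correct assignments", {
  # class b of 10 with one sample across the threshold
  pj <- projected_from_values(c(seq(0, 0.9, by = 0.1),
                                c(1.05, seq(2, 2.8, by = 0.1))),
                              rep(c("a", "b"), each = 10))
  cas <- fit_cascade(pj, c("a", "b"), theta = 0.1)
  expect_s3_class(cas, "cascade")
  sens <- classwise_sensitivity(cas, pj)
  expect_equal(unname(sens["b"]), 0.9)
  expect_equal(unname(sens["a"]), 1)
  # perfectly separated classes: all sensitivities 1
  pj2 <- projected_from_values(c(0, 1, 5, 6), c("a", "a", "b", "b"))
  cas2 <- fit_cascade(pj2, c("a", "b"), 0)
  expect_true(all(classwise_sensitivity(cas2, pj2) == 1))
})

test_that("accepted cascades always satisfy the sensitivity floor", {
  set.seed(41)
  for (rep in 1:20) {
    theta <- sample(c(0, 0.1, 0.2), 1)
    iv <- random_interval_layout(4, seed = rep + 100)
    pj <- projected_from_intervals(iv, n_per_class = 10, seed = rep)
    labs <- names(iv)
    ords <- list(labs, rev(labs), sample(labs))
    for (o in ords) {
      cas <- fit_cascade(pj, o, theta)
      if (inherits(cas, "cascade")) {
        expect_gte(min(cas$sensitivities), 1 - theta - 1e-12)
        expect_true(all(diff(cas$thresholds) > 0))
      }
    }
  }
})
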