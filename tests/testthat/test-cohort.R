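test_that("gap-time construction follows the W_k = T_k - T_{k-1} rule", {
  ep <- build_gap_times(c(0, 3, 7), follow_up = 12)
  expect_equal(ep$w, c(3, 4, 5))
  expect_equal(ep$delta, c(1, 1, 0))
  expect_equal(ep$k, 1:3)

  # no recurrence: a single censored gap spanning follow-up
  ep0 <- build_gap_times(0, follow_up = 10)
  expect_equal(ep0$w, 10)
  expect_equal(ep0$delta, 0)

  # follow-up ending exactly at the last event: no censored tail
  ep2 <- build_gap_times(c(0, 4, 9), follow_up = 9)
  expect_equal(ep2$delta, c(1, 1))

  expect_error(build_gap_times(c(0, 5, 3), 10), "increasing")
  expect_error(build_gap_times(c(1, 5), 10), "must be 0")
  expect_error(build_gap_times(c(0, 5), 4), "before the last event")
})

test_that("gap times conserve total follow-up across random histories", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(0:6, 1)
    times <- c(0, sort(runif(k, 0.01, 30)))
    fu <- max(times) + rexp(1, 1 / 5)
    ep <- build_gap_times(times, fu)
    expect_equal(sum(ep$w), fu, tolerance = 1e-12)
    expect_true(all(ep$w > 0))
  }
})

test_that("cohort validation reports every violated invariant without mutating", {
  s1 <- make_subject("A")
  s2 <- make_subject("B", event_times = 0, follow_up = 8, t = c(0, 2),
                     titer = c(5, 7))
  s3 <- make_subject("C")
  ch <- new_cohort(list(s1, s2, s3))
  expect_s3_class(validate_cohort(ch), "jm_validation")
  expect_equal(nrow(validate_cohort(ch)), 0)

  # censored episode followed by another episode
  bad <- ch
  bad$subjects[["B"]]$episodes <- data.frame(k = 1:2, w = c(4, 4),
                                             delta = c(0, 1))
  rep <- validate_cohort(bad)
  expect_true("censoring_terminal" %in% rep$rule)
  expect_true("B" %in% rep$subject_id)
  expect_error(validate_cohort(bad, stop_on_error = TRUE), "invalid cohort")

  # duplicate ids are caught at construction
  expect_error(new_cohort(list(s1, make_subject("A"))), "duplicate")

  # several simultaneous problems are all reported
  ugly <- ch
  ugly$subjects[["C"]]$episodes$w[1] <- -2
  ugly$subjects[["C"]]$episodes$k <- c(2, 3)
  ugly$subjects[["C"]]$observations$y[1] <- 99
  rep2 <- validate_cohort(ugly)
  expect_setequal(
    intersect(c("gap_positive", "episode_indexing", "transform_consistency"),
              rep2$rule),
    c("gap_positive", "episode_indexing", "transform_consistency"))
})

test_that("covariate indicators must be coded 0/1", {
  expect_error(subject_covariates(50, 2, 0, 0, 30, 10), "male")
  expect_error(subject_covariates(50, 1, 0.5, 0, 30, 10), "single")
  expect_error(subject_covariates(50, 1, 0, 0, 30, -1), "follow_up")
})
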