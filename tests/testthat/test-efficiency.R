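test_that("termination efficiency matches the closed form on step tracks", {
  tr <- make_step_track(10, 0)
  expect_equal(termination_efficiency(list(tr), 30, "+")$T, 100)

  tr2 <- make_step_track(8, 2)
  r <- termination_efficiency(list(tr2), 30, "+")
  expect_equal(r$T, 75)
  expect_equal(r$u, 8)
  expect_equal(r$d, 2)
  expect_true(r$evaluable)
})

test_that("low upstream coverage is not evaluable at the default 0.25", {
  tr <- make_step_track(0.2, 0.1)
  r <- termination_efficiency(list(tr), 30, "+")
  expect_false(r$evaluable)
  expect_equal(r$reason, "low_upstream_coverage")
  expect_true(is.na(r$T))
  # boundary: exactly at threshold counts as evaluable
  tr2 <- make_step_track(0.25, 0.1)
  expect_true(termination_efficiency(list(tr2), 30, "+")$evaluable)
})

test_that("T is scale-invariant but evaluability is absolute", {
  tr <- make_step_track(4, 1)
  t1 <- termination_efficiency(list(tr), 30, "+")$T
  tr_big <- coverage_track("c", "+", tr$values * 7)
  expect_equal(termination_efficiency(list(tr_big), 30, "+")$T, t1)
  tr_tiny <- coverage_track("c", "+", tr$values * 0.01)
  expect_false(termination_efficiency(list(tr_tiny), 30, "+")$evaluable)
})

test_that("windows exclude the three summit-proximal positions", {
  # signal only inside the excluded +-3 zone must not contribute
  v <- numeric(60)
  v[27:33] <- 100           # within 3 nt of summit 30
  v[17:26] <- 8             # upstream window 17..26 on +
  v[34:43] <- 2             # downstream window 34..43
  tr <- coverage_track("c", "+", v)
  r <- termination_efficiency(list(tr), 30, "+")
  expect_equal(r$u, 8)
  expect_equal(r$d, 2)
  expect_equal(r$T, 75)
})

test_that("minus-strand windows mirror the plus-strand computation", {
  tr_plus <- make_step_track(8, 2, strand = "+")
  tr_minus <- make_step_track(8, 2, strand = "-", summit = 31)
  rp <- termination_efficiency(list(tr_plus), 30, "+")
  rm <- termination_efficiency(list(tr_minus), 31, "-")
  expect_equal(rm$T, rp$T)
  expect_equal(rm$u, rp$u)
})

test_that("negative efficiencies flag readthrough gain, edges flagged", {
  tr <- make_step_track(2, 6)
  r <- termination_efficiency(list(tr), 30, "+")
  expect_lt(r$T, 0)
  expect_true(r$readthrough_gain)

  edge <- termination_efficiency(list(make_step_track(8, 2)), 5, "+")
  expect_false(edge$evaluable)
  expect_equal(edge$reason, "window_out_of_bounds")
})

test_that("planted efficiencies are recovered from noisy replicates", {
  set.seed(13)
  n_sites <- 50
  errs <- vapply(seq_len(n_sites), function(i) {
    t_true <- runif(1, 20, 95)
    level <- runif(1, 30, 120)
    reps <- lapply(1:3, function(r) {
      v <- c(rpois(30, level), rpois(30, level * (1 - t_true / 100)))
      coverage_track("c", "+", v)
    })
    termination_efficiency(reps, 30, "+", threshold = 1)$T - t_true
  }, numeric(1))
  expect_lt(mean(abs(errs)), 5)
  expect_gte(mean(abs(errs) <= 5), 0.9)
})
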