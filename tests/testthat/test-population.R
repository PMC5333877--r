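test_that("R0 and GRR follow their defining sums", {
  s <- sched_of(lx = c(1, 1), mx = c(0, 5))
  expect_equal(net_reproductive_rate(s), 5)
  expect_equal(gross_reproductive_rate(s), 5)
  s2 <- sched_of(lx = c(1, 0.5, 0.25), mx = c(0, 5, 3))
  expect_equal(net_reproductive_rate(s2), 3.25)
  expect_equal(gross_reproductive_rate(s2), 8)
  expect_equal(net_reproductive_rate(sched_of(c(1, 1), c(0, 0))), 0)
})

test_that("R0 equals female fraction times mean female fecundity", {
  # 10 eggs, 4 become laying females (50 eggs each), rest lay nothing
  sc <- toy_scheme()
  mk <- function(id, sex, eggs = NULL) rec1(id, sex,
    c(egg = 2, L1 = 2, L2 = 2, pupa = 2), "adult", 10,
    if (!is.null(eggs)) data.frame(age = 10, eggs = eggs))
  cht <- cohort(c(lapply(1:4, function(i) mk(paste0("f", i), "female", 50)),
                  lapply(1:6, function(i) mk(paste0("m", i), "male"))), sc)
  expect_equal(net_reproductive_rate(life_schedule(cht)), (4 / 10) * 50)
})

test_that("GRR is at least R0, with equality only without mortality", {
  set.seed(42)
  for (i in 1:20) {
    cht <- random_cohort(sample(5:15, 1))
    s <- life_schedule(cht)
    expect_gte(gross_reproductive_rate(s) - net_reproductive_rate(s), -1e-12)
  }
  deathless <- sched_of(lx = rep(1, 4), mx = c(0, 1, 2, 1))
  expect_equal(gross_reproductive_rate(deathless),
               net_reproductive_rate(deathless))
  lossy <- sched_of(lx = c(1, 0.5), mx = c(0, 2))
  expect_gt(gross_reproductive_rate(lossy), net_reproductive_rate(lossy))
})

test_that("the Euler-Lotka solver hits closed-form cases exactly", {
  # single pulse of e^2 eggs at age 0: e^{-r} e^2 = 1 -> r = 2
  expect_equal(intrinsic_rate(sched_of(1, exp(2))), 2, tolerance = 1e-10)
  # 2 e^{-2r} + 4 e^{-3r} = 1 at r = ln 2
  expect_equal(intrinsic_rate(sched_of(c(1, 1, 1), c(0, 2, 4))), log(2),
               tolerance = 1e-10)
  # declining population: pulse of 0.5 at age 0 -> r = ln(1/2) < 0
  expect_equal(intrinsic_rate(sched_of(1, 0.5)), -log(2), tolerance = 1e-10)
  # general pulse: r = ln(M)/(x+1)
  s <- sched_of(lx = c(1, 1, 1, 1), mx = c(0, 0, 0, 9))
  expect_equal(intrinsic_rate(s), log(9) / 4, tolerance = 1e-10)
  expect_error(intrinsic_rate(sched_of(c(1, 1), c(0, 0))), "R0 = 0")
})

test_that("the solver agrees with a fine-grid scan on random schedules", {
  set.seed(77)
  for (i in 1:12) {
    n <- sample(5:30, 1)
    lx <- cumprod(c(1, runif(n - 1, 0.7, 1)))
    mx <- c(rep(0, 3), rpois(n - 3, 2)) * runif(n, 0, 2)
    if (sum(lx * mx) == 0) mx[4] <- 1
    s <- sched_of(lx, mx)
    r <- intrinsic_rate(s)
    expect_equal(r, grid_r_oracle(s$age, lx * mx), tolerance = 1e-6)
    # residual of the defining equation
    expect_lt(abs(sum(exp(-r * (s$age + 1)) * lx * mx) - 1), 1e-10)
  }
})

test_that("the sign of r matches R0 relative to one", {
  above <- sched_of(c(1, 0.9, 0.8), c(0, 1, 0.5))   # R0 = 1.3
  below <- sched_of(c(1, 0.5, 0.2), c(0, 1, 0.5))   # R0 = 0.6
  expect_gt(intrinsic_rate(above), 0)
  expect_lt(intrinsic_rate(below), 0)
  # R0 tuned to exactly 1 -> r = 0
  exact <- sched_of(c(1, 0.5, 0.25), c(0, 1, 2))
  expect_equal(net_reproductive_rate(exact), 1)
  expect_equal(intrinsic_rate(exact), 0, tolerance = 1e-10)
})

test_that("lambda and T are exact transforms of r and R0", {
  expect_equal(finite_rate(0), 1)
  expect_equal(finite_rate(log(2)), 2)
  expect_equal(mean_generation_time(exp(1), 1), 1)
  expect_error(mean_generation_time(0, 0.1), "R0")
  expect_error(mean_generation_time(2, 0), "r = 0")
  set.seed(88)
  for (i in 1:8) {
    cht <- random_cohort(12)
    s <- life_schedule(cht)
    if (net_reproductive_rate(s) <= 0) next
    pp <- population_params(s)
    expect_equal(pp$lambda, exp(pp$r))
    if (!is.na(pp$T)) expect_equal(pp$T, log(pp$R0) / pp$r)
  }
})

test_that("a cohort of identical clones bootstraps to zero SE", {
  sc <- toy_scheme()
  clone <- function(i) rec1(paste0("c", i), "female",
    c(egg = 2, L1 = 2, L2 = 2, pupa = 2), "adult", 6,
    data.frame(age = c(9, 10), eggs = c(3, 4)))
  cht <- cohort(lapply(1:12, clone), sc)
  b <- bootstrap_params(cht, B = 50, seed = 3)
  expect_equal(unname(b$se), rep(0, 5))
  expect_equal(b$n_degenerate, 0)
})

test_that("bootstrap runs are reproducible and need a seed", {
  cht <- simulate_cohort(study_spec(27, n0 = 60), seed = 2)
  b1 <- bootstrap_params(cht, B = 80, seed = 5)
  b2 <- bootstrap_params(cht, B = 80, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$se, b2$se)
  b3 <- bootstrap_params(cht, B = 80, seed = 6)
  expect_false(identical(b1$se, b3$se))
  expect_error(bootstrap_params(cht, B = 80), "seed")
})

test_that("the weighted bootstrap path equals rerunning the pipeline", {
  cht <- simulate_cohort(study_spec(24, n0 = 40), seed = 8)
  arr <- agestage:::cohort_boot_arrays(cht)
  set.seed(31)
  W <- stats::rmultinom(6, cht$n0, rep(1 / cht$n0, cht$n0))
  fast <- agestage:::boot_from_weights(arr, W)
  for (b in seq_len(ncol(W))) {
    idx <- rep(seq_len(cht$n0), W[, b])
    recs <- lapply(seq_along(idx), function(k) {
      r <- cht$records[[idx[k]]]
      r$id <- paste0(r$id, "_", k)
      r
    })
    s <- life_schedule(cohort(recs, cht$scheme))
    expect_equal(fast$R0[b], net_reproductive_rate(s), tolerance = 1e-12)
    expect_equal(fast$GRR[b], gross_reproductive_rate(s), tolerance = 1e-12)
    if (fast$R0[b] > 0)
      expect_equal(fast$r[b], intrinsic_rate(s), tolerance = 1e-9)
  }
})

test_that("degenerate replicates are counted and excluded from rates", {
  sc <- toy_scheme()
  # one laying female among many sterile males: resamples often miss her
  f <- rec1("f", "female", c(egg = 1, L1 = 1, L2 = 1, pupa = 1), "adult", 3,
            data.frame(age = 5, eggs = 8))
  ms <- lapply(1:7, function(i) rec1(paste0("m", i), "male",
    c(egg = 1, L1 = 1, L2 = 1, pupa = 1), "adult", 3))
  cht <- cohort(c(list(f), ms), sc)
  expect_warning(b <- bootstrap_params(cht, B = 200, seed = 4),
                 "no reproduction")
  expect_gt(b$n_degenerate, 0)
  expect_equal(sum(is.na(b$replicates$r)), b$n_degenerate)
  expect_false(anyNA(b$replicates$R0))
  expect_false(anyNA(b$se))
})

test_that("bootstrap SEs are stable across independent seeds", {
  cht <- simulate_cohort(study_spec(27), seed = 12)
  b1 <- bootstrap_params(cht, B = 2000, seed = 101)
  b2 <- bootstrap_params(cht, B = 2000, seed = 202)
  rel <- abs(b1$se - b2$se) / b1$se
  expect_true(all(rel < 0.15))
})
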