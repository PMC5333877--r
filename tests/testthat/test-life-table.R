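test_that("the census matrix follows one individual's stage intervals", {
  # egg 2 d (ages 0-1), L1 1 d (age 2), dies entering L2
  sc <- toy_scheme()
  cht <- cohort(list(
    rec1("a", "undetermined", c(egg = 2, L1 = 1), "L2", 0)
  ), sc)
  m <- build_age_stage_survival(cht)
  expect_equal(nrow(m), 3)
  expect_equal(unname(m[1, "egg"]), 1)
  expect_equal(unname(m[2, "egg"]), 1)
  expect_equal(unname(m[3, "L1"]), 1)
  expect_equal(sum(m), 3)  # no other occupancy
})

test_that("the census matrix equals a brute-force daily head-count", {
  set.seed(404)
  for (i in 1:15) {
    cht <- random_cohort(sample(4:20, 1))
    m <- build_age_stage_survival(cht)
    expect_equal(unclass(m)[, ], census_oracle(cht), ignore_attr = TRUE)
    # every entry is a multiple of 1/n0
    expect_true(all(abs(m * cht$n0 - round(m * cht$n0)) < 1e-12))
  }
})

test_that("row sums give l_x: non-increasing, l_0 = 1, counting identity", {
  set.seed(405)
  for (i in 1:10) {
    cht <- random_cohort(sample(5:20, 1))
    m <- build_age_stage_survival(cht)
    lx <- age_specific_survival(m)
    expect_equal(lx[1], 1)
    expect_true(all(diff(lx) <= 1e-12))
    deaths <- vapply(cht$records, death_age, integer(1))
    expect_equal(lx, vapply(attr(m, "ages"), function(x)
      mean(deaths > x), numeric(1)))
  }
})

test_that("survivors sum to 1 until the first death", {
  sc <- toy_scheme()
  cht <- cohort(list(
    rec1("a", "female", c(egg = 2, L1 = 2, L2 = 2, pupa = 2), "adult", 4),
    rec1("b", "male", c(egg = 1, L1 = 3, L2 = 2, pupa = 2), "adult", 6)
  ), sc)
  m <- build_age_stage_survival(cht)
  lx <- age_specific_survival(m)
  expect_true(all(lx[1:12] == 1))  # both live 12 days; first dies at age 12
})

test_that("f_x averages eggs over live adult females, 0/0 giving 0", {
  sc <- toy_scheme()
  mk <- function(id, eggs30) rec1(id, "female",
    c(egg = 5, L1 = 5, L2 = 5, pupa = 10), "adult", 10,
    data.frame(age = 30, eggs = eggs30))
  cht <- cohort(list(mk("f1", 10), mk("f2", 20),
                     rec1("m1", "male", c(egg = 5, L1 = 5, L2 = 5,
                                          pupa = 10), "adult", 3)), sc)
  m <- build_age_stage_survival(cht)
  f <- age_stage_fecundity(cht, m)
  expect_equal(f[31], 15)           # (10+20)/2 females alive at age 30
  expect_equal(f[m[, "adult female"] == 0],
               rep(0, sum(m[, "adult female"] == 0)))
  # m_x divides by all survivors: only the 2 females remain at age 30
  mx <- age_specific_fecundity(m, f)
  expect_equal(mx[31], 15)
  # at an age where the male is also alive, the denominator includes him
  cht2 <- cohort(list(mk("f1", 10), mk("f2", 20),
                      rec1("m1", "male", c(egg = 5, L1 = 5, L2 = 5,
                                           pupa = 10), "adult", 10),
                      rec1("m2", "male", c(egg = 5, L1 = 5, L2 = 5,
                                           pupa = 10), "adult", 10)), sc)
  m2 <- build_age_stage_survival(cht2)
  mx2 <- age_specific_fecundity(m2, age_stage_fecundity(cht2, m2))
  expect_equal(mx2[31], 30 / 4)
})

test_that("an all-female cohort has m_x = f_x", {
  sc <- toy_scheme()
  cht <- cohort(list(
    rec1("f1", "female", c(egg = 2, L1 = 2, L2 = 2, pupa = 2), "adult", 5,
         data.frame(age = 9, eggs = 6)),
    rec1("f2", "female", c(egg = 2, L1 = 2, L2 = 2, pupa = 2), "adult", 5,
         data.frame(age = 10, eggs = 4))
  ), sc)
  m <- build_age_stage_survival(cht)
  f <- age_stage_fecundity(cht, m)
  expect_equal(age_specific_fecundity(m, f), unname(f))
})

test_that("net maternity conserves the cohort's total eggs", {
  set.seed(406)
  for (i in 1:10) {
    cht <- random_cohort(sample(5:20, 1))
    s <- life_schedule(cht)
    total <- sum(vapply(cht$records, function(r) sum(r$fecundity$eggs),
                        numeric(1)))
    expect_equal(cht$n0 * sum(s$lxmx), total, tolerance = 1e-12)
    expect_equal(attr(s, "total_eggs"), total)
  }
})

test_that("stage duration summaries use completers only", {
  sc <- toy_scheme()
  cht <- cohort(list(
    rec1("a", "undetermined", c(egg = 2), "L1", 3),
    rec1("b", "undetermined", c(egg = 4), "L1", 1),
    rec1("c", "undetermined", integer(0), "egg", 2)
  ), sc)
  sm <- stage_duration_summary(cht)$stages
  egg <- sm[sm$stage == "egg", ]
  # the egg-death individual is excluded from the egg mean
  expect_equal(egg$n, 2)
  expect_equal(egg$mean, 3)
  expect_equal(egg$se, 1)  # sd(c(2,4))/sqrt(2) = sqrt(2)/sqrt(2)... = 1
  expect_equal(sm[sm$stage == "L1", "n"], 0)
})

test_that("pre-adult duration, longevity and lifespan split by sex", {
  sc <- toy_scheme()
  cht <- cohort(list(
    rec1("f", "female", c(egg = 2, L1 = 3, L2 = 3, pupa = 4), "adult", 10),
    rec1("m", "male", c(egg = 2, L1 = 2, L2 = 4, pupa = 4), "adult", 20),
    rec1("d", "undetermined", c(egg = 2), "L1", 1)
  ), sc)
  sm <- stage_duration_summary(cht)
  expect_equal(sm$stages[sm$stages$stage == "preadult", "mean"], 12)
  ad <- sm$adults
  expect_equal(ad[ad$measure == "adult longevity" & ad$sex == "female",
                  "mean"], 10)
  expect_equal(ad[ad$measure == "entire lifespan" & ad$sex == "male",
                  "mean"], 32)
  expect_equal(sm$immature_mortality_pct, 100 / 3)
})

test_that("immature mortality is deaths before adulthood over n0", {
  sc <- toy_scheme()
  adults <- lapply(1:127, function(i)
    rec1(paste0("a", i), "male", c(egg = 2, L1 = 2, L2 = 2, pupa = 2),
         "adult", 3))
  dead <- lapply(1:23, function(i)
    rec1(paste0("d", i), "undetermined", integer(0), "egg", 1))
  cht <- cohort(c(adults, dead), sc)
  expect_equal(cht$n0, 150)
  expect_equal(immature_mortality(cht), 100 * 23 / 150)
  expect_equal(immature_mortality(cohort(adults, sc)), 0)
  expect_equal(immature_mortality(cohort(dead, sc)), 100)
})

test_that("reproduction timing follows the APOP/TPOP definitions", {
  sc <- toy_scheme()
  # emerges at age 20, first egg at 22, last at 30
  f <- rec1("f", "female", c(egg = 5, L1 = 5, L2 = 5, pupa = 5), "adult",
            15, data.frame(age = c(22, 23, 25, 30), eggs = c(3, 1, 2, 5)))
  cht <- cohort(list(f), sc)
  rs <- reproduction_summary(cht)
  expect_false(rs$empty)
  expect_equal(rs$per_female$apop, 2)
  expect_equal(rs$per_female$tpop, 22)
  expect_equal(rs$per_female$oviposition_days, 9)   # 22..30 span
  expect_equal(rs$per_female$total_eggs, 11)
  active <- reproduction_summary(cht, period = "active")
  expect_equal(active$per_female$oviposition_days, 4)

  # gap days count under the span convention
  g <- rec1("g", "female", c(egg = 5, L1 = 5, L2 = 5, pupa = 5), "adult",
            15, data.frame(age = c(22, 23, 25), eggs = c(1, 1, 1)))
  rs2 <- reproduction_summary(cohort(list(g), sc))
  expect_equal(rs2$per_female$oviposition_days, 4)

  # no reproducing female -> flagged empty
  m <- rec1("m", "male", c(egg = 5, L1 = 5, L2 = 5, pupa = 5), "adult", 5)
  expect_true(reproduction_summary(cohort(list(m), sc))$empty)
})

test_that("forced pre-oviposition delays are recovered exactly", {
  sp <- study_spec(27, n0 = 80)
  sp$apop <- day_pmf(1, 1)          # every female starts laying 1 d in
  sp$dispersion <- "none"           # deterministic counts, no zero days
  cht <- simulate_cohort(sp, seed = 9)
  rs <- reproduction_summary(cht)
  expect_true(rs$n_females > 10)
  expect_equal(unique(rs$per_female$apop), 1)
  expect_equal(rs$summary[rs$summary$measure == "apop", "se"], 0)
})
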