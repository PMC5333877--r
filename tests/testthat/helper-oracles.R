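# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately recompute quantities by a different route than
# the package (explicit per-day walks, grid scans, normal equations).

# stage occupied by a record on day x (0-based age), or NA if dead:
# expand the life history into one label per day lived and index it
day_stage <- function(rec, x) {
  labels <- c(rep(names(rec$stage_durations), rec$stage_durations),
              rep(rec$death_stage, rec$days_in_death_stage))
  if (x + 1 > length(labels)) NA_character_ else labels[x + 1]
}

# brute-force daily census: head-count per (age, stage)/n0 with the adult
# column split by sex, matching build_age_stage_survival's layout
census_oracle <- function(cht) {
  amax <- max(vapply(cht$records, death_age, integer(1)))
  cols <- c(setdiff(cht$scheme$stages, "adult"), "adult female", "adult male")
  m <- matrix(0, amax, length(cols), dimnames = list(NULL, cols))
  for (x in 0:(amax - 1)) {
    for (rec in cht$records) {
      s <- day_stage(rec, x)
      if (is.na(s)) next
      col <- if (s == "adult") paste("adult", rec$sex) else s
      m[x + 1, col] <- m[x + 1, col] + 1
    }
  }
  m / cht$n0
}

# two-stage fine-grid scan for the Euler-Lotka root, independent of the
# package's bisection
grid_r_oracle <- function(age, lxmx) {
  g <- function(r) vapply(r, function(ri)
    sum(exp(-ri * (age + 1)) * lxmx) - 1, numeric(1))
  lo <- -2; hi <- 2
  while (g(lo) < 0) lo <- lo * 2
  while (g(hi) > 0) hi <- hi * 2
  grid <- seq(lo, hi, length.out = 40001)
  best <- grid[which.min(abs(g(grid)))]
  step <- grid[2] - grid[1]
  fine <- seq(best - step, best + step, length.out = 40001)
  fine[which.min(abs(g(fine)))]
}

# closed-form simple linear regression via normal equations
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r2 = r2)
}

# a random but always-valid cohort built directly from records (no use of
# the package's simulator), for property tests
random_cohort <- function(n, scheme = stage_scheme(c("egg", "L1", "pupa",
                                                     "adult"))) {
  stages <- scheme$stages
  records <- lapply(seq_len(n), function(i) {
    k <- sample(length(stages), 1)        # death stage index
    death <- stages[k]
    dur <- if (k > 1) {
      stats::setNames(sample(1:4, k - 1, replace = TRUE),
                      stages[seq_len(k - 1)])
    } else {
      integer(0)
    }
    sex <- if (death == "adult") sample(c("female", "male"), 1)
           else "undetermined"
    died <- sample(1:5, 1)
    fec <- NULL
    if (sex == "female") {
      emerge <- sum(dur)
      ages <- seq(emerge, emerge + died - 1)
      eggs <- stats::rpois(length(ages), 3)
      keep <- eggs > 0
      if (any(keep)) fec <- data.frame(age = ages[keep], eggs = eggs[keep])
    }
    individual_record(paste0("r", i), "test", sex, dur, death, died, fec)
  })
  cohort(records, scheme, "test")
}

# single-record shorthand
rec1 <- function(id, sex, dur, death, died, fec = NULL,
                 treatment = "toy") {
  individual_record(id, treatment, sex, dur, death, died, fec)
}

toy_scheme <- function() stage_scheme(c("egg", "L1", "L2", "pupa", "adult"))

# a life_schedule-shaped data frame from raw vectors
sched_of <- function(lx, mx) {
  data.frame(age = seq_along(lx) - 1, lx = lx, mx = mx)
}
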