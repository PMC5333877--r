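#' Probability mass function over whole days
#'
#' Small helper for building the day-valued distributions a
#' \code{\link{cohort_spec}} is made of: a named numeric vector whose
#' names are integer day values and whose values sum to one.
#'
#' @param days integer day values
#' @param prob probabilities (default uniform)
#' @return named numeric pmf
#' @export
day_pmf <- function(days, prob = NULL) {
  if (is.null(prob)) prob <- rep(1 / length(days), length(days))
  stopifnot(length(days) == length(prob), all(prob >= 0),
            abs(sum(prob) - 1) < 1e-8, all(days == floor(days)))
  stats::setNames(prob / sum(prob), as.character(as.integer(days)))
}

#' Two- or three-point day pmf with an exact mean
#'
#' Discretises a continuous mean duration onto neighbouring whole days so
#' that the pmf's expectation equals the target exactly: either the
#' floor/ceiling two-point mix, or (with \code{spread >= 1}) a shifted
#' binomial on \code{2 spread + 1} days, which adds realistic day-to-day
#' variation while keeping the mean.
#'
#' @param mean target mean (>= \code{min_day})
#' @param spread half-width in days of the binomial support (0 = two-point)
#' @param min_day smallest admissible day value (1 for stage durations,
#'   0 for pre-oviposition delays)
#' @return named numeric pmf
#' @export
pmf_around_mean <- function(mean, spread = 1L, min_day = 1L) {
  stopifnot(mean >= min_day)
  while (spread > 0L) {
    base <- round(mean) - spread
    p <- (mean - base) / (2 * spread)
    if (base >= min_day && p >= 0 && p <= 1)
      return(day_pmf(base + 0:(2 * spread),
                     stats::dbinom(0:(2 * spread), 2 * spread, p)))
    spread <- spread - 1L
  }
  f <- floor(mean)
  if (f == mean) return(day_pmf(f, 1))
  day_pmf(c(f, f + 1), c(1 - (mean - f), mean - f))
}

pmf_days <- function(pmf) as.integer(names(pmf))
pmf_mean <- function(pmf) sum(pmf_days(pmf) * pmf)

# exact direct convolution of two age/day distributions given as plain
# vectors with offset 0 (index i = value i-1); supports here are small,
# so O(nm) beats FFT round-off
conv0 <- function(a, b) {
  if (!length(a) || !length(b)) return(numeric())
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# named day pmf -> offset-0 vector (index 1 = day 0)
pmf_vec <- function(pmf) {
  d <- pmf_days(pmf)
  v <- numeric(max(d) + 1L)
  v[d + 1L] <- pmf
  v
}

#' Generative description of a synthetic cohort
#'
#' Specifies the stochastic life-history model the simulator draws from:
#' per-stage duration pmfs and completion (survival) probabilities for the
#' immature stages, the sex ratio among emerging adults, the adult
#' pre-oviposition delay, a daily fecundity curve over the oviposition
#' window, and sex-specific adult longevity. All the corresponding exact
#' expected schedules are computable in closed form
#' (\code{\link{expected_schedules}}), which is what makes this a usable
#' ground truth for estimator-recovery tests.
#'
#' @param n0 initial number of eggs
#' @param treatment treatment label
#' @param stages named list over immature stages (egg first, pupa last):
#'   each element a list with \code{pmf} (day pmf of the completed
#'   duration) and \code{survival} (probability of completing the stage);
#'   death inside a stage happens on a uniformly chosen day of the drawn
#'   duration
#' @param female_fraction probability an emerging adult is female
#' @param apop day pmf of the adult pre-oviposition period (days from
#'   female emergence to oviposition onset; day values may be 0)
#' @param fecundity numeric vector of expected eggs per day over the
#'   oviposition window (element s = day s-1 after onset)
#' @param longevity_female,longevity_male day pmfs of adult longevity
#'   (days lived as adult, >= 1)
#' @param dispersion daily egg-count noise: \code{"poisson"} (default),
#'   \code{"nbinom"}, or \code{"none"} (deterministic rounded means)
#' @param nb_size negative-binomial size parameter when
#'   \code{dispersion = "nbinom"}
#' @return a \code{cohort_spec}
#' @export
cohort_spec <- function(n0, treatment, stages, female_fraction, apop,
                        fecundity, longevity_female, longevity_male,
                        dispersion = c("poisson", "nbinom", "none"),
                        nb_size = 5) {
  dispersion <- match.arg(dispersion)
  stopifnot(n0 >= 1, female_fraction >= 0, female_fraction <= 1,
            all(fecundity >= 0), length(fecundity) >= 1)
  if (is.null(names(stages)) || names(stages)[1L] != "egg")
    stop("stages must be named and start with 'egg'")
  for (s in names(stages)) {
    st <- stages[[s]]
    if (is.null(st$pmf) || is.null(st$survival) ||
        st$survival < 0 || st$survival > 1 ||
        abs(sum(st$pmf) - 1) > 1e-8 || any(pmf_days(st$pmf) < 1))
      stop("invalid stage specification for '", s, "'")
  }
  for (pm in list(apop, longevity_female, longevity_male))
    stopifnot(abs(sum(pm) - 1) < 1e-8, all(pm >= 0))
  stopifnot(all(pmf_days(longevity_female) >= 1),
            all(pmf_days(longevity_male) >= 1),
            all(pmf_days(apop) >= 0))
  structure(
    list(n0 = as.integer(n0), treatment = as.character(treatment),
         stages = stages, female_fraction = female_fraction, apop = apop,
         fecundity = fecundity, longevity_female = longevity_female,
         longevity_male = longevity_male, dispersion = dispersion,
         nb_size = nb_size),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n0 = %d, stages %s\n", x$treatment, x$n0,
              paste(names(x$stages), collapse = " > ")))
  cat(sprintf("  female fraction %.2f, %s fecundity over %d days (sum %.1f)\n",
              x$female_fraction, x$dispersion, length(x$fecundity),
              sum(x$fecundity)))
  invisible(x)
}

scheme_of_spec <- function(spec, grouping = NULL) {
  stage_scheme(c(names(spec$stages), "adult"), grouping)
}

draw_pmf <- function(pmf, n = 1L) {
  d <- pmf_days(pmf)
  if (length(d) == 1L) rep(d, n) else sample(d, n, replace = TRUE, prob = pmf)
}

# per-day realized mean of the egg curve under the chosen noise model
fec_mu <- function(spec) {
  if (spec$dispersion == "none") round(spec$fecundity) else spec$fecundity
}

#' Simulate a cohort from a generative spec
#'
#' Draws \code{n0} individual life histories: each immature stage is
#' completed with its survival probability and a duration from its pmf;
#' a death occurs on a uniformly chosen day within the failed stage's
#' drawn duration. Emerging adults are sexed by the female fraction and
#' live a drawn adult longevity; females start ovipositing after a drawn
#' pre-oviposition delay and lay daily egg counts from the dispersion
#' model around the fecundity curve, for as long as they are alive and
#' the window lasts. Fully reproducible for a fixed seed.
#'
#' @param spec a \code{cohort_spec}
#' @param seed integer seed (required)
#' @param grouping optional grouping map passed to the cohort's
#'   \code{\link{stage_scheme}}
#' @return a validated \code{cohort} with \code{n0} records
#' @export
simulate_cohort <- function(spec, seed, grouping = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  scheme <- scheme_of_spec(spec, grouping)
  imm <- names(spec$stages)
  mu <- fec_mu(spec)
  S <- length(mu)

  records <- vector("list", spec$n0)
  for (i in seq_len(spec$n0)) {
    dur <- integer(0)
    death_stage <- NULL
    days_in_death <- NULL
    sex <- "undetermined"
    for (s in imm) {
      st <- spec$stages[[s]]
      D <- draw_pmf(st$pmf)
      if (stats::runif(1) <= st$survival) {
        dur[s] <- D
      } else {
        death_stage <- s
        days_in_death <- if (D == 1L) 1L else sample.int(D, 1L)
        break
      }
    }
    fec <- NULL
    if (is.null(death_stage)) {  # reached adulthood
      sex <- if (stats::runif(1) < spec$female_fraction) "female" else "male"
      L <- draw_pmf(if (sex == "female") spec$longevity_female
                    else spec$longevity_male)
      death_stage <- "adult"
      days_in_death <- L
      if (sex == "female") {
        a <- draw_pmf(spec$apop)
        tdays <- a:min(a + S - 1L, L - 1L)
        tdays <- tdays[tdays >= a & tdays <= L - 1L & (tdays - a) < S]
        if (length(tdays)) {
          m <- mu[tdays - a + 1L]
          eggs <- switch(spec$dispersion,
            poisson = stats::rpois(length(m), m),
            nbinom = stats::rnbinom(length(m), size = spec$nb_size, mu = m),
            none = as.integer(m))
          keep <- eggs > 0
          if (any(keep))
            fec <- data.frame(age = sum(dur) + tdays[keep],
                              eggs = as.integer(eggs[keep]))
        }
      }
    }
    records[[i]] <- individual_record(
      id = sprintf("%s-%04d", spec$treatment, i),
      treatment = spec$treatment, sex = sex,
      stage_durations = dur, death_stage = death_stage,
      days_in_death_stage = days_in_death, fecundity = fec)
  }
  cohort(records, scheme, spec$treatment)
}

#' Exact expected life schedule of a cohort spec
#'
#' Computes, by convolution of the stage-duration pmfs weighted by the
#' cumulative survival probabilities, the exact expectation of the
#' schedules a simulated cohort estimates: l_x (probability of being alive
#' at age x), expected eggs laid at each age, and the large-cohort limits
#' of f_x (eggs per live adult female) and m_x (eggs per survivor, the
#' ratio of expectations). Within-stage deaths use the same
#' uniform-day-of-death model as the simulator.
#'
#' @param spec a \code{cohort_spec}
#' @return a \code{life_schedule} data frame (age, lx, fx, mx, lxmx) with
#'   attribute \code{expected = TRUE}
#' @export
expected_schedules <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mu <- fec_mu(spec)
  S <- length(mu)

  entry <- 1            # offset-0 vector: P(entering current stage at age x)
  death <- numeric(0)   # offset-0 pmf of age at death
  add <- function(a, b) {
    n <- max(length(a), length(b))
    c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  }
  for (s in names(spec$stages)) {
    st <- spec$stages[[s]]
    pv <- pmf_vec(st$pmf)
    if (st$survival < 1) {
      # days lived in the failed stage: u with prob sum_{D>=u} pmf(D)/D
      d <- pmf_days(st$pmf)
      umax <- max(d)
      lived <- vapply(seq_len(umax), function(u)
        sum(st$pmf[d >= u] / d[d >= u]), numeric(1))
      death <- add(death, (1 - st$survival) * conv0(entry, c(0, lived)))
    }
    entry <- st$survival * conv0(entry, pv)
  }
  emerge <- entry       # deficient: sums to P(reach adulthood)
  phi <- spec$female_fraction
  lf <- pmf_vec(spec$longevity_female)
  lm <- pmf_vec(spec$longevity_male)
  if (phi > 0) death <- add(death, phi * conv0(emerge, lf))
  if (phi < 1) death <- add(death, (1 - phi) * conv0(emerge, lm))

  amax <- length(death) - 1L          # last possible death age
  ages <- 0:(amax - 1L)               # alive somewhere on 0..amax-1
  lx <- 1 - cumsum(death)[ages + 1L]
  lx <- pmin(pmax(lx, 0), 1)

  # P(female alive at age x) and E[eggs at age x]
  Lf_days <- pmf_days(spec$longevity_female)
  surv_f <- function(t) sum(spec$longevity_female[Lf_days > t])  # P(L_f > t)
  femalive <- numeric(length(ages))
  eggs <- numeric(length(ages))
  es <- which(emerge > 0) - 1L        # emergence ages with mass
  ad <- pmf_days(spec$apop)
  for (e in es) {
    pe <- emerge[e + 1L] * phi
    if (pe == 0) next
    ts <- 0:(amax - 1L - e)
    femalive[e + ts + 1L] <- femalive[e + ts + 1L] +
      pe * vapply(ts, surv_f, numeric(1))
    for (ai in seq_along(ad)) {
      a <- ad[ai]
      pa <- spec$apop[[ai]]
      if (pa == 0) next
      ss <- 0:(S - 1L)
      x <- e + a + ss
      keep <- x <= amax - 1L
      if (!any(keep)) next
      eggs[x[keep] + 1L] <- eggs[x[keep] + 1L] +
        pe * pa * mu[ss[keep] + 1L] *
        vapply(a + ss[keep], surv_f, numeric(1))
    }
  }
  fx <- ifelse(femalive > 0, eggs / femalive, 0)
  mx <- ifelse(lx > 0, eggs / lx, 0)
  structure(
    data.frame(age = ages, lx = lx, fx = fx, mx = mx, lxmx = lx * mx),
    n0 = spec$n0, expected = TRUE,
    class = c("life_schedule", "data.frame")
  )
}

#' True population parameters of a cohort spec
#'
#' Applies the same parameter definitions used for observed cohorts
#' (\code{\link{population_params}}) to the exact expected schedules, so
#' simulation studies have an analytic target.
#'
#' @param spec a \code{cohort_spec}
#' @param tol Euler-Lotka tolerance
#' @return a \code{population_params}
#' @export
true_params <- function(spec, tol = 1e-12) {
  population_params(expected_schedules(spec), tol)
}

#' Illustrative per-temperature cohort specs
#'
#' Ships a ready-made spec for each rearing temperature of the study
#' design this package emulates (constant 21-36 degrees C, 150 eggs per
#' treatment), parameterised from the published per-treatment means:
#' stage-duration pmfs hitting the mean development times exactly,
#' per-stage survival chosen so the cumulative immature mortality matches
#' the reported percentage, a 1:1 sex ratio, mean-matched pre-oviposition
#' delays and adult longevities, and a triangular daily fecundity curve
#' scaled to the reported lifetime fecundity. At 36 degrees the egg stage
#' never hatches. These specs are illustrative life-history models, not a
#' reconstruction of the raw data: printed means constrain them, but the
#' dispersions are modelling choices.
#'
#' @param temperature one of 21, 24, 27, 30, 33, 36
#' @param n0 cohort size (default 150)
#' @return a \code{cohort_spec}
#' @export
study_spec <- function(temperature, n0 = 150L) {
  key <- as.character(temperature)
  tab <- study_spec_table()
  if (!key %in% names(tab)) stop("no spec for temperature ", temperature)
  p <- tab[[key]]
  k <- length(p$durations)
  surv <- if (is.null(p$mortality)) rep(1, k)
          else rep((1 - p$mortality)^(1 / k), k)
  if (!is.null(p$egg_fails) && p$egg_fails) surv[1L] <- 0
  stages <- stats::setNames(lapply(seq_len(k), function(i)
    list(pmf = pmf_around_mean(p$durations[[i]]), survival = surv[[i]])),
    names(p$durations))
  O <- max(1L, round(p$ovi_days))
  curve <- fecundity_curve(p$total_eggs, O)
  cohort_spec(
    n0 = n0, treatment = paste0(key, "C"), stages = stages,
    female_fraction = 0.5,
    apop = pmf_around_mean(p$apop, min_day = 0L),
    fecundity = curve,
    longevity_female = pmf_around_mean(p$longevity_f, spread = 3L),
    longevity_male = pmf_around_mean(p$longevity_m, spread = 3L)
  )
}

# published per-treatment means used to parameterise the illustrative
# specs: immature-stage mean durations (days), immature mortality, adult
# longevities, APOP, oviposition period, lifetime fecundity per female
study_spec_table <- function() {
  list(
    "21" = list(
      durations = c(egg = 6.35, L1 = 1.36, L2 = 2.48, L3 = 3.44, L4 = 2.83,
                    L5 = 3.35, L6 = 4.52, L7 = 5.79, pupa = 8.15),
      mortality = 0.2466, longevity_f = 25.90, longevity_m = 26.62,
      apop = 2.55, ovi_days = 19.06, total_eggs = 376.02),
    "24" = list(
      durations = c(egg = 5, L1 = 1.11, L2 = 2.05, L3 = 3.17, L4 = 2.68,
                    L5 = 3.58, L6 = 2.87, pupa = 6.90),
      mortality = 0.3143, longevity_f = 26.14, longevity_m = 29.68,
      apop = 1.46, ovi_days = 15.40, total_eggs = 299.17),
    "27" = list(
      durations = c(egg = 5, L1 = 1.85, L2 = 1.96, L3 = 2.08, L4 = 2.20,
                    L5 = 4.41, pupa = 5.04),
      mortality = 0.1533, longevity_f = 32.70, longevity_m = 34.17,
      apop = 1.45, ovi_days = 18.31, total_eggs = 299.18),
    "30" = list(
      durations = c(egg = 3, L1 = 1.28, L2 = 2.80, L3 = 1.92, L4 = 1.77,
                    L5 = 3.71, pupa = 4.07),
      mortality = 0.26, longevity_f = 17.41, longevity_m = 17.98,
      apop = 1.14, ovi_days = 11.94, total_eggs = 321.28),
    "33" = list(
      durations = c(egg = 3, L1 = 1.10, L2 = 1.94, L3 = 1.40, L4 = 2.67,
                    L5 = 2.98, pupa = 4.06),
      mortality = 0.2752, longevity_f = 28.52, longevity_m = 25.29,
      apop = 3.81, ovi_days = 11.22, total_eggs = 23.24),
    "36" = list(
      durations = c(egg = 3, L1 = 1.10, L2 = 1.94, L3 = 1.40, L4 = 2.67,
                    L5 = 2.98, pupa = 4.06),
      egg_fails = TRUE, longevity_f = 5, longevity_m = 5,
      apop = 1, ovi_days = 1, total_eggs = 0.5)
  )
}

# triangular daily-egg curve over `days` days peaking a third of the way
# in, scaled to a target lifetime total
fecundity_curve <- function(total, days, peak = max(1L, round(days / 3))) {
  s <- seq_len(days)
  w <- ifelse(s <= peak, s / peak,
              (days - s + 1) / max(1, days - peak + 1))
  total * w / sum(w)
}

#' Serialise a cohort spec to YAML
#'
#' @param spec a \code{cohort_spec}
#' @param path output path
#' @return \code{path} invisibly
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- list(
    n0 = spec$n0, treatment = spec$treatment,
    stages = lapply(spec$stages, function(st)
      list(days = pmf_days(st$pmf), prob = unname(st$pmf),
           survival = st$survival)),
    female_fraction = spec$female_fraction,
    apop = list(days = pmf_days(spec$apop), prob = unname(spec$apop)),
    fecundity = spec$fecundity,
    longevity_female = list(days = pmf_days(spec$longevity_female),
                            prob = unname(spec$longevity_female)),
    longevity_male = list(days = pmf_days(spec$longevity_male),
                          prob = unname(spec$longevity_male)),
    dispersion = spec$dispersion, nb_size = spec$nb_size
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  o <- yaml::read_yaml(path)
  as_pmf <- function(z) day_pmf(unlist(z$days), unlist(z$prob))
  cohort_spec(
    n0 = o$n0, treatment = o$treatment,
    stages = lapply(o$stages, function(st)
      list(pmf = day_pmf(unlist(st$days), unlist(st$prob)),
           survival = st$survival)),
    female_fraction = o$female_fraction,
    apop = as_pmf(o$apop),
    fecundity = unlist(o$fecundity),
    longevity_female = as_pmf(o$longevity_female),
    longevity_male = as_pmf(o$longevity_male),
    dispersion = o$dispersion, nb_size = o$nb_size
  )
}
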