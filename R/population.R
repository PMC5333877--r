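#' Net reproductive rate R0
#'
#' Expected lifetime offspring per newborn individual (both sexes in the
#' denominator): \code{R0 = sum_x l_x m_x}.
#'
#' @param schedule a \code{life_schedule} (or any data frame with columns
#'   \code{lx} and \code{mx})
#' @return R0, offspring per individual
#' @export
net_reproductive_rate <- function(schedule) {
  sum(schedule$lx * schedule$mx)
}

#' Gross reproductive rate GRR
#'
#' Lifetime reproduction ignoring mortality: \code{GRR = sum_x m_x}.
#' Always at least R0, with equality only when no one dies before the end
#' of reproduction.
#'
#' @inheritParams net_reproductive_rate
#' @return GRR, offspring per individual
#' @export
gross_reproductive_rate <- function(schedule) {
  sum(schedule$mx)
}

# Euler-Lotka left-hand side minus one, the function whose root is r.
# Age enters as (x+1): age 0 is the oviposition day, so an egg laid on a
# mother's age-x day starts its own age-0 day one census later.
el_g <- function(r, age, lxmx) sum(exp(-r * (age + 1)) * lxmx) - 1

#' Intrinsic rate of increase r
#'
#' Solves the Euler-Lotka equation \code{sum_x exp(-r (x+1)) l_x m_x = 1}
#' for its unique real root. The left-hand side is strictly decreasing in
#' r whenever any l_x m_x > 0, so the root is found by geometric expansion
#' of a bracket from [-1, 1] followed by bisection; negative r (declining
#' population, R0 < 1) is permitted.
#'
#' @inheritParams net_reproductive_rate
#' @param tol bisection stops when the bracket is narrower than this and
#'   the residual is below it (default 1e-12)
#' @return r, per day
#' @export
intrinsic_rate <- function(schedule, tol = 1e-12) {
  age <- schedule$age
  lxmx <- schedule$lx * schedule$mx
  if (sum(lxmx) <= 0)
    stop("R0 = 0: the cohort never reproduces, r is undefined")
  lo <- -1; hi <- 1
  while (el_g(lo, age, lxmx) < 0) lo <- lo * 2
  while (el_g(hi, age, lxmx) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (el_g(mid, age, lxmx) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  r <- (lo + hi) / 2
  stopifnot(abs(el_g(r, age, lxmx)) <= 1e-10)
  r
}

#' Finite rate of increase
#'
#' Per-day population multiplication factor at the stable age-stage
#' distribution: \code{lambda = exp(r)}.
#'
#' @param r intrinsic rate of increase, per day
#' @return lambda, per day
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' The time a population growing at rate r needs to multiply R0-fold:
#' \code{T = ln(R0) / r}.
#'
#' @param R0 net reproductive rate (> 0)
#' @param r intrinsic rate of increase (nonzero)
#' @return T, days
#' @export
mean_generation_time <- function(R0, r) {
  if (R0 <= 0) stop("mean generation time undefined for R0 <= 0")
  if (r == 0) stop("mean generation time undefined for r = 0")
  log(R0) / r
}

#' All population growth parameters of a schedule
#'
#' @inheritParams net_reproductive_rate
#' @param tol tolerance passed to \code{\link{intrinsic_rate}}
#' @return a \code{population_params} list: \code{R0}, \code{GRR},
#'   \code{r}, \code{lambda}, \code{T}. When the schedule has no
#'   reproduction, \code{R0} and \code{GRR} are 0 and the growth-rate
#'   entries are NA.
#' @export
population_params <- function(schedule, tol = 1e-12) {
  R0 <- net_reproductive_rate(schedule)
  GRR <- gross_reproductive_rate(schedule)
  if (R0 > 0) {
    r <- intrinsic_rate(schedule, tol)
    lam <- finite_rate(r)
    Tg <- if (r != 0) mean_generation_time(R0, r) else NA_real_
  } else {
    r <- lam <- Tg <- NA_real_
  }
  structure(list(R0 = R0, GRR = GRR, r = r, lambda = lam, T = Tg),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "R0 = %.4g  GRR = %.4g  r = %.4g /day  lambda = %.4g /day  T = %.4g d\n",
    x$R0, x$GRR, x$r, x$lambda, x$T))
  invisible(x)
}

# Per-individual summaries needed to recompute a life schedule under
# resampling: days lived, live-adult-female indicator by age, eggs by age.
cohort_boot_arrays <- function(cht) {
  amax <- max(vapply(cht$records, death_age, integer(1)))
  n <- cht$n0
  alive <- matrix(0, n, amax)
  eggs <- matrix(0, n, amax)
  for (i in seq_len(n)) {
    rec <- cht$records[[i]]
    d <- death_age(rec)
    if (d > 0) alive[i, seq_len(d)] <- 1
    if (nrow(rec$fecundity))
      eggs[i, rec$fecundity$age + 1L] <- rec$fecundity$eggs
  }
  list(alive = alive, eggs = eggs, age = 0:(amax - 1L), n = n)
}

# Vectorised Euler-Lotka bisection over the columns of a net-maternity
# matrix (ages x replicates). Columns with zero reproduction return NA.
el_solve_many <- function(age, LM, tol = 1e-12) {
  ok <- colSums(LM) > 0
  r <- rep(NA_real_, ncol(LM))
  if (!any(ok)) return(r)
  M <- LM[, ok, drop = FALSE]
  xp1 <- age + 1
  g <- function(rv) colSums(exp(-outer(xp1, rv)) * M) - 1
  lo <- rep(-1, ncol(M)); hi <- rep(1, ncol(M))
  while (any(bad <- g(lo) < 0)) lo[bad] <- lo[bad] * 2
  while (any(bad <- g(hi) > 0)) hi[bad] <- hi[bad] * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gpos <- g(mid) > 0
    lo[gpos] <- mid[gpos]
    hi[!gpos] <- mid[!gpos]
    if (max(hi - lo) < tol) break
  }
  r[ok] <- (lo + hi) / 2
  r
}

# Recompute population parameters for resample weight columns (n x B
# multiplicity matrix): the fast path behind bootstrap_params. Each column
# is one bootstrap cohort of size n; schedules follow from weighted
# head-counts exactly as in life_schedule.
boot_from_weights <- function(arr, W, tol = 1e-12) {
  aliveC <- crossprod(arr$alive, W)           # ages x B survivors
  eggsC <- crossprod(arr$eggs, W)             # ages x B eggs laid
  n <- arr$n
  LM <- eggsC / n                             # l_x m_x = eggs_x / n0
  R0 <- colSums(LM)
  MX <- ifelse(aliveC > 0, eggsC / aliveC, 0) # m_x = eggs per survivor
  GRR <- colSums(MX)
  r <- el_solve_many(arr$age, LM, tol)
  lambda <- exp(r)
  Tg <- ifelse(!is.na(r) & r != 0 & R0 > 0, log(R0) / r, NA_real_)
  data.frame(R0 = R0, GRR = GRR, r = r, lambda = lambda, T = Tg)
}

#' Bootstrap uncertainty for population parameters
#'
#' Resamples n0 individuals with replacement B times, reruns the whole
#' pipeline (census matrix, schedules, Euler-Lotka solve) on every
#' resample, and summarises each parameter by the standard deviation of
#' its replicates (the bootstrap SE) and a percentile confidence interval.
#' Replicates in which no resampled female reproduces have R0 = 0 and no
#' defined growth rate; they are counted, kept in the R0/GRR statistics
#' (where 0 is a real outcome) and excluded from r, lambda and T, with a
#' warning when any occur.
#'
#' @param cht a \code{cohort}
#' @param B number of bootstrap replicates (default 10000)
#' @param seed integer seed; required, so runs are reproducible
#' @param conf confidence level for the percentile interval (default 0.95)
#' @param tol Euler-Lotka tolerance
#' @return a \code{bootstrap_result}: list with point \code{estimates}
#'   (\code{population_params} of the full cohort), \code{replicates}
#'   (B-row data frame), \code{se}, \code{ci} (2 x 5), \code{B},
#'   \code{n_degenerate}
#' @export
bootstrap_params <- function(cht, B = 10000L, seed, conf = 0.95,
                             tol = 1e-12) {
  stopifnot(inherits(cht, "cohort"), B >= 2L)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the bootstrap")
  set.seed(seed)
  arr <- cohort_boot_arrays(cht)
  W <- stats::rmultinom(B, arr$n, rep(1 / arr$n, arr$n))
  reps <- boot_from_weights(arr, W, tol)
  n_deg <- sum(reps$R0 == 0)
  if (n_deg > 0)
    warning(sprintf(
      "%d of %d bootstrap replicates had no reproduction; excluded from r/lambda/T",
      n_deg, B))
  if (n_deg == B) stop("all bootstrap replicates degenerate")
  alpha <- (1 - conf) / 2
  se <- vapply(reps, function(v) stats::sd(v[!is.na(v)]), numeric(1))
  ci <- vapply(reps, function(v)
    stats::quantile(v[!is.na(v)], c(alpha, 1 - alpha), names = FALSE),
    numeric(2))
  rownames(ci) <- c("lower", "upper")
  structure(
    list(estimates = population_params(life_schedule(cht), tol),
         replicates = reps, se = se, ci = ci, B = B,
         conf = conf, n_degenerate = n_deg),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  est <- unlist(x$estimates)
  cat(sprintf("Bootstrap (B = %d, %d degenerate):\n", x$B, x$n_degenerate))
  for (p in names(est))
    cat(sprintf("  %-6s %10.4f  SE %8.4f  CI [%.4f, %.4f]\n", p, est[[p]],
                x$se[[p]], x$ci["lower", p], x$ci["upper", p]))
  invisible(x)
}

#' Population-parameter table with uncertainty
#'
#' Flattens a \code{bootstrap_result} into the one-row-per-parameter table
#' usually reported for a treatment: estimate, bootstrap SE, percentile CI.
#'
#' @param boot a \code{bootstrap_result}
#' @return data frame with columns parameter, estimate, se, ci_lower,
#'   ci_upper, B, n_degenerate
#' @export
params_table <- function(boot) {
  stopifnot(inherits(boot, "bootstrap_result"))
  est <- unlist(boot$estimates)
  data.frame(
    parameter = names(est),
    estimate = unname(est),
    se = unname(boot$se[names(est)]),
    ci_lower = boot$ci["lower", names(est)],
    ci_upper = boot$ci["upper", names(est)],
    B = boot$B,
    n_degenerate = boot$n_degenerate,
    row.names = NULL
  )
}
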