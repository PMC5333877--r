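#' Age-stage-specific survival matrix s_xj
#'
#' Performs a daily census of the cohort: \code{s[x, j]} is the fraction of
#' the initial cohort (n0) alive in stage j on day x, with age 0 the day of
#' oviposition. The adult stage is split by sex into \code{"adult female"}
#' and \code{"adult male"} columns — the two-sex convention — so that the
#' female fecundity column of the life table lines up with an actual
#' head-count of live females. Every entry is a multiple of 1/n0 and the
#' row sums give the age-specific survival curve l_x.
#'
#' @param cht a \code{cohort} (validate first; see
#'   \code{\link{validate_cohort}})
#' @return an \code{age_stage_matrix}: a numeric matrix, rows = ages
#'   0..(max death age - 1), columns = immature stages then adult female,
#'   adult male; attribute \code{n0} carries the initial cohort size
#' @export
build_age_stage_survival <- function(cht) {
  stopifnot(inherits(cht, "cohort"))
  if (cht$n0 == 0L) stop("empty cohort")
  stages <- cht$scheme$stages
  imm <- setdiff(stages, "adult")
  cols <- c(imm, "adult female", "adult male")
  amax <- max(vapply(cht$records, death_age, integer(1)))
  if (amax == 0L) stop("no individual lived a full day")

  counts <- matrix(0L, nrow = amax, ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (rec in cht$records) {
    at <- 0L
    for (s in names(rec$stage_durations)) {
      d <- rec$stage_durations[[s]]
      col <- if (s == "adult") paste("adult", rec$sex) else s
      if (d > 0L) counts[(at + 1L):(at + d), col] <-
          counts[(at + 1L):(at + d), col] + 1L
      at <- at + d
    }
    d <- rec$days_in_death_stage
    s <- rec$death_stage
    col <- if (s == "adult") paste("adult", rec$sex) else s
    if (d > 0L) counts[(at + 1L):(at + d), col] <-
        counts[(at + 1L):(at + d), col] + 1L
  }
  structure(counts / cht$n0,
            ages = 0:(amax - 1L), n0 = cht$n0,
            class = c("age_stage_matrix", "matrix", "array"))
}

#' Age-specific survival l_x from an age-stage matrix
#'
#' l_x is the probability that a newly laid egg is alive at age x,
#' whatever its stage: the row sums of s_xj.
#'
#' @param mat an \code{age_stage_matrix}
#' @return numeric vector indexed by age 0, 1, ...
#' @export
age_specific_survival <- function(mat) {
  stopifnot(inherits(mat, "age_stage_matrix"))
  unname(rowSums(mat))
}

#' Age-stage-specific fecundity f_xj
#'
#' Mean daily eggs per surviving adult female at each age. Only the adult
#' female column is non-zero (only adult females oviposit), so the result
#' is returned as the single vector f_x; ages where no female is alive are
#' 0 by the 0/0 convention.
#'
#' @param cht the \code{cohort}
#' @param mat its \code{age_stage_matrix}
#' @return numeric vector f_x over the matrix's ages
#' @export
age_stage_fecundity <- function(cht, mat) {
  stopifnot(inherits(cht, "cohort"), inherits(mat, "age_stage_matrix"))
  eggs <- eggs_by_age(cht, nrow(mat))
  females <- attr(mat, "n0") * mat[, "adult female"]
  ifelse(females > 0, eggs / females, 0)
}

#' Age-specific fecundity m_x
#'
#' Mean daily eggs per surviving individual of age x, both sexes counted
#' in the denominator: \code{m_x = sum_j s_xj f_xj / sum_j s_xj}. With f
#' non-zero only in the adult-female column this is total eggs laid at age
#' x divided by all survivors at age x; 0 where l_x = 0.
#'
#' @param mat an \code{age_stage_matrix}
#' @param f the f_x vector from \code{\link{age_stage_fecundity}}
#' @return numeric vector m_x over ages
#' @export
age_specific_fecundity <- function(mat, f) {
  stopifnot(inherits(mat, "age_stage_matrix"), length(f) == nrow(mat))
  lx <- rowSums(mat)
  num <- mat[, "adult female"] * f
  unname(ifelse(lx > 0, num / lx, 0))
}

# total eggs laid by the cohort on each day 0..(amax-1)
eggs_by_age <- function(cht, amax) {
  eggs <- numeric(amax)
  for (rec in cht$records) {
    fec <- rec$fecundity
    if (nrow(fec)) {
      i <- fec$age + 1L
      eggs[i] <- eggs[i] + fec$eggs
    }
  }
  eggs
}

#' Full life schedule of a cohort
#'
#' Convenience wrapper assembling the aligned age vectors of the life
#' table: survival l_x, per-female fecundity f_x, per-capita fecundity
#' m_x and the net maternity l_x m_x, whose sum is the net reproductive
#' rate R0.
#'
#' @param cht a \code{cohort}
#' @param mat optionally a precomputed \code{age_stage_matrix}
#' @return a \code{life_schedule}: data frame with columns \code{age},
#'   \code{lx}, \code{fx}, \code{mx}, \code{lxmx}; attributes \code{n0}
#'   and \code{total_eggs}
#' @export
life_schedule <- function(cht, mat = build_age_stage_survival(cht)) {
  lx <- age_specific_survival(mat)
  fx <- age_stage_fecundity(cht, mat)
  mx <- age_specific_fecundity(mat, fx)
  structure(
    data.frame(age = attr(mat, "ages"), lx = lx, fx = fx, mx = mx,
               lxmx = lx * mx),
    n0 = attr(mat, "n0"),
    total_eggs = sum(eggs_by_age(cht, nrow(mat))),
    class = c("life_schedule", "data.frame")
  )
}

mean_se <- function(x) {
  n <- length(x)
  c(mean = mean(x), se = if (n > 1L) stats::sd(x) / sqrt(n) else 0,
    n = n)
}

#' Stage durations, longevity, lifespan and immature mortality
#'
#' Per-stage mean and standard error of development time over the
#' individuals that completed each stage (dying inside a stage excludes an
#' individual from that stage's mean, though its days lived still count in
#' the census matrix); total pre-adult duration over individuals reaching
#' adulthood; adult longevity (emergence to death) and entire lifespan
#' (egg to death) split by sex; and the immature mortality percentage.
#' SE is the sample standard deviation over sqrt(n).
#'
#' @param cht a \code{cohort}
#' @return a \code{stage_duration_summary}: list with data frames
#'   \code{stages} (stage, mean, se, n), \code{adults} (measure, sex, mean,
#'   se, n), and scalar \code{immature_mortality_pct}
#' @export
stage_duration_summary <- function(cht) {
  stopifnot(inherits(cht, "cohort"))
  pre <- setdiff(cht$scheme$stages, "adult")

  per_stage <- lapply(pre, function(s) {
    d <- unlist(lapply(cht$records, function(r)
      if (s %in% names(r$stage_durations)) r$stage_durations[[s]]))
    if (is.null(d)) d <- numeric()
    c(stage = s, mean_se(d))
  })
  reached_adult <- Filter(function(r) r$death_stage == "adult", cht$records)
  preadult <- vapply(reached_adult, function(r) sum(r$stage_durations),
                     numeric(1))
  stages <- data.frame(
    stage = c(pre, "preadult"),
    mean = c(vapply(per_stage, function(z) as.numeric(z[["mean"]]), 0),
             mean_se(preadult)[["mean"]]),
    se = c(vapply(per_stage, function(z) as.numeric(z[["se"]]), 0),
           mean_se(preadult)[["se"]]),
    n = c(vapply(per_stage, function(z) as.numeric(z[["n"]]), 0),
          length(preadult))
  )

  adult_rows <- list()
  for (sx in c("female", "male")) {
    of_sex <- Filter(function(r) r$sex == sx, reached_adult)
    lon <- vapply(of_sex, function(r) as.numeric(r$days_in_death_stage),
                  numeric(1))
    life <- vapply(of_sex, function(r) as.numeric(death_age(r)), numeric(1))
    adult_rows[[paste0("longevity_", sx)]] <-
      data.frame(measure = "adult longevity", sex = sx,
                 t(mean_se(lon)))
    adult_rows[[paste0("lifespan_", sx)]] <-
      data.frame(measure = "entire lifespan", sex = sx,
                 t(mean_se(life)))
  }
  adults <- do.call(rbind, adult_rows)
  rownames(adults) <- NULL

  structure(
    list(stages = stages, adults = adults,
         immature_mortality_pct = immature_mortality(cht)),
    class = "stage_duration_summary"
  )
}

#' Immature (pre-adult) mortality percentage
#'
#' Share of the initial cohort dying before reaching the adult stage,
#' reported as a percentage of n0.
#'
#' @param cht a \code{cohort}
#' @return percentage in [0, 100]
#' @examples
#' # a cohort of 150 eggs with 23 pre-adult deaths gives 15.33...%
#' @export
immature_mortality <- function(cht) {
  stopifnot(inherits(cht, "cohort"))
  dead_young <- sum(vapply(cht$records,
                           function(r) r$death_stage != "adult", TRUE))
  100 * dead_young / cht$n0
}

#' Reproduction timing and fecundity summary
#'
#' Over reproducing females (females that laid at least one egg): the adult
#' pre-oviposition period APOP (first-egg age minus emergence age), the
#' total pre-oviposition period TPOP (first-egg age, counted from
#' oviposition of the female herself), the oviposition period and the total
#' lifetime fecundity; cohort means with standard errors.
#'
#' The oviposition period is by default the inclusive first-to-last-egg
#' span (gap days without eggs count); set
#' \code{period = "active"} to count only days with at least one egg.
#'
#' @param cht a \code{cohort}
#' @param period \code{"span"} (default) or \code{"active"}
#' @return a \code{reproduction_summary}: list with \code{per_female}
#'   (data frame id, apop, tpop, oviposition_days, total_eggs),
#'   \code{summary} (measure, mean, se, n) and \code{n_females}; flagged
#'   \code{empty = TRUE} when no female reproduced
#' @export
reproduction_summary <- function(cht, period = c("span", "active")) {
  stopifnot(inherits(cht, "cohort"))
  period <- match.arg(period)
  females <- Filter(function(r) r$sex == "female" &&
                      r$death_stage == "adult" &&
                      sum(r$fecundity$eggs) > 0, cht$records)
  if (!length(females)) {
    return(structure(list(per_female = NULL, summary = NULL,
                          n_females = 0L, empty = TRUE),
                     class = "reproduction_summary"))
  }
  per <- do.call(rbind, lapply(females, function(r) {
    laid <- r$fecundity[r$fecundity$eggs > 0, , drop = FALSE]
    emerge <- sum(r$stage_durations)
    first <- min(laid$age)
    last <- max(laid$age)
    data.frame(
      id = r$id,
      apop = first - emerge,
      tpop = first,
      oviposition_days = if (period == "span") last - first + 1L
                         else nrow(laid),
      total_eggs = sum(laid$eggs)
    )
  }))
  sm <- do.call(rbind, lapply(
    c("apop", "tpop", "oviposition_days", "total_eggs"),
    function(v) data.frame(measure = v, t(mean_se(per[[v]])))))
  structure(list(per_female = per, summary = sm,
                 n_females = nrow(per), empty = FALSE),
            class = "reproduction_summary")
}
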