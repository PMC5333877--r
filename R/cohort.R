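#' Construct one individual's life-history record
#'
#' One record is one organism followed from oviposition (age 0) to death
#' under daily observation. Ages are whole days; an individual occupies a
#' stage on the half-open interval [entry age, entry age + duration).
#' Completed-stage durations are kept separately from the days lived in the
#' stage where death occurred, so age at death is always
#' \code{sum(stage_durations) + days_in_death_stage}. For adults that die of
#' old age, \code{death_stage = "adult"} and \code{days_in_death_stage} is
#' the adult longevity.
#'
#' @param id identifier (coerced to character)
#' @param treatment treatment label, e.g. a rearing temperature
#' @param sex one of \code{"female"}, \code{"male"}, \code{"undetermined"}
#'   (undetermined is only allowed for individuals dying before adulthood)
#' @param stage_durations named integer vector of completed-stage durations
#'   in days, in scheme order; must be exactly the stages preceding
#'   \code{death_stage}
#' @param death_stage label of the stage in which death occurred
#' @param days_in_death_stage whole days lived in the death stage (>= 0)
#' @param fecundity data frame with columns \code{age} (days since
#'   oviposition) and \code{eggs} (non-negative integer counts); females only
#' @return an object of class \code{individual_record}
#' @export
individual_record <- function(id, treatment, sex, stage_durations,
                              death_stage, days_in_death_stage,
                              fecundity = NULL) {
  if (is.null(fecundity))
    fecundity <- data.frame(age = integer(), eggs = integer())
  fecundity <- data.frame(age = as.integer(fecundity$age),
                          eggs = as.integer(fecundity$eggs))
  if (all(is_whole(stage_durations))) {
    nm <- names(stage_durations)
    stage_durations <- as.integer(stage_durations)
    if (length(stage_durations)) names(stage_durations) <- nm
  }
  if (length(days_in_death_stage) == 1L && is_whole(days_in_death_stage))
    days_in_death_stage <- as.integer(days_in_death_stage)
  structure(
    list(
      id = as.character(id),
      treatment = as.character(treatment),
      sex = as.character(sex),
      stage_durations = stage_durations,
      death_stage = as.character(death_stage),
      days_in_death_stage = days_in_death_stage,
      fecundity = fecundity
    ),
    class = "individual_record"
  )
}

#' Age at death of a record
#'
#' Total whole days lived: completed-stage durations plus days lived in the
#' death stage. The individual is alive (counted in the daily census) on
#' ages \code{0 .. death_age(rec) - 1}.
#' @param rec an \code{individual_record}
#' @return integer number of days lived
#' @export
death_age <- function(rec) {
  as.integer(sum(rec$stage_durations) + rec$days_in_death_stage)
}

#' Age at which a record entered a given stage
#' @param rec an \code{individual_record}
#' @param stage stage label (must be a completed stage or the death stage)
#' @return integer entry age, or \code{NA} if the stage was never reached
#' @export
entry_age <- function(rec, stage) {
  stages <- c(names(rec$stage_durations), rec$death_stage)
  i <- match(stage, stages)
  if (is.na(i)) return(NA_integer_)
  as.integer(sum(rec$stage_durations[seq_len(i - 1L)]))
}

#' Assemble a cohort of individual records
#'
#' A cohort is every egg that started a treatment — individuals dying in
#' the egg stage are records too, so the initial cohort size \code{n0}
#' equals the record count.
#'
#' @param records list of \code{individual_record}s
#' @param scheme the \code{stage_scheme} shared by all records
#' @param treatment treatment label; defaults to the first record's
#' @return an object of class \code{cohort}
#' @export
cohort <- function(records, scheme, treatment = NULL) {
  stopifnot(is_stage_scheme(scheme), length(records) > 0L)
  if (is.null(treatment)) treatment <- records[[1L]]$treatment
  structure(
    list(treatment = as.character(treatment), scheme = scheme,
         records = records, n0 = length(records)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  sexes <- table(vapply(x$records, `[[`, "", "sex"))
  cat("<cohort> treatment:", x$treatment, " n0:", x$n0, "\n")
  cat("  stages:", paste(x$scheme$stages, collapse = " > "), "\n")
  cat("  sexes:", paste(names(sexes), sexes, sep = "=", collapse = " "), "\n")
  invisible(x)
}

is_whole <- function(x) is.finite(x) & x == floor(x)

#' Check every record invariant of a cohort
#'
#' Violations are returned as data, not raised, so a whole file can be
#' audited in one pass. An empty result means the cohort is internally
#' consistent.
#'
#' @param cht a \code{cohort}
#' @return character vector of violation messages (empty if none), each
#'   naming the offending record and rule
#' @export
validate_cohort <- function(cht) {
  stopifnot(inherits(cht, "cohort"))
  sch <- cht$scheme
  out <- character()
  bad <- function(rec, msg) sprintf("record %s: %s", rec$id, msg)

  for (rec in cht$records) {
    if (!rec$sex %in% c("female", "male", "undetermined")) {
      out <- c(out, bad(rec, paste0("invalid sex '", rec$sex, "'")))
      next
    }
    if (!rec$death_stage %in% sch$stages) {
      out <- c(out, bad(rec, paste0("unknown death stage '",
                                    rec$death_stage, "'")))
      next
    }
    k <- match(rec$death_stage, sch$stages)
    expect_completed <- sch$stages[seq_len(k - 1L)]
    if (!identical(as.character(names(rec$stage_durations)), expect_completed))
      out <- c(out, bad(rec, sprintf(
        "completed stages (%s) are not the stages preceding death stage %s",
        paste(names(rec$stage_durations), collapse = ","), rec$death_stage)))
    d <- rec$stage_durations
    if (length(d) && (!all(is_whole(d)) || any(d < 1)))
      out <- c(out, bad(rec, "stage durations must be positive whole days"))
    if (!is_whole(rec$days_in_death_stage) || rec$days_in_death_stage < 0)
      out <- c(out, bad(rec,
        "days_in_death_stage must be a non-negative whole number"))
    if (rec$sex == "undetermined" && rec$death_stage == "adult")
      out <- c(out, bad(rec, "sex undetermined but reached the adult stage"))

    fec <- rec$fecundity
    if (nrow(fec)) {
      if (rec$sex != "female")
        out <- c(out, bad(rec, "fecundity recorded for a non-female"))
      if (!all(is_whole(fec$eggs)) || any(fec$eggs < 0))
        out <- c(out, bad(rec, "egg counts must be non-negative integers"))
      if (rec$death_stage == "adult") {
        emerge <- sum(rec$stage_durations)
        if (any(fec$age < emerge))
          out <- c(out, bad(rec, sprintf(
            "fecundity at age %d before adult emergence at age %d",
            min(fec$age), emerge)))
        if (any(fec$age >= death_age(rec)))
          out <- c(out, bad(rec, "fecundity recorded after death"))
      } else {
        out <- c(out, bad(rec, "fecundity recorded for a non-adult"))
      }
    }
  }
  out
}

#' Pool raw stages into analysis stages
#'
#' Applies the scheme's grouping map: the durations of raw stages that map
#' to the same analysis stage are summed per individual, and a death inside
#' a pooled group carries over the days already spent in the group's earlier
#' raw stages, so every individual's age at death is unchanged.
#'
#' @param cht a \code{cohort}
#' @return a \code{cohort} over the analysis stages (its scheme has an
#'   identity grouping); record count unchanged
#' @export
apply_grouping <- function(cht) {
  stopifnot(inherits(cht, "cohort"))
  sch <- cht$scheme
  if (identical(sch$stages, sch$analysis_stages)) return(cht)
  new_scheme <- stage_scheme(sch$analysis_stages)
  map <- sch$grouping

  records <- lapply(cht$records, function(rec) {
    g <- unname(map[names(rec$stage_durations)])
    dur <- if (length(g)) {
      v <- tapply(rec$stage_durations, factor(g, levels = unique(g)), sum)
      stats::setNames(as.integer(v), names(v))
    } else {
      rec$stage_durations
    }
    new_death <- unname(map[[rec$death_stage]])
    extra <- 0L
    if (new_death %in% names(dur)) {
      # death inside a pooled group: completed raw days of that group move
      # into the death-stage tally
      extra <- dur[[new_death]]
      dur <- dur[names(dur) != new_death]
    }
    individual_record(rec$id, rec$treatment, rec$sex, dur, new_death,
                      rec$days_in_death_stage + extra, rec$fecundity)
  })
  cohort(records, new_scheme, cht$treatment)
}

#' Write a cohort to CSV
#'
#' Two plain CSV files are written: the individuals table (one row per
#' record, one duration column per raw stage before adult, plus death stage,
#' days in death stage and a redundant death-age column used as a
#' consistency check on re-read) and a long fecundity table
#' (\code{id, age, eggs}) holding every female's daily egg counts.
#'
#' @param cht a \code{cohort}
#' @param path path of the individuals CSV; the fecundity table goes to the
#'   same name with suffix \code{_fecundity.csv} unless overridden
#' @param fecundity_path optional explicit path for the fecundity table
#' @return \code{path}, invisibly
#' @export
write_cohort <- function(cht, path, fecundity_path = NULL) {
  stopifnot(inherits(cht, "cohort"))
  if (is.null(fecundity_path)) fecundity_path <- fec_path_for(path)
  pre <- setdiff(cht$scheme$stages, "adult")

  rows <- lapply(cht$records, function(rec) {
    d <- rep(NA_integer_, length(pre))
    names(d) <- pre
    d[names(rec$stage_durations)] <- as.integer(rec$stage_durations)
    c(list(id = rec$id, treatment = rec$treatment, sex = rec$sex),
      as.list(d),
      list(death_stage = rec$death_stage,
           days_in_death_stage = as.integer(rec$days_in_death_stage),
           death_age = death_age(rec)))
  })
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r,
    check.names = FALSE)))
  names(tab) <- c("id", "treatment", "sex", paste0("d_", pre),
                  "death_stage", "days_in_death_stage", "death_age")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)

  fec <- do.call(rbind, lapply(cht$records, function(rec)
    if (nrow(rec$fecundity))
      data.frame(id = rec$id, age = rec$fecundity$age,
                 eggs = rec$fecundity$eggs)))
  if (is.null(fec)) fec <- data.frame(id = character(), age = integer(),
                                      eggs = integer())
  utils::write.csv(fec, fecundity_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fec_path_for <- function(path) sub("(\\.[^.]+)?$", "_fecundity.csv",
                                   path, perl = TRUE)

#' Read a cohort from CSV
#'
#' Reads the individuals table written by \code{\link{write_cohort}} (plus
#' its long fecundity companion), validates it against the scheme, and
#' fails with the offending row and field on malformed input (missing
#' columns, fractional durations, fecundity attached to a male, death-age
#' mismatches).
#'
#' @param path individuals CSV path
#' @param scheme the \code{stage_scheme} the file must conform to
#' @param fecundity_path optional explicit fecundity CSV path; defaults to
#'   \code{path} with suffix \code{_fecundity.csv}
#' @return a validated \code{cohort} with rows in file order
#' @export
read_cohort <- function(path, scheme, fecundity_path = NULL) {
  stopifnot(file.exists(path), is_stage_scheme(scheme))
  if (is.null(fecundity_path)) fecundity_path <- fec_path_for(path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(id = "character"))
  pre <- setdiff(scheme$stages, "adult")
  need <- c("id", "treatment", "sex", paste0("d_", pre),
            "death_stage", "days_in_death_stage")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))

  fec <- if (file.exists(fecundity_path)) {
    utils::read.csv(fecundity_path, colClasses = c(id = "character"))
  } else {
    data.frame(id = character(), age = integer(), eggs = integer())
  }
  fec_by_id <- split(fec[c("age", "eggs")], fec$id)

  records <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    for (s in pre) {
      v <- row[[paste0("d_", s)]]
      if (!is.na(v) && !is_whole(v))
        stop(sprintf("row %d: duration of stage %s is %s, not a whole day",
                     i, s, format(v)))
    }
    if (!is_whole(row$days_in_death_stage))
      stop(sprintf("row %d: days_in_death_stage is not a whole number", i))
    k <- match(row$death_stage, scheme$stages)
    if (is.na(k))
      stop(sprintf("row %d: unknown death stage '%s'", i, row$death_stage))
    completed <- scheme$stages[seq_len(k - 1L)]
    dur <- vapply(completed, function(s) as.integer(row[[paste0("d_", s)]]),
                  integer(1))
    if (anyNA(dur))
      stop(sprintf("row %d: missing duration for completed stage %s",
                   i, paste(completed[is.na(dur)], collapse = ",")))
    f <- fec_by_id[[row$id]]
    if (is.null(f)) f <- data.frame(age = integer(), eggs = integer())
    f <- f[order(f$age), , drop = FALSE]
    rownames(f) <- NULL
    if (nrow(f) && row$sex != "female")
      stop(sprintf("row %d (id %s): fecundity recorded for sex '%s'",
                   i, row$id, row$sex))
    rec <- individual_record(row$id, row$treatment, row$sex,
                             dur, row$death_stage,
                             as.integer(row$days_in_death_stage), f)
    if ("death_age" %in% names(tab) && !is.na(row$death_age) &&
        death_age(rec) != row$death_age)
      stop(sprintf(
        "row %d: stage durations sum to death age %d but file says %d",
        i, death_age(rec), as.integer(row$death_age)))
    rec
  })
  cht <- cohort(records, scheme, tab$treatment[1L])
  v <- validate_cohort(cht)
  if (length(v)) stop("invalid cohort:\n  ", paste(v, collapse = "\n  "))
  cht
}
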