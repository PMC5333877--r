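#' Define an ordered developmental stage scheme
#'
#' A stage scheme lists the developmental stages of a cohort in the order
#' they are passed through (egg first, adult last) and, optionally, a
#' many-to-one grouping that maps raw stages onto coarser analysis stages.
#' Grouping is how variable instar counts are reconciled across treatments:
#' cohorts reared at different temperatures may moult through five, six or
#' seven larval instars, and the later instars are pooled into a single
#' analysis stage so that age-stage matrices share one column set.
#'
#' @param stages character vector of raw stage labels, in developmental
#'   order. Must start with \code{"egg"} and end with \code{"adult"}.
#' @param grouping named character vector mapping raw stage labels to
#'   analysis stage labels (many-to-one, order preserving). Stages not
#'   named are mapped to themselves. \code{NULL} means identity.
#' @return an object of class \code{stage_scheme} with elements
#'   \code{stages} (raw labels), \code{grouping} (full raw-to-analysis map)
#'   and \code{analysis_stages} (grouped labels, in order).
#' @examples
#' # seven instars with the 5th-7th pooled into one analysis stage
#' sc <- stage_scheme(
#'   c("egg", paste0("L", 1:7), "pupa", "adult"),
#'   grouping = c(L5 = "L5-7", L6 = "L5-7", L7 = "L5-7")
#' )
#' sc$analysis_stages
#' @export
stage_scheme <- function(stages, grouping = NULL) {
  stages <- as.character(stages)
  if (anyDuplicated(stages))
    stop("stage labels must be unique")
  if (length(stages) < 2L)
    stop("a scheme needs at least an egg and an adult stage")
  if (stages[1L] != "egg")
    stop("the first stage must be 'egg'")
  if (stages[length(stages)] != "adult")
    stop("the last stage must be 'adult'")

  full <- stats::setNames(stages, stages)
  if (!is.null(grouping)) {
    grouping <- unlist(grouping)
    unknown <- setdiff(names(grouping), stages)
    if (length(unknown))
      stop("grouping names unknown stages: ", paste(unknown, collapse = ", "))
    full[names(grouping)] <- grouping
  }
  if (full[["egg"]] != "egg" || full[["adult"]] != "adult")
    stop("egg and adult cannot be grouped away")

  analysis <- unique(unname(full))
  # order preservation: the analysis index must be non-decreasing along the
  # raw order, so a later raw stage never maps to an earlier analysis stage
  idx <- match(unname(full), analysis)
  if (any(diff(idx) < 0L))
    stop("grouping must preserve stage order")

  structure(
    list(stages = stages, grouping = full, analysis_stages = analysis),
    class = "stage_scheme"
  )
}

#' @export
print.stage_scheme <- function(x, ...) {
  cat("<stage_scheme> raw:", paste(x$stages, collapse = " > "), "\n")
  if (!identical(x$stages, x$analysis_stages))
    cat("  grouped to:", paste(x$analysis_stages, collapse = " > "), "\n")
  invisible(x)
}

#' Convenience scheme for an insect with a given number of instars
#'
#' Builds \code{egg, L1, ..., Lk, pupa, adult} and pools instars from
#' \code{group_from} upward into a single analysis stage, the usual device
#' for comparing cohorts whose instar number varies with temperature.
#'
#' @param n_instars number of larval instars (>= 1)
#' @param group_from first instar of the pooled terminal group, or
#'   \code{NULL} for no grouping. Default pools from the 5th instar on.
#' @return a \code{stage_scheme}
#' @examples
#' instar_scheme(7)$analysis_stages  # egg L1..L4 L5-7 pupa adult
#' @export
instar_scheme <- function(n_instars, group_from = 5L) {
  stopifnot(n_instars >= 1L)
  stages <- c("egg", paste0("L", seq_len(n_instars)), "pupa", "adult")
  grouping <- NULL
  if (!is.null(group_from) && n_instars > group_from) {
    pooled <- paste0("L", group_from:n_instars)
    lab <- paste0("L", group_from, "-", n_instars)
    grouping <- stats::setNames(rep(lab, length(pooled)), pooled)
  }
  stage_scheme(stages, grouping)
}

is_stage_scheme <- function(x) inherits(x, "stage_scheme")

#' Read or write a stage scheme as YAML
#'
#' @param path file path
#' @return \code{read_scheme} returns a \code{stage_scheme};
#'   \code{write_scheme} returns \code{path} invisibly.
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  grouping <- if (length(obj$grouping)) unlist(obj$grouping) else NULL
  stage_scheme(obj$stages, grouping)
}

#' @rdname read_scheme
#' @param scheme a \code{stage_scheme}
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(is_stage_scheme(scheme))
  explicit <- scheme$grouping[scheme$grouping != names(scheme$grouping)]
  yaml::write_yaml(
    list(stages = scheme$stages, grouping = as.list(explicit)),
    path
  )
  invisible(path)
}
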