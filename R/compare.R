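#' One-way analysis of variance across treatment groups
#'
#' Classical fixed-effects decomposition, fitted with \code{stats::lm}.
#' Returns the pooled mean-square error and residual degrees of freedom
#' needed downstream by the LSD comparisons. When the within-group
#' variance is exactly zero but group means differ, the F statistic is
#' infinite and the p-value is reported as 0 by convention.
#'
#' @param groups named list of numeric vectors, one per group (>= 2
#'   groups, each with >= 2 values)
#' @return an \code{anova_result}: list with \code{groups} (label, n,
#'   mean, se), \code{F}, \code{df} (between, within), \code{p},
#'   \code{mse}
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs at least 2 values: ",
         paste(names(groups)[ns < 2L], collapse = ", "))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  means <- vapply(groups, mean, numeric(1))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    # zero within-variance: means are either all equal (nothing to test)
    # or trivially separated; by convention F = Inf and p = 0 then
    mse <- 0
    sep <- stats::var(rep(means, ns)) > 0
    Fv <- if (sep) Inf else 0
    p <- if (sep) 0 else 1
    dfs <- c(between = length(groups) - 1L,
             within = length(y) - length(groups))
  } else {
    tab <- stats::anova(stats::lm(y ~ g))
    mse <- tab["Residuals", "Mean Sq"]
    Fv <- tab["g", "F value"]
    p <- tab["g", "Pr(>F)"]
    dfs <- c(between = unname(tab["g", "Df"]),
             within = unname(tab["Residuals", "Df"]))
  }
  gstats <- data.frame(
    label = names(groups),
    n = as.integer(ns),
    mean = vapply(groups, mean, numeric(1)),
    se = vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                numeric(1)),
    row.names = NULL
  )
  structure(
    list(groups = gstats, F = Fv, df = dfs, p = p, mse = mse),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p, x$mse))
  invisible(x)
}

#' Pairwise Fisher LSD p-values
#'
#' Unprotected pairwise t tests using the pooled ANOVA mean square and its
#' residual degrees of freedom; with unequal group sizes the standard
#' error of a difference is \code{sqrt(MSE (1/n_i + 1/n_j))}.
#'
#' @param result an \code{anova_result}
#' @return symmetric matrix of two-sided p-values (diagonal NA)
#' @export
lsd_pairwise <- function(result) {
  stopifnot(inherits(result, "anova_result"))
  gs <- result$groups
  k <- nrow(gs)
  p <- matrix(NA_real_, k, k, dimnames = list(gs$label, gs$label))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sed <- sqrt(result$mse * (1 / gs$n[i] + 1 / gs$n[j]))
    if (sed == 0) {
      pv <- if (gs$mean[i] == gs$mean[j]) 1 else 0
    } else {
      tval <- (gs$mean[i] - gs$mean[j]) / sed
      pv <- 2 * stats::pt(-abs(tval), result$df[["within"]])
    }
    p[i, j] <- p[j, i] <- pv
  }
  p
}

# Insert-and-absorb compact letter display. sig is a logical matrix over
# groups in display order (TRUE = significantly different). Returns a list
# of index sets (letter columns) such that a pair shares a column iff it
# is not significantly different.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!sig[i, j]) next
    for (ci in rev(seq_along(cols))) {
      col <- cols[[ci]]
      if (i %in% col && j %in% col) {
        # split the column: one copy without i, one without j
        cols[[ci]] <- setdiff(col, i)
        cols[[length(cols) + 1L]] <- setdiff(col, j)
      }
    }
    # absorb columns that became subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          !(length(cols[[a]]) == length(cols[[b]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by their highest-ranked member for stable lettering
  cols[order(vapply(cols, min, integer(1)))]
}

#' Compact letter display from Fisher LSD comparisons
#'
#' Groups are sorted by descending mean and letters assigned by the
#' insert-and-absorb algorithm, so that two groups share a letter exactly
#' when their LSD comparison is non-significant at level alpha; 'a' marks
#' the largest mean. The assignment depends only on the pattern of
#' significant pairs, not on the order groups were supplied in.
#'
#' @param result an \code{anova_result}
#' @param alpha significance level (default 0.05)
#' @return a \code{letter_display}: list with \code{letters} (named
#'   character vector, group -> letter string), \code{alpha},
#'   \code{p} (the pairwise LSD p matrix), \code{order} (labels by
#'   descending mean)
#' @export
lsd_letters <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "anova_result"), alpha > 0, alpha < 1)
  p <- lsd_pairwise(result)
  ord <- order(-result$groups$mean)
  labs <- result$groups$label[ord]
  sig <- p[labs, labs, drop = FALSE] < alpha
  diag(sig) <- FALSE
  cols <- cld_insert_absorb(sig)
  lets <- stats::setNames(rep("", length(labs)), labs)
  for (ci in seq_along(cols)) {
    for (m in cols[[ci]])
      lets[labs[m]] <- paste0(lets[labs[m]], letters[ci])
  }
  structure(
    list(letters = lets[result$groups$label], alpha = alpha, p = p,
         order = labs),
    class = "letter_display"
  )
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("LSD letters (alpha = %g):\n", x$alpha))
  for (g in x$order) cat(sprintf("  %-12s %s\n", g, x$letters[[g]]))
  invisible(x)
}

#' Format a lettered mean comparison row
#'
#' Produces the familiar table cells \code{"mean+/-SE letter"} (e.g.
#' \code{"35.20±0.30a"}) for one measured variable compared across
#' treatments.
#'
#' @param groups named list of numeric vectors, one per treatment
#' @param alpha significance level for the letters
#' @param digits decimal places for mean and SE
#' @return named character vector of formatted cells, in input order
#' @export
lettered_row <- function(groups, alpha = 0.05, digits = 2) {
  an <- one_way_anova(groups)
  ld <- lsd_letters(an, alpha)
  cells <- sprintf(paste0("%.", digits, "f±%.", digits, "f%s"),
                   an$groups$mean, an$groups$se,
                   ld$letters[an$groups$label])
  stats::setNames(cells, an$groups$label)
}
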