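#!/usr/bin/env Rscript
# Stage 4: compare the reproducing treatments (21-33 C) trait by trait
# with one-way ANOVA and Fisher LSD letters, emitting the familiar
# "mean+/-SE letter" table rows (letters: 'a' = largest mean; groups
# sharing a letter are not significantly different at the 5% level).

suppressMessages(library(agestage))

temps <- c(21, 24, 27, 30, 33)
cohorts <- lapply(temps, function(tm) {
  label <- paste0(tm, "C")
  sp <- read_cohort_spec(file.path("results/cohorts",
                                   paste0("spec_", label, ".yaml")))
  read_cohort(file.path("results/cohorts", paste0("cohort_", label, ".csv")),
              stage_scheme(c(names(sp$stages), "adult")))
})
names(cohorts) <- paste0(temps, "C")

trait <- function(cht, what) {
  adults <- Filter(function(r) r$death_stage == "adult", cht$records)
  switch(what,
    preadult = vapply(adults, function(r) sum(r$stage_durations), numeric(1)),
    longevity_female = vapply(Filter(function(r) r$sex == "female", adults),
                              function(r) as.numeric(r$days_in_death_stage),
                              numeric(1)),
    longevity_male = vapply(Filter(function(r) r$sex == "male", adults),
                            function(r) as.numeric(r$days_in_death_stage),
                            numeric(1)),
    fecundity = {
      rs <- reproduction_summary(cht)
      if (rs$empty) numeric(0) else rs$per_female$total_eggs
    },
    apop = {
      rs <- reproduction_summary(cht)
      if (rs$empty) numeric(0) else rs$per_female$apop
    })
}

rows <- list()
for (what in c("preadult", "longevity_female", "longevity_male",
               "fecundity", "apop")) {
  groups <- lapply(cohorts, trait, what = what)
  groups <- groups[lengths(groups) >= 2L]
  cells <- lettered_row(groups, alpha = 0.05, digits = 2)
  an <- one_way_anova(groups)
  rows[[what]] <- data.frame(trait = what, treatment = names(cells),
                             cell = unname(cells),
                             F = an$F, p = an$p, row.names = NULL)
  message(sprintf("%-16s F(%d,%d) = %8.2f  p = %.3g   %s", what,
                  an$df[["between"]], an$df[["within"]], an$F, an$p,
                  paste(names(cells), cells, collapse = "  ")))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/comparison_table.csv", row.names = FALSE)
message("comparison table written to results/comparison_table.csv")
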