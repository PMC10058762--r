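## Baseline characteristics table across trajectory classes.

#' Summarize baseline characteristics by trajectory class
#'
#' Builds a characteristics table in the usual cohort-paper shape: one
#' column for the whole sample, one per class, and a p-value column —
#' one-way ANOVA for continuous variables, chi-square for categorical
#' ones. A mortality-rate row (per 1000 person-years, from
#' [person_year_rates()]) is appended when follow-up columns are present.
#'
#' @param records per-subject data frame including a `class` column.
#' @param continuous,categorical variable names to summarize; defaults
#'   cover the standard covariate set, intersected with what is present.
#' @return data frame with columns `variable`, `all`, `class_1..G`, `p`;
#'   continuous entries are "mean (sd)", categorical entries are "x%".
#' @export
summarize_baseline <- function(records,
                               continuous = c("baseline_dnas", "age_entry",
                                              "physical_activity", "bmi",
                                              "energy_kcal", "income"),
                               categorical = c("chronic_disease", "medicine",
                                               "smoker", "drinker")) {
  stopifnot("class" %in% names(records))
  cl <- factor(records$class)
  G <- nlevels(cl)
  small <- any(table(cl) < 2L)
  continuous <- intersect(continuous, names(records))
  categorical <- intersect(categorical, names(records))
  fmt_ms <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                stats::sd(x, na.rm = TRUE))
  rows <- list()
  for (v in continuous) {
    x <- records[[v]]
    p <- if (small) NA_real_ else
      summary(stats::aov(x ~ cl))[[1L]][["Pr(>F)"]][1L]
    rows[[v]] <- c(variable = v, all = fmt_ms(x),
                   vapply(levels(cl), function(l) fmt_ms(x[cl == l]), ""),
                   p = format_pval(p))
  }
  for (v in categorical) {
    x <- records[[v]]
    num <- if (is.factor(x)) x else factor(x)
    p <- if (small || nlevels(num) < 2L) NA_real_ else
      suppressWarnings(stats::chisq.test(table(num, cl))$p.value)
    pct <- function(z) {
      z <- z[!is.na(z)]
      sprintf("%.1f%%", 100 * mean(z == levels(num)[nlevels(num)]))
    }
    rows[[v]] <- c(variable = v, all = pct(num),
                   vapply(levels(cl), function(l) pct(num[cl == l]), ""),
                   p = format_pval(p))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", "all", paste0("class_", levels(cl)), "p")
  rownames(out) <- NULL
  if (all(c("followup_years", "event") %in% names(records))) {
    rt_all <- person_year_rates(records, group_by = NULL)
    rt <- person_year_rates(records, group_by = "class")
    fmt_rt <- function(r) sprintf("%.1f (%.1f-%.1f)", r$rate, r$lo, r$hi)
    out <- rbind(out, c("mortality_rate_per_1000py", fmt_rt(rt_all),
                        vapply(levels(cl), function(l)
                          fmt_rt(rt[rt$group == l, ]), ""),
                        NA_character_))
  }
  out
}

format_pval <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}
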