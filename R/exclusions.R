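## Cohort eligibility filter.

#' Apply cohort eligibility rules
#'
#' Removes subjects violating any of the study's eligibility criteria:
#' baseline age outside `age_range`; fewer than `min_rounds` dietary
#' rounds; energy intake outside `energy_range` (kcal/day) at any retained
#' round; missing food-group values; missing key covariates (individual
#' income, smoking status, chronic disease history, medicine use, physical
#' activity); a cancer flag; or a pregnancy/lactation flag. Exclusion
#' counts are reported per criterion, counting every subject that violates
#' that criterion (so a subject violating two rules appears in both
#' counts); the removed set is the union. The filter is idempotent.
#'
#' @param panel long intake panel (see [score_panel()]); food-group columns
#'   are every column other than `subject_id`, `round`, `age_years`,
#'   `energy_kcal`.
#' @param survival per-subject table with `age_entry` and (optionally) the
#'   key covariates and `cancer` / `pregnant_lactating` flags; missing
#'   columns simply cannot trigger their rule.
#' @param age_range allowed baseline age window (years).
#' @param min_rounds minimum number of dietary rounds.
#' @param energy_range allowed energy intake (kcal/day).
#' @param key_covariates covariate columns whose missingness excludes.
#' @return list with filtered `panel` and `survival`, `log`: data frame of
#'   per-criterion exclusion counts, `n_before`, `n_after`.
#' @export
apply_exclusions <- function(panel, survival,
                             age_range = c(30, 60), min_rounds = 3L,
                             energy_range = c(500, 8000),
                             key_covariates = c("income", "smoker",
                                                "chronic_disease",
                                                "medicine",
                                                "physical_activity")) {
  ids <- survival$subject_id
  if (!all(panel$subject_id %in% ids))
    stop("panel contains subjects absent from the survival table")
  viol <- list()
  viol$age <- ids[survival$age_entry < age_range[1L] |
                    survival$age_entry > age_range[2L]]
  rounds <- table(factor(panel$subject_id, levels = ids))
  viol$few_rounds <- ids[rounds < min_rounds]
  if ("energy_kcal" %in% names(panel)) {
    bad <- !is.na(panel$energy_kcal) &
      (panel$energy_kcal < energy_range[1L] |
         panel$energy_kcal > energy_range[2L])
    viol$energy <- unique(panel$subject_id[bad])
  } else viol$energy <- character(0)
  food_cols <- setdiff(names(panel),
                       c("subject_id", "round", "age_years", "energy_kcal"))
  miss_food <- rowSums(is.na(panel[, food_cols, drop = FALSE])) > 0 |
    (if ("energy_kcal" %in% names(panel)) is.na(panel$energy_kcal) else FALSE)
  viol$missing_food <- unique(panel$subject_id[miss_food])
  kc <- intersect(key_covariates, names(survival))
  viol$missing_covariate <- if (length(kc))
    ids[rowSums(is.na(survival[, kc, drop = FALSE])) > 0] else character(0)
  viol$cancer <- if ("cancer" %in% names(survival))
    ids[isTRUE_vec(survival$cancer)] else character(0)
  viol$pregnant_lactating <- if ("pregnant_lactating" %in% names(survival))
    ids[isTRUE_vec(survival$pregnant_lactating)] else character(0)

  drop <- unique(unlist(viol))
  log <- data.frame(criterion = names(viol),
                    n_excluded = vapply(viol, length, 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(panel = panel[!panel$subject_id %in% drop, , drop = FALSE],
       survival = survival[!ids %in% drop, , drop = FALSE],
       log = log, n_before = length(ids),
       n_after = length(ids) - length(drop))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
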