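#' Construct a dietary guideline specification
#'
#' A guideline specification holds, for each food group, the recommended
#' intake range (grams/day) and the reference intake used as the target
#' point of the non-adherence score. When no explicit reference is given it
#' defaults to the midpoint of the recommended range.
#'
#' @param groups character vector of unique food-group names.
#' @param low,high numeric vectors, recommended minimum and maximum intake
#'   in grams/day for each group; `0 <= low <= high`.
#' @param reference optional numeric vector of reference intakes; must lie
#'   inside `[low, high]`. Defaults to `(low + high) / 2`.
#' @return An object of class `guideline_spec`: a data frame with columns
#'   `group`, `low`, `high`, `reference`.
#' @examples
#' guideline_spec(c("dairy", "salt"), low = c(300, 0), high = c(500, 5))
#' @export
guideline_spec <- function(groups, low, high, reference = NULL) {
  groups <- as.character(groups)
  n <- length(groups)
  if (n < 1L) stop("guideline must contain at least one food group")
  if (length(low) != n || length(high) != n)
    stop("'low' and 'high' must have one entry per food group")
  if (anyDuplicated(groups))
    stop("duplicated food-group name(s): ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "))
  low <- as.numeric(low); high <- as.numeric(high)
  bad <- which(!is.finite(low) | !is.finite(high) | low < 0 | low > high)
  if (length(bad))
    stop("invalid recommended range in row(s) ",
         paste(bad, collapse = ", "), " (group ",
         paste(groups[bad], collapse = ", "),
         "): need 0 <= low <= high")
  if (is.null(reference)) {
    reference <- (low + high) / 2
  } else {
    reference <- as.numeric(reference)
    if (length(reference) != n)
      stop("'reference' must have one entry per food group")
    bad <- which(!is.finite(reference) | reference < low | reference > high)
    if (length(bad))
      stop("reference outside recommended range in row(s) ",
           paste(bad, collapse = ", "), " (group ",
           paste(groups[bad], collapse = ", "), ")")
  }
  out <- data.frame(group = groups, low = low, high = high,
                    reference = reference, stringsAsFactors = FALSE)
  class(out) <- c("guideline_spec", "data.frame")
  out
}

#' Read a guideline specification from a CSV file
#'
#' The file must have columns `group,low,high` and optionally `reference`
#' (all intakes in grams/day). A missing `reference` column, or `NA` entries
#' in it, default to the range midpoint.
#'
#' @param path path to a CSV file.
#' @return A [guideline_spec()] object.
#' @export
load_guideline <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "low", "high")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("guideline file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  ref <- if ("reference" %in% names(tab)) as.numeric(tab$reference) else
    rep(NA_real_, nrow(tab))
  mid <- (as.numeric(tab$low) + as.numeric(tab$high)) / 2
  ref[is.na(ref)] <- mid[is.na(ref)]
  guideline_spec(tab$group, tab$low, tab$high, ref)
}

#' Default 10-group guideline table
#'
#' Returns the guideline shipped with the package: the ten food groups of
#' the Chinese Dietary Guidelines (cereals and tubers, vegetables, fruits,
#' meat, aquatic products, soybean and nuts, eggs, dairy products, edible
#' oil, salt) with approximate pagoda-style recommended ranges. The numeric
#' ranges are editable defaults, not an authoritative transcription; users
#' with a specific guideline edition should load their own table with
#' [load_guideline()].
#'
#' @return A [guideline_spec()] object with 10 rows.
#' @export
default_guideline <- function() {
  load_guideline(system.file("extdata", "cdg_guideline.csv",
                             package = "dnastraj", mustWork = TRUE))
}

#' @export
print.guideline_spec <- function(x, ...) {
  cat("Dietary guideline:", nrow(x), "food groups (g/day)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

## internal: coerce intake input to a numeric matrix aligned to the guideline
intake_matrix <- function(grams, guideline) {
  if (is.data.frame(grams)) grams <- as.matrix(grams)
  if (!is.matrix(grams)) grams <- matrix(grams, nrow = 1L)
  n <- nrow(guideline)
  if (!is.null(colnames(grams))) {
    miss <- setdiff(guideline$group, colnames(grams))
    if (length(miss))
      stop("intake is missing food group(s): ", paste(miss, collapse = ", "))
    grams <- grams[, guideline$group, drop = FALSE]
  } else if (ncol(grams) != n) {
    stop("intake must have exactly ", n, " food-group entries")
  }
  storage.mode(grams) <- "double"
  grams
}

#' Normalize intake vectors against a guideline
#'
#' Puts raw gram intakes on the scale the non-adherence score is computed
#' on. In `"ratio"` mode (the default used throughout the package) each
#' group is divided by its guideline reference, so the reference point maps
#' to 1 in every coordinate and the score is independent of the units of
#' any single group. `"grams"` leaves intakes untouched. `"zscore"`
#' standardizes each group by sample statistics that must be supplied.
#'
#' @param grams numeric vector (one observation), matrix, or data frame of
#'   g/day intakes; columns aligned to (or named after) the guideline groups.
#' @param guideline a [guideline_spec()].
#' @param mode one of `"ratio"`, `"grams"`, `"zscore"`.
#' @param stats for `mode = "zscore"`, a list with numeric vectors `mean`
#'   and `sd` per group (e.g. from [intake_stats()]).
#' @return A list with `x`: the normalized intake matrix, and `reference`:
#'   the reference point on the same scale.
#' @export
normalize_intake <- function(grams, guideline,
                             mode = c("ratio", "grams", "zscore"),
                             stats = NULL) {
  mode <- match.arg(mode)
  x <- intake_matrix(grams, guideline)
  if (any(x < 0, na.rm = TRUE)) stop("negative intake values are not allowed")
  ref <- guideline$reference
  switch(mode,
    ratio = {
      if (any(ref <= 0))
        stop("ratio normalization needs a positive reference for every ",
             "group; group(s) with reference 0: ",
             paste(guideline$group[ref <= 0], collapse = ", "),
             ". Supply a positive reference or use another mode.")
      list(x = sweep(x, 2L, ref, "/"), reference = rep(1, length(ref)))
    },
    grams = list(x = x, reference = ref),
    zscore = {
      if (is.null(stats) || is.null(stats$mean) || is.null(stats$sd))
        stop("zscore mode requires 'stats' with per-group 'mean' and 'sd' ",
             "(see intake_stats())")
      if (any(stats$sd <= 0)) stop("zscore mode: all group SDs must be > 0")
      list(x = sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/"),
           reference = (ref - stats$mean) / stats$sd)
    })
}

#' Per-group sample statistics for z-score normalization
#'
#' @param panel an intake panel (see [score_panel()]).
#' @param guideline a [guideline_spec()].
#' @return list with `mean` and `sd` per food group.
#' @export
intake_stats <- function(panel, guideline) {
  x <- intake_matrix(panel[, guideline$group, drop = FALSE], guideline)
  list(mean = colMeans(x), sd = apply(x, 2L, stats::sd))
}

#' Dietary non-adherence score
#'
#' The score of an intake vector is its distance from the guideline
#' reference point after normalization: with normalized intakes \eqn{x_i}
#' and normalized references \eqn{y_i} over the n food groups,
#' `euclidean` gives \eqn{\sqrt{\sum_i (x_i - y_i)^2}} and `manhattan`
#' gives \eqn{\sum_i |x_i - y_i|}. A score of 0 means the diet sits exactly
#' at the recommended reference in every group; larger scores mean larger
#' deviation from the recommended pattern.
#'
#' @inheritParams normalize_intake
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return Numeric vector of scores, one per row of `grams`.
#' @examples
#' g <- guideline_spec(letters[1:3], low = c(0, 0, 0), high = c(2, 4, 6))
#' compute_dnas(c(1, 2, 3), g)            # at the reference -> 0
#' compute_dnas(c(2, 2, 3), g)            # one group doubled -> 1
#' @export
compute_dnas <- function(grams, guideline,
                         metric = c("euclidean", "manhattan"),
                         mode = c("ratio", "grams", "zscore"),
                         stats = NULL) {
  metric <- match.arg(metric)
  nm <- normalize_intake(grams, guideline, mode, stats)
  d <- sweep(nm$x, 2L, nm$reference, "-")
  if (any(!is.finite(d)))
    stop("non-finite normalized intake value(s); check for missing intakes")
  if (metric == "euclidean") sqrt(rowSums(d^2)) else rowSums(abs(d))
}

#' Score a longitudinal intake panel
#'
#' @param panel data frame in long format with columns `subject_id`,
#'   `round`, `age_years`, optionally `energy_kcal`, and one column per
#'   guideline food group (g/day).
#' @inheritParams compute_dnas
#' @return Data frame `subject_id, round, age_years, score`, ordered by
#'   subject then round, one row per input row.
#' @export
score_panel <- function(panel, guideline,
                        metric = c("euclidean", "manhattan"),
                        mode = c("ratio", "grams", "zscore"),
                        stats = NULL) {
  need <- c("subject_id", "round", "age_years")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("intake panel is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(panel) == 0L)
    return(data.frame(subject_id = character(), round = integer(),
                      age_years = numeric(), score = numeric()))
  key <- paste(panel$subject_id, panel$round, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (subject_id, round) pair(s): ",
         paste(utils::head(sub("\r", ", ", unique(key[duplicated(key)])), 5L),
               collapse = "; "))
  score <- compute_dnas(panel[, setdiff(names(panel), c(need, "energy_kcal")),
                              drop = FALSE],
                        guideline, metric, mode, stats)
  out <- data.frame(subject_id = panel$subject_id, round = panel$round,
                    age_years = panel$age_years, score = score,
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$round), , drop = FALSE]
}
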