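# Staged dispersion analysis: partition longitudinal fitted parameters
# into reproductive stages and quantify the variability reduction that
# accompanies a successful insemination.

#' Assign reproductive stage labels
#'
#' Cows with a positive pregnancy outcome get three stages: `"stage1"`
#' before (and including) the insemination day, `"stage2"` for pregnancy
#' days 1--15 and `"stage3"` from day 16 on.  Cows whose insemination
#' failed are split into `"before"` and `"after"` at the insemination day,
#' the insemination day itself counting as `"after"`.  Nonpregnant records
#' with no insemination on file are `"before"`.
#'
#' @param records data.frame with `pregnant_outcome`,
#'   `days_since_insemination` and `insemination_day` columns (a cohort
#'   table or any one row of it).
#' @return character vector of stage labels, one per record.
#' @examples
#' assign_stage(data.frame(pregnant_outcome = TRUE, insemination_day = 10,
#'                         days_since_insemination = c(-3, 0, 15, 16)))
#' @export
assign_stage <- function(records) {
  dsi <- records$days_since_insemination
  preg <- records$pregnant_outcome
  insem <- records$insemination_day
  if (any(preg & (is.na(dsi) | is.na(insem))))
    stop("assign_stage: pregnant record lacks a resolved insemination day",
         call. = FALSE)
  if (any(!preg & is.na(dsi) & !is.na(insem)))
    stop("assign_stage: record has an insemination day but no days_since_insemination",
         call. = FALSE)
  ifelse(preg,
         ifelse(dsi <= 0, "stage1", ifelse(dsi <= 15, "stage2", "stage3")),
         ifelse(is.na(dsi) | dsi < 0, "before", "after"))
}

stage_order <- function() c("stage1", "stage2", "stage3", "before", "after")

#' Per-stage dispersion of fitted parameters
#'
#' Sample mean and SD (n - 1 denominator) of each requested parameter
#' within each reproductive stage.  A stage with fewer than two points
#' reports `NA` for its SDs (absent, not zero).
#'
#' @param table cohort table carrying fitted-parameter columns (e.g. from
#'   [fit_cohort()]) and either a `stage` column or the fields needed by
#'   [assign_stage()].
#' @param parameters character vector of parameter columns to summarise.
#' @return data.frame with one row per stage: `stage`, `n_points`, then
#'   `mean_<param>` and `sd_<param>` columns.
#' @export
stage_dispersion <- function(table,
                             parameters = c("delta_eps", "tau_ps",
                                            "alpha", "sigma_dc")) {
  missing_cols <- setdiff(parameters, names(table))
  if (length(missing_cols))
    stop("stage_dispersion: missing parameter columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stage <- if ("stage" %in% names(table)) table$stage else assign_stage(table)
  stages <- intersect(stage_order(), unique(stage))
  out <- data.frame(stage = stages,
                    n_points = vapply(stages, function(s) sum(stage == s),
                                      integer(1)))
  for (p in parameters) {
    out[[paste0("mean_", p)]] <- vapply(stages, function(s)
      mean(table[[p]][stage == s]), numeric(1))
    out[[paste0("sd_", p)]] <- vapply(stages, function(s) {
      v <- table[[p]][stage == s]
      if (length(v) < 2) NA_real_ else stats::sd(v)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Percent drop in variability
#'
#' `100 * (sd_reference - sd_comparison) / sd_reference`; negative when
#' variability increased.
#'
#' @param sd_reference reference-stage SD, > 0.
#' @param sd_comparison comparison-stage SD.
#' @return percent drop.
#' @examples
#' percent_drop(1.0, 0.5)  # 50
#' @export
percent_drop <- function(sd_reference, sd_comparison) {
  if (any(!is.finite(sd_reference)) || any(sd_reference <= 0))
    stop("percent_drop: sd_reference must be positive (drop undefined otherwise)",
         call. = FALSE)
  100 * (sd_reference - sd_comparison) / sd_reference
}

#' Headline variability drop of one parameter
#'
#' Convenience wrapper: stage dispersion of `parameter`, then the percent
#' drop between a reference and a comparison stage.  The default pairing
#' contrasts the pre-insemination state with the post-day-16 plateau for
#' pregnant cows; use `c("before", "after")` for nonpregnant cohorts.
#'
#' @inheritParams stage_dispersion
#' @param parameter one parameter column name.
#' @param pairing length-2 character vector `(reference, comparison)`.
#' @return list: `drop_pct`, `sd_reference`, `sd_comparison`, `summary`
#'   (the full [stage_dispersion()] table).
#' @export
variability_drop <- function(table, parameter = "delta_eps",
                             pairing = c("stage1", "stage3")) {
  summ <- stage_dispersion(table, parameters = parameter)
  col <- paste0("sd_", parameter)
  i_ref <- match(pairing[1], summ$stage)
  i_cmp <- match(pairing[2], summ$stage)
  if (is.na(i_ref) || is.na(i_cmp))
    stop(sprintf("variability_drop: stages %s/%s absent from the table",
                 pairing[1], pairing[2]), call. = FALSE)
  sd_ref <- summ[[col]][i_ref]
  sd_cmp <- summ[[col]][i_cmp]
  list(drop_pct = percent_drop(sd_ref, sd_cmp),
       sd_reference = sd_ref, sd_comparison = sd_cmp, summary = summ)
}
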