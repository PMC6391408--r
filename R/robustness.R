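# Ensemble robustness classification and regional aggregation.
#
# A projected change is "robust" when more than 50% of the climate models
# show a significant period difference (two-sided t-test at the 95% level)
# AND more than 80% of the models agree on the sign of change. Both
# thresholds are strict; ties are non-robust.

#' Aggregate watershed fluxes to a regional load
#'
#' Multiplies each member watershed's per-area flux by its area and sums,
#' yielding the regional nitrogen load per climate model.
#'
#' @param period_means Tibble `watershed_id`, `model_id`,
#'   `mean_flux_kg_km2_yr` (or an annual table with `flux_kg_km2_yr` and
#'   `year`, in which case the load is per model-year).
#' @param members Character vector of member watershed ids (nonempty).
#' @param watersheds Tibble `watershed_id`, `area_km2`.
#' @return Tibble `model_id` (and `year` if present), `load_kg_yr`.
#' @export
aggregate_load <- function(period_means, members, watersheds) {
  if (length(members) == 0L) rn_invalid_input("region has no member watersheds")
  missing_ws <- setdiff(members, watersheds$watershed_id)
  if (length(missing_ws)) {
    rn_missing_input(paste0("no area for watershed(s): ",
                            paste(head(missing_ws, 3), collapse = ", ")))
  }
  vcol <- if ("mean_flux_kg_km2_yr" %in% names(period_means)) {
    "mean_flux_kg_km2_yr"
  } else if ("flux_kg_km2_yr" %in% names(period_means)) {
    "flux_kg_km2_yr"
  } else {
    rn_invalid_input("flux column not found")
  }
  sub <- period_means[period_means$watershed_id %in% members, , drop = FALSE]
  have <- unique(sub$watershed_id)
  if (!all(members %in% have)) {
    rn_missing_input(paste0("no flux for watershed(s): ",
                            paste(head(setdiff(members, have), 3),
                                  collapse = ", ")))
  }
  sub <- dplyr::left_join(sub, watersheds[c("watershed_id", "area_km2")],
                          by = "watershed_id")
  keys <- intersect(c("model_id", "year"), names(sub))
  sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(load_kg_yr = sum(.data[[vcol]] * .data$area_km2),
                     .groups = "drop")
}

#' Percent change between a historical and a future value
#'
#' @param hist Historical value(s), strictly positive.
#' @param fut Future value(s).
#' @return `100 * (fut - hist) / hist`.
#' @export
percent_change <- function(hist, fut) {
  if (any(!is.finite(hist)) || any(hist <= 0)) {
    rn_invalid_input("historical value must be finite and > 0")
  }
  100 * (fut - hist) / hist
}

#' Classify robustness of an ensemble of period changes
#'
#' Per climate model, a two-sided Welch t-test at the 95% confidence level
#' compares the future against the historical annual values; significance is
#' counted when p < 0.05, and the sign of change is the sign of the
#' difference in model means (a zero difference counts toward neither sign).
#' The change is robust when strictly more than 50% of models are
#' significant and strictly more than 80% share the majority sign.
#'
#' @param historical,future Tibbles with columns `model_id` and `value`
#'   (annual values, >= 2 per model in each period; the same models must
#'   appear in both).
#' @return One-row tibble: `n_models`, `n_significant`, `n_sign_agree`
#'   (majority-sign count), `robust`.
#' @export
classify_robust <- function(historical, future) {
  for (d in list(historical, future)) {
    if (!all(c("model_id", "value") %in% names(d))) {
      rn_invalid_input("need columns `model_id` and `value`")
    }
  }
  # statistics run over the future ensemble's members; each must have a
  # historical counterpart (RCP ensembles are subsets of the historical one)
  models <- sort(unique(future$model_id))
  if (!all(models %in% historical$model_id)) {
    rn_invalid_input("every future model needs a historical counterpart")
  }
  n_sig <- 0L
  n_pos <- 0L
  n_neg <- 0L
  for (m in models) {
    h <- historical$value[historical$model_id == m]
    f <- future$value[future$model_id == m]
    if (length(h) < 2L || length(f) < 2L) {
      rn_invalid_input(sprintf("model %s has fewer than 2 values per period", m))
    }
    # degenerate (zero-variance) samples have no defined t statistic and
    # count as non-significant
    p <- tryCatch(t.test(f, h, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    if (is.finite(p) && p < 0.05) n_sig <- n_sig + 1L
    d <- mean(f) - mean(h)
    if (d > 0) n_pos <- n_pos + 1L else if (d < 0) n_neg <- n_neg + 1L
  }
  n <- length(models)
  n_agree <- max(n_pos, n_neg)
  tibble::tibble(
    n_models = n,
    n_significant = n_sig,
    n_sign_agree = n_agree,
    robust = (n_sig / n > 0.5) && (n_agree / n > 0.8))
}

#' Ensemble mean and spread of per-model changes
#'
#' @param changes Numeric vector of per-model percent changes (>= 2 models).
#' @return Named vector `mean`, `sd` (sample SD, n - 1 denominator).
#' @export
ensemble_summary <- function(changes) {
  if (length(changes) < 2L) {
    rn_invalid_input("need at least 2 models for an ensemble summary")
  }
  c(mean = mean(changes), sd = stats::sd(changes))
}

#' Multi-scenario direction-agreement mask
#'
#' Per unit (watershed, region or grid cell), emits the across-scenario mean
#' change when at least `min_agree` of the scenarios agree on the direction
#' of change, and masks the unit otherwise. A zero change counts toward
#' neither direction.
#'
#' @param changes Tibble `unit_id`, `scenario_id`, `change`; every unit must
#'   carry all scenarios.
#' @param min_agree Minimum number of same-sign scenarios (default 5 of 6).
#' @return Tibble `unit_id`, `n_scenarios`, `n_pos`, `n_neg`, `agree`
#'   (logical), `mean_change` (NA where masked).
#' @export
scenario_agreement <- function(changes, min_agree = 5) {
  need <- c("unit_id", "scenario_id", "change")
  if (!all(need %in% names(changes))) {
    rn_invalid_input("need columns unit_id, scenario_id, change")
  }
  n_scen <- length(unique(changes$scenario_id))
  cnt <- dplyr::count(changes, .data$unit_id)
  if (any(cnt$n != n_scen)) {
    rn_missing_input("every unit must carry all scenarios")
  }
  changes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_scenarios = dplyr::n(),
      n_pos = sum(.data$change > 0),
      n_neg = sum(.data$change < 0),
      mean_change = mean(.data$change),
      .groups = "drop") |>
    dplyr::mutate(
      agree = pmax(.data$n_pos, .data$n_neg) >= min_agree,
      mean_change = ifelse(.data$agree, .data$mean_change, NA_real_)) |>
    dplyr::select("unit_id", "n_scenarios", "n_pos", "n_neg", "agree",
                  "mean_change")
}

#' Regional change results with robustness
#'
#' The full change-assessment pipeline for a pair of flux fields: per region
#' and climate model, annual loads are aggregated, 30-year period means and
#' percent changes computed, the ensemble mean and SD summarized, and
#' robustness classified from the per-model annual regional loads.
#'
#' @param hist_field,fut_field Flux fields from [run_projection()] covering
#'   the respective periods.
#' @param world A `tn_world` (or list with `watersheds` and `regions`).
#' @param hist_period,fut_period Periods as in [period_mean()] (defaults:
#'   the canonical historical and end-of-century periods).
#' @param regions Optional tibble `region_id`, `watershed_id` overriding
#'   `world$regions`.
#' @return Tibble per region: period-mean loads (ensemble means),
#'   `pct_change_mean`, `pct_change_sd`, robustness counts and flag.
#' @export
change_results <- function(hist_field, fut_field, world,
                           hist_period = NULL, fut_period = NULL,
                           regions = NULL) {
  per <- canonical_periods()
  hist_period <- hist_period %||%
    list(start = per$start[1], end = per$end[1])
  fut_period <- fut_period %||%
    list(start = per$start[3], end = per$end[3])
  regions <- regions %||% world$regions
  ws <- world$watersheds

  out <- lapply(split(regions$watershed_id, regions$region_id), function(members) {
    lh <- aggregate_load(hist_field, members, ws)   # per model-year loads
    lf <- aggregate_load(fut_field, members, ws)
    lh <- lh[lh$year %in% hist_period$start:hist_period$end, , drop = FALSE]
    lf <- lf[lf$year %in% fut_period$start:fut_period$end, , drop = FALSE]
    if (nrow(lh) == 0L || nrow(lf) == 0L) {
      rn_missing_input("flux fields do not cover the requested periods")
    }
    rb <- classify_robust(
      dplyr::rename(lh, value = "load_kg_yr"),
      dplyr::rename(lf, value = "load_kg_yr"))
    mh <- lh |>
      dplyr::group_by(.data$model_id) |>
      dplyr::summarise(hist = mean(.data$load_kg_yr), .groups = "drop")
    mf <- lf |>
      dplyr::group_by(.data$model_id) |>
      dplyr::summarise(fut = mean(.data$load_kg_yr), .groups = "drop")
    pm <- dplyr::inner_join(mh, mf, by = "model_id")
    pc <- percent_change(pm$hist, pm$fut)
    es <- if (nrow(pm) >= 2) ensemble_summary(pc) else c(mean = mean(pc), sd = NA_real_)
    tibble::tibble(
      hist_load_kg_yr = mean(pm$hist),
      fut_load_kg_yr = mean(pm$fut),
      pct_change_mean = es[["mean"]],
      pct_change_sd = es[["sd"]],
      n_models = rb$n_models,
      n_significant = rb$n_significant,
      n_sign_agree = rb$n_sign_agree,
      robust = rb$robust)
  })
  dplyr::bind_rows(out, .id = "region_id")
}
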