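# Empirical log-linear model of riverine total nitrogen (TN) flux.
#
# ln(Q_TN) = b0 + b1 * f_NANI + b2 * P_Annual + b3 * P_MAM,ext + b4 * LU_D,C
# f_NANI   = asinh(NANI / 2)
#
# Q_TN is TN flux [kg N km^-2 y^-1], NANI net anthropogenic nitrogen input
# [kg N km^-2 y^-1], P_Annual annual precipitation [mm], P_MAM,ext extreme
# March-May precipitation [mm], LU_D,C the developed + cropland cover [%].

#' Coefficients of the TN loading model
#'
#' Constructs the coefficient set of the log-linear TN flux model. The
#' defaults are the published regression coefficients of the model calibrated
#' on 280 catchment-years of observed loads.
#'
#' @param intercept Intercept on the ln(kg N km^-2 y^-1) scale.
#' @param f_nani Slope on the asinh-transformed NANI (dimensionless).
#' @param p_annual Slope per mm of annual precipitation.
#' @param p_mam_ext Slope per mm of extreme springtime precipitation.
#' @param lu_dc Slope per percent of developed + cropland cover.
#'
#' @return A named numeric vector of class `tn_coefficients`.
#' @export
#' @examples
#' tn_coefficients()
tn_coefficients <- function(intercept = 0.538, f_nani = 0.438,
                            p_annual = 0.0012, p_mam_ext = 0.0033,
                            lu_dc = 0.0213) {
  x <- c(intercept = intercept, f_nani = f_nani, p_annual = p_annual,
         p_mam_ext = p_mam_ext, lu_dc = lu_dc)
  if (!is.numeric(x) || length(x) != 5L || any(!is.finite(x))) {
    rn_invalid_input("all five model coefficients must be finite numbers")
  }
  structure(x, class = "tn_coefficients")
}

#' @export
print.tn_coefficients <- function(x, ...) {
  cat("TN loading model coefficients:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Inverse hyperbolic sine transform of NANI
#'
#' Maps net anthropogenic nitrogen input onto the scale used by the TN
#' model: `f_NANI = asinh(NANI / 2) = ln(NANI/2 + sqrt((NANI/2)^2 + 1))`.
#' Unlike a log transform it is defined for zero and negative inputs
#' (net-export watersheds), is odd, and tracks `ln(NANI)` for large inputs.
#'
#' @param nani Numeric vector of NANI values in kg N km^-2 y^-1.
#' @return Transformed values (dimensionless), same length as `nani`.
#' @export
#' @examples
#' transform_nani(c(-2, 0, 2))
transform_nani <- function(nani) {
  if (!is.numeric(nani) || length(nani) == 0L) {
    rn_invalid_input("`nani` must be a non-empty numeric vector")
  }
  if (any(!is.finite(nani))) {
    rn_invalid_input("`nani` contains non-finite values")
  }
  asinh(nani / 2)
}

check_predictors <- function(data) {
  need <- c("nani", "p_annual", "p_mam_ext", "lu_dc")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rn_invalid_input(paste0("missing predictor column(s): ",
                            paste(miss, collapse = ", ")))
  }
  for (v in need) {
    if (any(!is.finite(data[[v]]))) {
      rn_invalid_input(paste0("non-finite values in predictor `", v, "`"))
    }
  }
  if (any(data$p_mam_ext < 0) || any(data$p_annual < data$p_mam_ext)) {
    rn_invalid_input("require p_annual >= p_mam_ext >= 0")
  }
  if (any(data$lu_dc < 0 | data$lu_dc > 100)) {
    rn_invalid_input("`lu_dc` must lie in [0, 100] percent")
  }
  invisible(data)
}

#' Predict log TN flux
#'
#' Evaluates the linear predictor of the TN model for one or more predictor
#' records.
#'
#' @param data A data frame (or list) with columns `nani`
#'   (kg N km^-2 y^-1), `p_annual` (mm), `p_mam_ext` (mm) and `lu_dc`
#'   (percent, 0-100).
#' @param coefficients A [tn_coefficients()] set.
#' @return Numeric vector of ln TN flux, ln(kg N km^-2 y^-1).
#' @export
#' @examples
#' predict_ln_tn(data.frame(nani = 0, p_annual = 0, p_mam_ext = 0, lu_dc = 0))
predict_ln_tn <- function(data, coefficients = tn_coefficients()) {
  if (!inherits(coefficients, "tn_coefficients")) {
    coefficients <- do.call(tn_coefficients, as.list(coefficients))
  }
  check_predictors(data)
  coefficients[["intercept"]] +
    coefficients[["f_nani"]] * transform_nani(data$nani) +
    coefficients[["p_annual"]] * data$p_annual +
    coefficients[["p_mam_ext"]] * data$p_mam_ext +
    coefficients[["lu_dc"]] * data$lu_dc
}

#' Predict TN flux
#'
#' Exponentiates the linear predictor of [predict_ln_tn()]. No
#' retransformation bias correction is applied; the fitted log-linear model
#' is used directly on the natural scale.
#'
#' @inheritParams predict_ln_tn
#' @return TN flux in kg N km^-2 y^-1 (strictly positive).
#' @export
predict_tn_flux <- function(data, coefficients = tn_coefficients()) {
  exp(predict_ln_tn(data, coefficients))
}

lu_col <- function(category) paste0("lu_", category, "_pct")

lu_predictor <- function(data, subset) {
  cols <- lu_col(subset)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    rn_invalid_input(paste0("calibration data lacks land-use column(s): ",
                            paste(miss, collapse = ", ")))
  }
  rowSums(as.matrix(data[, cols, drop = FALSE]))
}

check_calibration_data <- function(data) {
  need <- c("catchment_id", "year", "tn_flux_kg_km2_yr", "nani_kg_km2_yr",
            "p_annual_mm", "p_mam_ext_mm")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rn_invalid_input(paste0("calibration data missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  if (nrow(data) == 0L) rn_invalid_input("calibration data is empty")
  if (anyDuplicated(data[c("catchment_id", "year")])) {
    rn_invalid_input("duplicate (catchment_id, year) records in calibration data")
  }
  if (any(!is.finite(data$tn_flux_kg_km2_yr)) ||
      any(data$tn_flux_kg_km2_yr <= 0)) {
    rn_invalid_input("observed TN flux must be strictly positive (log is taken)")
  }
  invisible(data)
}

calibration_design <- function(data, lu_subsets) {
  x <- cbind(
    f_nani = transform_nani(data$nani_kg_km2_yr),
    p_annual = data$p_annual_mm,
    p_mam_ext = data$p_mam_ext_mm
  )
  for (i in seq_along(lu_subsets)) {
    v <- lu_predictor(data, lu_subsets[[i]])
    nm <- paste0("lu_", paste(lu_subsets[[i]], collapse = "+"))
    x <- cbind(x, v)
    colnames(x)[ncol(x)] <- nm
  }
  x
}

#' Calibrate the TN loading model
#'
#' Fits the log-linear TN model by ordinary least squares of the log observed
#' flux on the three fixed predictors (transformed NANI, annual
#' precipitation, extreme springtime precipitation) plus one or two summed
#' percent-cover land-use variables.
#'
#' @param data Calibration table with columns `catchment_id`, `year`,
#'   `tn_flux_kg_km2_yr`, `nani_kg_km2_yr`, `p_annual_mm`, `p_mam_ext_mm`
#'   and one `lu_<category>_pct` column per aggregated land-use category.
#' @param lu_subsets A character vector (one land-use variable) or a list of
#'   character vectors (each summed into one variable) naming aggregated
#'   land-use categories. Default: the developed + cropland variable.
#' @return An object of class `tn_model`: coefficient estimates, standard
#'   errors, R-squared, residual SD on the ln scale, BIC and the land-use
#'   subset(s) used.
#' @export
#' @examples
#' cal <- generate_calibration_dataset(world_config(seed = 1), noise_sd = 0)
#' fit <- calibrate_tn_model(cal$data)
#' round(fit$coefficients, 4)
calibrate_tn_model <- function(data, lu_subsets = c("cropland", "developed")) {
  if (is.character(lu_subsets)) lu_subsets <- list(lu_subsets)
  check_calibration_data(data)
  x <- calibration_design(data, lu_subsets)
  p <- ncol(x) + 1L
  if (nrow(data) < p + 2L) {
    rn_invalid_input(sprintf(
      "need at least %d records to fit %d coefficients", p + 2L, p))
  }
  y <- log(data$tn_flux_kg_km2_yr)
  df_fit <- data.frame(.y = y, x, check.names = FALSE)
  fit <- lm(.y ~ ., data = df_fit)
  if (fit$rank < p || any(is.na(coef(fit)))) {
    rn_degenerate_design(
      "rank-deficient design: a predictor is constant or collinear")
  }
  sm <- summary(fit)
  est <- coef(fit)
  names(est)[1] <- "intercept"
  names(est) <- gsub("`", "", names(est), fixed = TRUE)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(est)
  structure(list(
    coefficients = est,
    std_errors = se,
    lu_subsets = lu_subsets,
    r_squared = unname(sm$r.squared),
    residual_sd = unname(sm$sigma),
    bic = BIC(fit),
    n = nrow(data)
  ), class = "tn_model")
}

#' @export
print.tn_model <- function(x, ...) {
  cat("Calibrated TN loading model (ln scale OLS)\n")
  cat(sprintf("  n = %d catchment-years, R^2 = %.3f, residual SD = %.3f\n",
              x$n, x$r_squared, x$residual_sd))
  cat("  land-use variable(s):",
      paste(vapply(x$lu_subsets, paste, "", collapse = "+"), collapse = "; "),
      "\n")
  print(round(rbind(estimate = x$coefficients, se = x$std_errors), 5))
  invisible(x)
}

#' Extract plug-in coefficients from a fitted model
#'
#' Maps a fitted single-land-use-variable model onto a [tn_coefficients()]
#' set usable by the scenario engine.
#'
#' @param model A `tn_model` with exactly one land-use variable.
#' @return A `tn_coefficients` object.
#' @export
as_tn_coefficients <- function(model) {
  stopifnot(inherits(model, "tn_model"))
  if (length(model$lu_subsets) != 1L) {
    rn_invalid_input("model must have exactly one land-use variable")
  }
  est <- model$coefficients
  tn_coefficients(intercept = est[["intercept"]], f_nani = est[["f_nani"]],
                  p_annual = est[["p_annual"]], p_mam_ext = est[["p_mam_ext"]],
                  lu_dc = est[[length(est)]])
}

#' @export
predict.tn_model <- function(object, newdata, type = c("flux", "ln"), ...) {
  type <- match.arg(type)
  lp <- object$coefficients[["intercept"]] +
    object$coefficients[["f_nani"]] * transform_nani(newdata$nani_kg_km2_yr) +
    object$coefficients[["p_annual"]] * newdata$p_annual_mm +
    object$coefficients[["p_mam_ext"]] * newdata$p_mam_ext_mm
  for (i in seq_along(object$lu_subsets)) {
    b <- object$coefficients[[4L + i]]
    lp <- lp + b * lu_predictor(newdata, object$lu_subsets[[i]])
  }
  if (type == "ln") lp else exp(lp)
}

all_subsets <- function(categories) {
  n <- length(categories)
  out <- list()
  for (k in seq_len(n)) {
    cmb <- utils::combn(categories, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

subset_label <- function(lu_subsets) {
  paste(vapply(lu_subsets, function(s) paste(sort(s), collapse = "+"), ""),
        collapse = " | ")
}

#' Exhaustive land-use model selection
#'
#' Considers every candidate land-use predictor formed as a summed
#' percent-cover variable over a nonempty subset of the aggregated land-use
#' categories (and, with `max_lu_predictors = 2`, every unordered pair of
#' disjoint subsets), fits each candidate alongside the three fixed
#' predictors, and returns the fit with minimum BIC. Ties are broken in
#' favour of fewer land-use variables, then lexicographic subset order.
#' Candidates whose design is rank deficient (e.g. a category with no
#' variation) are skipped.
#'
#' @inheritParams calibrate_tn_model
#' @param categories Land-use categories to search over; defaults to all six
#'   aggregated categories present in `data`.
#' @param max_lu_predictors 1 or 2 summed land-use variables per candidate.
#' @return The winning `tn_model`, with a `selection` tibble (candidate
#'   label, number of land-use variables, BIC, R-squared) attached.
#' @export
select_tn_model <- function(data, categories = NULL, max_lu_predictors = 1) {
  check_calibration_data(data)
  if (is.null(categories)) {
    categories <- lu_categories()[lu_col(lu_categories()) %in% names(data)]
  }
  if (length(categories) == 0L) {
    rn_invalid_input("no land-use percent columns found in `data`")
  }
  subsets <- all_subsets(categories)
  candidates <- lapply(subsets, list)
  if (max_lu_predictors >= 2) {
    for (i in seq_along(subsets)) {
      for (j in seq_along(subsets)) {
        if (j <= i) next
        if (length(intersect(subsets[[i]], subsets[[j]])) == 0L) {
          candidates <- c(candidates, list(list(subsets[[i]], subsets[[j]])))
        }
      }
    }
  }

  y <- log(data$tn_flux_kg_km2_yr)
  n <- length(y)
  xfix <- calibration_design(data, list())
  lu_mat <- as.matrix(data[lu_col(categories)])
  colnames(lu_mat) <- categories

  rows <- vector("list", length(candidates))
  best <- NULL
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    xlu <- vapply(cand, function(s) {
      rowSums(lu_mat[, s, drop = FALSE])
    }, numeric(n))
    x <- cbind(1, xfix, xlu)
    fit <- stats::lm.fit(x, y)
    p <- ncol(x)
    if (fit$rank < p) next
    rss <- sum(fit$residuals^2)
    if (rss <= 0) rss <- .Machine$double.xmin
    # BIC of a Gaussian fit: n log(2*pi*rss/n) + n + (p + 1) log(n)
    bic <- n * log(2 * pi * rss / n) + n + (p + 1) * log(n)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    lab <- subset_label(cand)
    rows[[ci]] <- tibble::tibble(candidate = lab, n_lu_vars = length(cand),
                                 bic = bic, r_squared = r2)
    key <- list(bic = bic, n_lu = length(cand), lab = lab)
    if (is.null(best) ||
        key$bic < best$key$bic - 1e-9 ||
        (abs(key$bic - best$key$bic) <= 1e-9 &&
         (key$n_lu < best$key$n_lu ||
          (key$n_lu == best$key$n_lu && key$lab < best$key$lab)))) {
      best <- list(key = key, cand = cand)
    }
  }
  if (is.null(best)) {
    rn_degenerate_design("no candidate land-use model could be fitted")
  }
  model <- calibrate_tn_model(data, lu_subsets = best$cand)
  model$selection <- dplyr::arrange(dplyr::bind_rows(rows), .data$bic)
  model
}

#' Serialize / restore a fitted TN model
#'
#' Writes the fitted model (coefficients, standard errors, land-use subsets,
#' fit statistics) as a YAML document, and reads it back.
#'
#' @param model A `tn_model`.
#' @param path File path.
#' @return `read_fitted_model()` returns the restored `tn_model`.
#' @export
write_fitted_model <- function(model, path) {
  stopifnot(inherits(model, "tn_model"))
  doc <- list(
    coefficients = as.list(model$coefficients),
    std_errors = as.list(model$std_errors),
    lu_subsets = lapply(model$lu_subsets, as.list),
    r_squared = model$r_squared,
    residual_sd = model$residual_sd,
    bic = model$bic,
    n = model$n
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(list(
    coefficients = unlist(doc$coefficients),
    std_errors = unlist(doc$std_errors),
    lu_subsets = lapply(doc$lu_subsets, function(s) unlist(s)),
    r_squared = doc$r_squared,
    residual_sd = doc$residual_sd,
    bic = doc$bic,
    n = doc$n
  ), class = "tn_model")
}
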