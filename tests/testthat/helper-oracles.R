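# Independent oracles: hand-coded statistics kept deliberately separate from
# the implementation paths they check.

# Welch two-sample two-sided t-test p-value via the incomplete beta function
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  # P(|T| > |t|) = I_{df/(df+t^2)}(df/2, 1/2)
  pbeta(df / (df + t^2), df / 2, 0.5)
}

# brute-force robustness classifier: explicit per-model loop
oracle_classify <- function(historical, future) {
  models <- sort(unique(future$model_id))
  n_sig <- 0L; n_pos <- 0L; n_neg <- 0L
  for (m in models) {
    h <- historical$value[historical$model_id == m]
    f <- future$value[future$model_id == m]
    if (oracle_welch_p(f, h) < 0.05) n_sig <- n_sig + 1L
    d <- mean(f) - mean(h)
    if (d > 0) n_pos <- n_pos + 1L
    if (d < 0) n_neg <- n_neg + 1L
  }
  n <- length(models)
  list(n_models = n, n_significant = n_sig,
       n_sign_agree = max(n_pos, n_neg),
       robust = (n_sig / n > 0.5) && (max(n_pos, n_neg) / n > 0.8))
}

# order-statistic percentile with linear interpolation, coded from the
# h = (n - 1) p + 1 definition
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# naive day-by-day precipitation features for a single watershed-model series
oracle_features <- function(series, year, baseline, season = 3:5, p = 0.95) {
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  pop <- c()
  for (i in seq_len(nrow(series))) {
    if (yr[i] %in% baseline && mo[i] %in% season) pop <- c(pop, series$pr_mm[i])
  }
  thr <- oracle_percentile(pop, p)
  ann <- 0; ext <- 0
  for (i in seq_len(nrow(series))) {
    if (yr[i] == year) {
      ann <- ann + series$pr_mm[i]
      if (mo[i] %in% season && series$pr_mm[i] > thr) {
        ext <- ext + series$pr_mm[i]
      }
    }
  }
  list(threshold = thr, annual = ann, extreme = ext)
}

# random multi-year daily series for one watershed-model pair
random_toy_series <- function(years = 1981:1985, wet_p = 0.3, scale = 8) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  pr <- ifelse(runif(length(dates)) < wet_p,
               rgamma(length(dates), shape = 0.8, scale = scale), 0)
  data.frame(date = dates, pr_mm = pr)
}
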