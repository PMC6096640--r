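#' Standardize genetic values against a reference year
#'
#' Genetic gain is reported in units of the reference-year standard
#' deviation, centred at the reference-year mean (so the reference year has
#' mean zero and unit SD by construction).
#'
#' @param values Numeric vector of true genetic values.
#' @param ref_mean,ref_sd Reference mean and SD (`ref_sd > 0`).
#' @return Standardized values.
#' @export
standardize_gain <- function(values, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) abort("ref_sd must be > 0")
  (values - ref_mean) / ref_sd
}

#' Realized effective population size from genic-variance decay
#'
#' Under drift the genic variance decays as sigma2_(t+1) = sigma2_t (1 -
#' delta_C), so a gamma generalized linear model with log link of genic
#' variance on year has slope beta with delta_C = 1 - exp(beta), and the
#' realized effective population size is Ne = 1 / (2 delta_C). When the
#' fitted variance trend is non-decreasing (delta_C <= 0), Ne is undefined
#' and reported as `NA`.
#'
#' @param data Data frame with a year column and a positive genic-variance
#'   column.
#' @param year_col,var_col Column names (defaults `year`,
#'   `genic_variance`; a `genic_var` column is picked up automatically).
#' @return An `ne_estimate` with fields `delta_C`, `Ne`, `beta`, `n_years`.
#' @examples
#' d <- data.frame(year = 0:19, genic_variance = 0.95^(0:19))
#' glance(estimate_ne(d)) # delta_C = 0.05, Ne = 10
#' @export
estimate_ne <- function(data, year_col = "year", var_col = "genic_variance") {
  data <- as.data.frame(data)
  if (!var_col %in% names(data) && "genic_var" %in% names(data)) {
    var_col <- "genic_var"
  }
  year <- data[[year_col]]
  v <- data[[var_col]]
  if (is.null(year) || is.null(v)) abort("year / genic variance columns not found")
  if (length(v) < 3) abort("Ne estimation needs at least 3 years")
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("genic variances must all be positive")
  }
  # suppressWarnings: the gamma AIC can NaN-warn on near-exact fits
  fit <- suppressWarnings(glm(v ~ year, family = Gamma(link = "log"),
                              control = glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- unname(coef(fit)["year"])
  delta_C <- 1 - exp(beta)
  structure(list(delta_C = delta_C,
                 Ne = if (delta_C > 0) 1 / (2 * delta_C) else NA_real_,
                 beta = beta, n_years = length(v), fit = fit,
                 data = tibble(year = year, genic_variance = v)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> delta_C = %.5g, Ne = %s (over %d years)\n",
              x$delta_C,
              if (is.na(x$Ne)) "undefined (no decay)" else sprintf("%.4g", x$Ne),
              x$n_years))
  invisible(x)
}

#' Efficiency of converting genetic diversity into genetic gain
#'
#' Robust linear regression (Huber M-estimator, tuning constant 1.345,
#' iteratively reweighted least squares, at most 50 iterations) of achieved
#' standardized genetic gain y_t on lost genetic diversity x_t = 1 -
#' sigma_t / sigma_ref. The slope is the efficiency: standardized gain
#' extracted per unit of relative genic standard deviation spent. Trailing
#' exactly-repeated (y, x) points - a program sitting at its selection
#' limit - are removed before fitting.
#'
#' @param data Data frame with gain and diversity-loss columns.
#' @param gain_col,loss_col Column names (defaults `gain`,
#'   `diversity_loss`).
#' @return An `efficiency_estimate` with fields `slope` (efficiency),
#'   `intercept` and `n_points`.
#' @examples
#' d <- data.frame(gain = seq(0, 10, length.out = 5),
#'                 diversity_loss = seq(0, 0.4, length.out = 5))
#' glance(estimate_efficiency(d))$efficiency # 25
#' @export
estimate_efficiency <- function(data, gain_col = "gain",
                                loss_col = "diversity_loss") {
  data <- as.data.frame(data)
  y <- data[[gain_col]]
  x <- data[[loss_col]]
  if (is.null(y) || is.null(x)) abort("gain / diversity-loss columns not found")
  keep <- c(TRUE, abs(diff(y)) > 0 | abs(diff(x)) > 0)
  y <- y[keep]
  x <- x[keep]
  if (length(unique(paste(y, x))) < 3) {
    abort("efficiency estimation needs at least 3 distinct points")
  }
  # 50 IRLS steps are the estimator's budget; no warning if it stops there
  fit <- suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                                    maxit = 50))
  structure(list(slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 n_points = length(y), fit = fit,
                 data = tibble(gain = y, diversity_loss = x)),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> efficiency (slope) = %.4g over %d points\n",
              x$slope, x$n_points))
  invisible(x)
}

#' Aggregate replicate series
#'
#' Per (scenario, year, metric): mean over replicates and a
#' normal-approximation 95% confidence interval (mean +/- 1.96 SE).
#'
#' @param results Long tibble with columns `replicate`, `year`, `metric`,
#'   `value` and optionally `scenario`.
#' @return A `metrics_summary` tibble with `mean`, `lo`, `hi`, `n`.
#' @export
summarize_replicates <- function(results) {
  grp <- intersect(c("scenario", "year", "metric"), names(results))
  out <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(grp))),
    n = sum(!is.na(.data$value)),
    se = stats::sd(.data$value, na.rm = TRUE) / sqrt(pmax(.data$n, 1)),
    mean = mean(.data$value, na.rm = TRUE),
    .groups = "drop")
  out$se[!is.finite(out$se)] <- 0
  out$lo <- out$mean - 1.96 * out$se
  out$hi <- out$mean + 1.96 * out$se
  out <- dplyr::select(out, dplyr::all_of(grp), "mean", "lo", "hi", "n")
  class(out) <- c("metrics_summary", class(out))
  out
}
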