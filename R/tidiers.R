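#' Tidy a fitted genomic prediction model
#' @param x A `gp_model`.
#' @param ... Unused.
#' @return Tibble with one row per marker: `term`, `estimate`.
#' @export
tidy.gp_model <- function(x, ...) {
  tibble(term = names(x$effects), estimate = unname(x$effects))
}

#' @rdname tidy.gp_model
#' @export
glance.gp_model <- function(x, ...) {
  tibble(sigma2_marker = unname(x$variance_components["marker"]),
         sigma2_residual = unname(x$variance_components["residual"]),
         lambda = x$lambda, intercept = x$intercept,
         n_records = x$n_records, n_markers = length(x$effects))
}

#' Tidy an effective-population-size estimate
#' @param x An `ne_estimate`.
#' @param ... Unused.
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble(term = c("beta", "delta_C", "Ne"),
         estimate = c(x$beta, x$delta_C, x$Ne))
}

#' @rdname tidy.ne_estimate
#' @export
glance.ne_estimate <- function(x, ...) {
  tibble(delta_C = x$delta_C, Ne = x$Ne, n_years = x$n_years)
}

#' Tidy an efficiency estimate
#' @param x An `efficiency_estimate`.
#' @param ... Unused.
#' @export
tidy.efficiency_estimate <- function(x, ...) {
  tibble(term = c("(Intercept)", "diversity_loss"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.efficiency_estimate
#' @export
glance.efficiency_estimate <- function(x, ...) {
  tibble(efficiency = x$slope, intercept = x$intercept, n_points = x$n_points)
}

#' Tidy a cross plan
#' @param x A `cross_plan`.
#' @param ... Unused.
#' @return The crossing list as a plain tibble (`female`, `male`).
#' @export
tidy.cross_plan <- function(x, ...) {
  tibble(female = x$female, male = x$male)
}

#' @rdname tidy.cross_plan
#' @export
glance.cross_plan <- function(x, ...) {
  n <- contributions(x)
  ev <- attr(x, "evaluation")
  out <- tibble(n_crosses = attr(x, "n_crosses"),
                n_parents = sum(n > 0),
                max_contribution = max(n))
  if (!is.null(ev)) out <- dplyr::bind_cols(out, ev)
  out
}
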