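#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeat comparison
#'
#' @param x a [compare_conditions()] result.
#' @param ... unused.
#' @return One row per (repeat, condition): `biological_repeat`,
#'   `condition`, `raw`, `pair_mean`, `normalized`.
#' @method tidy repeat_comparison
#' @export
tidy.repeat_comparison <- function(x, ...) {
  x$per_repeat
}

#' @rdname tidy.repeat_comparison
#' @return For `glance`: a one-row tibble with the measure name, test,
#'   statistic, two-tailed p-value, significance stars, repeat count and
#'   degeneracy flag.
#' @method glance repeat_comparison
#' @export
glance.repeat_comparison <- function(x, ...) {
  tibble::tibble(measure_name = x$measure_name,
                 condition_a = x$conditions[1], condition_b = x$conditions[2],
                 test = x$test, statistic = x$statistic,
                 p_value = x$p_value, stars = x$stars,
                 n_repeats = x$n_repeats, degenerate = x$degenerate)
}

#' Tidy a diffusion fit
#'
#' @param x a [fit_diffusion()] result.
#' @param ... unused.
#' @return `tidy`: one row per fitted quantity (`D`, `offset`,
#'   `sigma_loc`); `glance`: a one-row summary.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("D", "offset", "sigma_loc"),
                 estimate = c(x$D, x$offset, x$sigma_loc),
                 unit = c("um^2/s", "um^2", "um"))
}

#' @rdname tidy.diffusion_fit
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, offset = x$offset, sigma_loc = x$sigma_loc,
                 negative_D = x$negative_D, n_lags = x$n_lags,
                 r_squared = summary(x$fit)$r.squared)
}

#' @method glance repeat_anova
#' @export
glance.repeat_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 df_between = x$df_between, df_within = x$df_within,
                 n_groups = x$n_groups, stars = x$stars,
                 degenerate = x$degenerate)
}
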