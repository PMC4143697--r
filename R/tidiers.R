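#' Tidy posterior draws of a model fit
#'
#' One row per parameter with posterior mean, standard deviation, a central
#' credible interval, and (when available) the Gelman-Rubin statistic.
#' Locus indicators are summarised by their posterior inclusion frequency.
#'
#' @param x An [fbcm_fit()] object.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble: `parameter`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`, `rhat`.
#' @export
tidy.fbcm_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  pars <- setdiff(names(x$draws), c("chain", "iteration"))
  rhat <- setNames(x$diagnostics$rhat, x$diagnostics$parameter)
  purrr::map_dfr(pars, function(p) {
    d <- x$draws[[p]]
    tibble::tibble(parameter = p,
                   estimate = mean(d),
                   std_error = sd(d),
                   conf_low = quantile(d, a, names = FALSE),
                   conf_high = quantile(d, 1 - a, names = FALSE),
                   rhat = rhat[p][[1]] %|NA|% NA_real_)
  })
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' One-row summary of a model fit
#'
#' @param x An [fbcm_fit()] object.
#' @param ... Unused.
#' @return Tibble with posterior means of the main parameters, the largest
#'   continuous-parameter R-hat, and the draw count.
#' @export
glance.fbcm_fit <- function(x, ...) {
  tibble::tibble(
    beta1 = mean(x$draws$beta1),
    beta2 = mean(x$draws$beta2),
    sigma2_phi = mean(x$draws$sigma2_phi),
    sigma2_eps = mean(x$draws$sigma2_eps),
    rhat_max = if (all(is.na(x$diagnostics$rhat))) NA_real_
               else max(x$diagnostics$rhat),
    n_draws = nrow(x$draws),
    n_chains = max(x$draws$chain)
  )
}

#' Trace plot of a model fit
#'
#' @param object An [fbcm_fit()] object.
#' @param parameters Which parameters to trace (default the five continuous
#'   model parameters).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbcm_fit <- function(object,
                              parameters = c("mu", "beta1", "beta2",
                                             "sigma2_phi", "sigma2_eps"),
                              ...) {
  long <- tidyr::pivot_longer(
    object$draws[, c("chain", "iteration", parameters)],
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain", x = "kept iteration", y = NULL)
}

#' Manhattan-style plot of a gene scan
#'
#' Gene Bayes factors by chromosomal start position, with the decision
#' cutoff drawn as a horizontal line.
#'
#' @param object An `fbcm_scan` tibble from [scan_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbcm_scan <- function(object, ...) {
  ok <- object[object$status == "ok", ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$start, y = .data$bf,
                                   colour = .data$chrom)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "bf_cutoff") %||% 2,
                        linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "gene start position", y = "gene Bayes factor") +
    ggplot2::theme(legend.position = "none")
}

#' Power curves from a simulation grid
#'
#' @param object An `fbcm_power` tibble from [power_grid()].
#' @param ... Unused.
#' @return A ggplot object: rejection rate against causal proportion, one
#'   curve per effect size, with binomial confidence ribbons.
#' @export
autoplot.fbcm_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$prop_causal, y = .data$rate,
                                       colour = factor(.data$beta1),
                                       fill = factor(.data$beta1))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "proportion of causal variants",
                  y = "empirical power",
                  colour = "beta1", fill = "beta1")
}
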