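#' Composite-hypothesis threshold from the residual scale
#'
#' The gene-level hypothesis compares `|beta1| > eps` (with at least one
#' active locus) against its complement; `eps` is tied to the residual
#' noise as `0.2 * sigma_eps_hat` so that "effect" means a fifth of a
#' residual standard deviation or more.
#'
#' @param sigma_eps_hat Positive residual-scale estimate, typically from
#'   [estimate_sigma_eps_null()].
#' @return `0.2 * sigma_eps_hat`.
#' @export
compute_epsilon <- function(sigma_eps_hat) {
  if (!is.numeric(sigma_eps_hat) || length(sigma_eps_hat) != 1 ||
      !is.finite(sigma_eps_hat) || sigma_eps_hat <= 0) {
    stop("`sigma_eps_hat` must be a positive number", call. = FALSE)
  }
  0.2 * sigma_eps_hat
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Prior odds of the composite association event
#'
#' Under the prior `beta1 ~ N(0, sigma_beta^2)` and independent
#' `alpha_k ~ Bern(p_k)` with `p_k ~ Beta(1, 1)` (so marginally
#' `alpha_k ~ Bern(1/2)`), the prior probability of the joint event
#' `{|beta1| > eps and sum(alpha) > 0}` is
#' `(1 - erf(x)) (1 - 0.5^K)` with `x = eps / (sqrt(2) sigma_beta)`, and the
#' prior odds are
#' `(1 - erf(x)) (1 - 0.5^K) / (erf(x) (1 - 0.5^K) + 0.5^K)`.
#'
#' @param epsilon Effect threshold (>= 0).
#' @param sigma_beta Prior standard deviation of `beta1`.
#' @param K Number of loci in the gene (>= 1).
#' @return Positive prior odds; equals `2^K - 1` at `epsilon = 0`.
#' @examples
#' prior_odds(0, 100, 3)       # 7
#' prior_odds(0.28, 100, 50)
#' @export
prior_odds <- function(epsilon, sigma_beta, K) {
  stopifnot(epsilon >= 0, sigma_beta > 0, K >= 1)
  x <- epsilon / (sqrt(2) * sigma_beta)
  e <- erf(x)
  pK <- 0.5^K
  (1 - e) * (1 - pK) / (e * (1 - pK) + pK)
}

event_prob <- function(m, n) (m + 0.5) / (n + 1)  # continuity-corrected

#' Hybrid gene-level Bayes factor from posterior draws
#'
#' Estimates the posterior probability of the composite event
#' `{|beta1| > eps and sum(alpha_k) > 0}` as a continuity-corrected draw
#' fraction `(m + 0.5) / (n + 1)`, forms its odds, and divides by the
#' analytic [prior_odds()].  Also computes a marginal Bayes factor for each
#' locus indicator (prior odds 1 since `P(alpha_k = 1) = 1/2` marginally).
#'
#' @param fit An [fbcm_fit()] object with free indicators.
#' @param sigma_eps_hat Residual-scale estimate used to set the threshold;
#'   required unless `epsilon` is given directly.
#' @param epsilon Optional explicit threshold, overriding
#'   `0.2 * sigma_eps_hat`.
#' @param joint If `TRUE` (default) the event includes the `sum(alpha) > 0`
#'   condition; `FALSE` uses the plain `|beta1| > eps` event in both
#'   numerator and prior.
#' @return An object of class `fbcm_bf`: list with `gene_bf`, `prior_odds`,
#'   `posterior_odds`, `epsilon`, `n_draws`, `effect_size` (posterior mean
#'   of `beta1`) and `variant_bfs` (tibble: `variant_id`, `posterior_freq`,
#'   `bf`).
#' @export
fbcm_bf <- function(fit, sigma_eps_hat = NULL, epsilon = NULL, joint = TRUE) {
  if (!inherits(fit, "fbcm_fit")) stop("`fit` must be an fbcm_fit", call. = FALSE)
  n <- nrow(fit$draws)
  if (n == 0) stop("fit has no draws", call. = FALSE)
  if (is.null(epsilon)) {
    if (is.null(sigma_eps_hat)) {
      stop("supply `sigma_eps_hat` (or an explicit `epsilon`)", call. = FALSE)
    }
    epsilon <- compute_epsilon(sigma_eps_hat)
  }
  K <- fit$K
  sigma_beta <- sqrt(fit$control$sigma2_beta)
  alpha_cols <- paste0("alpha_", seq_len(K))
  alpha_mat <- as.matrix(fit$draws[, alpha_cols, drop = FALSE])

  in_event <- abs(fit$draws$beta1) > epsilon
  if (joint) in_event <- in_event & rowSums(alpha_mat) > 0
  p1 <- event_prob(sum(in_event), n)
  post_odds <- p1 / (1 - p1)
  pr_odds <- if (joint) prior_odds(epsilon, sigma_beta, K)
             else {
               x <- epsilon / (sqrt(2) * sigma_beta)
               (1 - erf(x)) / erf(x)
             }

  variant_bfs <- tibble::tibble(
    variant_id = if (!is.null(fit$variant_ids)) fit$variant_ids
                 else paste0("v", seq_len(K)),
    posterior_freq = colMeans(alpha_mat),
    bf = vapply(seq_len(K), function(k) {
      variant_bf(alpha_mat[, k])
    }, numeric(1))
  )

  structure(list(gene_bf = post_odds / pr_odds,
                 prior_odds = pr_odds,
                 posterior_odds = post_odds,
                 epsilon = epsilon,
                 n_draws = n,
                 effect_size = mean(fit$draws$beta1),
                 variant_bfs = variant_bfs,
                 joint = joint),
            class = "fbcm_bf")
}

#' Marginal Bayes factor for one locus indicator
#'
#' Continuity-corrected posterior odds of `alpha_k = 1` divided by the prior
#' odds, which equal 1 because the Beta(1,1) hyperprior makes
#' `P(alpha_k = 1) = 1/2` marginally.
#'
#' @param alpha_draws 0/1 vector of posterior draws of one indicator.
#' @return Positive, finite Bayes factor.
#' @export
variant_bf <- function(alpha_draws) {
  n <- length(alpha_draws)
  if (n == 0) stop("empty draw sequence", call. = FALSE)
  p1 <- event_prob(sum(alpha_draws), n)
  p1 / (1 - p1)
}

#' Jeffreys-style grade for a Bayes factor
#' @param bf Positive Bayes factor.
#' @return A descriptive label ("negative", "barely worth mentioning",
#'   "substantial", "strong", "very strong", "decisive").
#' @export
bf_grade <- function(bf) {
  cut(bf, c(-Inf, 1, 3, 10, 30, 100, Inf),
      labels = c("negative", "barely worth mentioning", "substantial",
                 "strong", "very strong", "decisive"),
      right = FALSE)
}

#' @exportS3Method base::print
print.fbcm_bf <- function(x, ...) {
  cat("Gene Bayes factor: ", signif(x$gene_bf, 4),
      " (", as.character(bf_grade(x$gene_bf)), ")\n", sep = "")
  cat("  posterior odds ", signif(x$posterior_odds, 4),
      " / prior odds ", signif(x$prior_odds, 4),
      ", epsilon = ", signif(x$epsilon, 4),
      ", ", x$n_draws, " draws\n", sep = "")
  cat("  effect size (posterior mean beta1): ",
      signif(x$effect_size, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fbcm_bf
#' @param x An `fbcm_bf` object.
#' @param ... Unused.
#' @export
tidy.fbcm_bf <- function(x, ...) x$variant_bfs

#' @rdname fbcm_bf
#' @export
glance.fbcm_bf <- function(x, ...) {
  tibble::tibble(gene_bf = x$gene_bf,
                 prior_odds = x$prior_odds,
                 posterior_odds = x$posterior_odds,
                 epsilon = x$epsilon,
                 effect_size = x$effect_size,
                 n_draws = x$n_draws)
}
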