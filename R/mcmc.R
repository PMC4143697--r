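#' MCMC control settings
#'
#' @param iterations Total sweeps per chain (default 50,000).
#' @param burn_in Sweeps discarded from the start of each chain; default
#'   half of `iterations`.
#' @param chains Number of independent chains started from dispersed initial
#'   values (default 3; at least 2 are needed for the Gelman-Rubin
#'   diagnostic).
#' @param sigma2_beta Prior variance of the fixed effects (intercept,
#'   within- and between-family effects, covariate coefficients); default
#'   `1e4`, a noninformative scale for phenotypes of order 1.
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @param ig_a,ig_b Shape and rate of the Inverse-Gamma priors on the two
#'   variance components (default 0.01, 0.01).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 50000L,
                         burn_in = iterations %/% 2L,
                         chains = 3L,
                         sigma2_beta = 1e4,
                         thin = 1L,
                         ig_a = 0.01, ig_b = 0.01) {
  stopifnot(iterations >= 2, burn_in >= 0, burn_in < iterations,
            chains >= 1, sigma2_beta > 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains),
                 sigma2_beta = sigma2_beta,
                 thin = as.integer(thin),
                 ig_a = ig_a, ig_b = ig_b),
            class = "mcmc_control")
}

#' Linear predictor of the collapsed family model
#'
#' Evaluates, for every offspring row of a collapsed gene,
#' `mu + x'c + beta1 (alpha[r] D_r + alpha[s] D_s) +
#'  beta2 (gamma[r] GE_r + gamma[s] GE_s) + phi_family`.
#' Pseudolocus indices (`r` or `s` equal to 0) contribute exactly zero.
#'
#' @param state Named list with elements `mu`, `beta1`, `beta2`, `alpha`
#'   (length K+1 with the pseudolocus at position 1), `gamma` (same),
#'   `phi` (length M) and optionally `covar_coef`.
#' @param gene A [collapse_gene()] result.
#' @return Numeric vector, one value per offspring.
#' @export
linear_predictor <- function(state, gene) {
  K <- attr(gene, "K")
  if (length(state$alpha) != K + 1 || length(state$gamma) != K + 1) {
    stop("`alpha` and `gamma` must have length K + 1 (pseudolocus first)",
         call. = FALSE)
  }
  a <- state$alpha; g <- state$gamma
  eta <- state$mu +
    state$beta1 * (a[gene$r + 1] * gene$D_r + a[gene$s + 1] * gene$D_s) +
    state$beta2 * (g[gene$r + 1] * gene$GE_r + g[gene$s + 1] * gene$GE_s) +
    state$phi[gene$family]
  cn <- attr(gene, "covariate_names")
  if (length(cn)) {
    eta <- eta + as.matrix(gene[, cn, drop = FALSE]) %*% state$covar_coef
  }
  as.numeric(eta)
}

#' Log joint density of data and parameters
#'
#' Sum of the Gaussian likelihood, the Gaussian family-effect terms, the
#' Bernoulli terms for the spike indicators, the (flat) Beta hyperpriors,
#' the normal priors on the fixed effects, and the Inverse-Gamma priors on
#' the variances.  Used as the reference density for sampler validation.
#'
#' @inheritParams linear_predictor
#' @param control An [mcmc_control()] (supplies the prior settings).
#' @return A finite scalar for valid states.
#' @export
log_joint <- function(state, gene, control = mcmc_control()) {
  if (state$sigma2_eps <= 0 || state$sigma2_phi <= 0) {
    stop("variances must be positive", call. = FALSE)
  }
  K <- attr(gene, "K")
  sb <- sqrt(control$sigma2_beta)
  eta <- linear_predictor(state, gene)
  lp <- sum(dnorm(gene$y, eta, sqrt(state$sigma2_eps), log = TRUE)) +
    sum(dnorm(state$phi, 0, sqrt(state$sigma2_phi), log = TRUE)) +
    sum(dbinom(state$alpha[-1], 1, state$p, log = TRUE)) +
    sum(dbinom(state$gamma[-1], 1, state$q, log = TRUE)) +
    sum(dbeta(state$p, 1, 1, log = TRUE)) +
    sum(dbeta(state$q, 1, 1, log = TRUE)) +
    dnorm(state$mu, 0, sb, log = TRUE) +
    dnorm(state$beta1, 0, sb, log = TRUE) +
    dnorm(state$beta2, 0, sb, log = TRUE) +
    dinvgamma_log(state$sigma2_phi, control$ig_a, control$ig_b) +
    dinvgamma_log(state$sigma2_eps, control$ig_a, control$ig_b)
  if (length(state$covar_coef)) {
    lp <- lp + sum(dnorm(state$covar_coef, 0, sb, log = TRUE))
  }
  lp
}

dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

chain_init <- function(gene, chain, control) {
  K <- attr(gene, "K"); M <- attr(gene, "M")
  vy <- if (nrow(gene) >= 2) var(gene$y) else 1
  if (!is.finite(vy) || vy <= 0) vy <- 1
  list(mu = rnorm(1) * (1 + chain),
       beta1 = rnorm(1) * (1 + chain),
       beta2 = rnorm(1) * (1 + chain),
       covar_coef = rep(0, length(attr(gene, "covariate_names"))),
       phi = rep(0, M),
       sigma2_phi = vy, sigma2_eps = vy,
       alpha = rep(0L, K), gamma = rep(0L, K))
}

run_one_chain <- function(gene, control, init,
                          clamp_alpha = -1L, clamp_gamma = -1L,
                          clamp_beta = FALSE, include_phi = TRUE,
                          include_mu = TRUE, fix_sigma2_eps = -1) {
  cn <- attr(gene, "covariate_names")
  X <- if (length(cn)) as.matrix(gene[, cn, drop = FALSE])
       else matrix(0, nrow(gene), 0)
  .gibbs_cpp(y = gene$y,
             fam = gene$family - 1L,
             M = attr(gene, "M"),
             X = X,
             r = gene$r, s = gene$s,
             Dr = gene$D_r, Ds = gene$D_s,
             GEr = gene$GE_r, GEs = gene$GE_s,
             K = attr(gene, "K"),
             iterations = control$iterations,
             burn_in = control$burn_in,
             thin = control$thin,
             sigma2_beta = control$sigma2_beta,
             ig_a = control$ig_a, ig_b = control$ig_b,
             init = init,
             clamp_alpha = as.integer(clamp_alpha),
             clamp_gamma = as.integer(clamp_gamma),
             clamp_beta = clamp_beta,
             include_phi = include_phi,
             include_mu = include_mu,
             fix_sigma2_eps = fix_sigma2_eps)
}

#' Fit the collapsed family model by Gibbs sampling
#'
#' Runs one or more chains of an exact conjugate Gibbs sampler over the
#' hierarchical model: Gaussian phenotype with a global intercept, optional
#' covariates, within-family effect `beta1` modulated by per-locus spike
#' indicators `alpha_k ~ Bern(p_k)`, between-family effect `beta2` modulated
#' by `gamma_k ~ Bern(q_k)`, a Gaussian family effect, and Inverse-Gamma
#' variance priors.  Chains start from dispersed initial values with
#' distinct sub-seeds, burn-in is discarded, and the Gelman-Rubin statistic
#' and lag-1 autocorrelation are reported for every continuous parameter
#' when two or more chains are run.
#'
#' @param gene A [collapse_gene()] result with at least one rare locus.
#' @param control An [mcmc_control()].
#' @param seed Integer seed; the fit is bit-reproducible given the seed.
#' @param clamp_alpha,clamp_gamma `-1` (free, default), `0` or `1` to clamp
#'   all indicators of that family at a value (used for sampler validation).
#' @param clamp_beta If `TRUE`, `beta1` and `beta2` are fixed at zero (the
#'   null pilot model used to estimate the residual scale).
#' @param include_phi,include_mu Include the family effect / the intercept.
#' @param fix_sigma2_eps If positive, the residual variance is fixed at this
#'   value instead of being sampled.
#' @param allow_uninformative If `TRUE`, fit even when no offspring carries a
#'   nonzero deviation (prior sampling; used for sampler validation).
#' @return An object of class `fbcm_fit`: a list with `draws` (a tibble of
#'   post-burn-in draws: `chain`, `iteration`, `mu`, `beta1`, `beta2`,
#'   `sigma2_phi`, `sigma2_eps`, covariate coefficients, and one 0/1 column
#'   per locus indicator `alpha_k` / `gamma_k`), `diagnostics` (per-parameter
#'   R-hat and lag-1 autocorrelation), and the call settings.
#' @export
fbcm_fit <- function(gene, control = mcmc_control(), seed = NULL,
                     clamp_alpha = -1L, clamp_gamma = -1L,
                     clamp_beta = FALSE, include_phi = TRUE,
                     include_mu = TRUE, fix_sigma2_eps = -1,
                     allow_uninformative = FALSE) {
  K <- attr(gene, "K")
  if (is.null(K)) stop("`gene` must be a collapse_gene() result", call. = FALSE)
  if (K < 1) stop("gene has no rare variants", call. = FALSE)
  if (!allow_uninformative && (nrow(gene) == 0L || n_informative(gene) == 0L)) {
    stop(errorCondition(
      "gene carries no information (no offspring with nonzero deviation)",
      class = c("fbcm_skip", "error", "condition")))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, control$chains)

  cn <- attr(gene, "covariate_names")
  cont_names <- c("mu", "beta1", "beta2", "sigma2_phi", "sigma2_eps", cn)
  vids <- attr(gene, "variants")$variant_id

  per_chain <- purrr::map(seq_len(control$chains), function(ch) {
    set.seed(chain_seeds[ch])
    init <- chain_init(gene, ch, control)
    raw <- run_one_chain(gene, control, init,
                         clamp_alpha, clamp_gamma, clamp_beta,
                         include_phi, include_mu, fix_sigma2_eps)
    cont <- raw$cont
    colnames(cont) <- cont_names
    alpha <- raw$alpha; colnames(alpha) <- paste0("alpha_", seq_len(K))
    gamma <- raw$gamma; colnames(gamma) <- paste0("gamma_", seq_len(K))
    dplyr::bind_cols(
      tibble::tibble(chain = ch, iteration = seq_len(nrow(cont))),
      tibble::as_tibble(cont),
      tibble::as_tibble(alpha),
      tibble::as_tibble(gamma)
    )
  })
  draws <- dplyr::bind_rows(per_chain)

  diagnostics <- tibble::tibble(
    parameter = cont_names,
    rhat = if (control$chains >= 2) {
      vapply(cont_names, function(p) {
        x <- draws[[p]]
        if (any(!is.finite(x))) return(NA_real_)
        gelman_rubin(split(x, draws$chain))
      }, numeric(1))
    } else NA_real_,
    acf1 = vapply(cont_names, function(p) {
      x <- draws[[p]][draws$chain == 1]
      s <- sd(x)
      if (!is.finite(s) || s == 0) return(NA_real_)
      acf(x, lag.max = 1, plot = FALSE)$acf[2]
    }, numeric(1))
  )

  structure(list(draws = draws,
                 diagnostics = diagnostics,
                 variant_ids = vids,
                 K = K,
                 control = control,
                 seed = seed,
                 clamped = clamp_beta),
            class = "fbcm_fit")
}

#' @exportS3Method base::print
print.fbcm_fit <- function(x, ...) {
  cat("Collapsed family model fit: ", x$K, " loci, ",
      max(x$draws$chain), " chain(s), ", nrow(x$draws), " kept draws\n",
      sep = "")
  cat("Posterior means: beta1 = ", signif(mean(x$draws$beta1), 4),
      ", beta2 = ", signif(mean(x$draws$beta2), 4),
      ", sigma2_eps = ", signif(mean(x$draws$sigma2_eps), 4), "\n", sep = "")
  if (!all(is.na(x$diagnostics$rhat))) {
    cat("Max R-hat (continuous parameters): ",
        signif(max(x$diagnostics$rhat), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free R-hat: with `m` chains of length `n`, the
#' between-chain variance `B` and mean within-chain variance `W` combine as
#' `sqrt(((n-1)/n * W + B/n) / W)`.  Values near 1 indicate that the chains
#' have mixed.
#'
#' @param chains List of numeric vectors of equal length (one per chain).
#' @return The potential scale reduction factor (>= 1 up to floating point,
#'   modulo the finite-sample (n-1)/n shrinkage).
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains",
                  call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  if (n < 10) stop("chains too short for a meaningful diagnostic",
                   call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Residual scale under the null pilot model
#'
#' Fits the model with both genetic effects clamped at zero (intercept,
#' covariates and family effect only) and returns the posterior mean of the
#' residual standard deviation `sigma_eps`.  The composite-hypothesis
#' threshold is set to `0.2 * sigma_eps_hat` downstream.
#'
#' @inheritParams fbcm_fit
#' @return Positive scalar `sigma_eps_hat`.
#' @export
estimate_sigma_eps_null <- function(gene, control = mcmc_control(), seed = NULL) {
  if (attr(gene, "M") < 2) stop("need at least 2 families", call. = FALSE)
  fit <- fbcm_fit(gene, control, seed = seed, clamp_beta = TRUE)
  est <- mean(sqrt(fit$draws$sigma2_eps))
  if (est < 1e-8) {
    warning("near-zero residual scale; phenotype may be constant",
            call. = FALSE)
  }
  est
}
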