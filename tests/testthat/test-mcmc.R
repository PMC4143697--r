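test_that("linear predictor follows the collapsed model formula", {
  gene <- tiny_gene(M = 3, n = 2, K = 3, seed = 5)
  K <- attr(gene, "K"); M <- attr(gene, "M")
  zero <- list(mu = 0, beta1 = 2, beta2 = 3,
               alpha = rep(0, K + 1), gamma = rep(0, K + 1),
               phi = rep(0, M), covar_coef = numeric(0))
  expect_equal(linear_predictor(zero, gene), rep(0, nrow(gene)))

  # pseudolocus offspring get mu + phi only, whatever beta is
  st <- list(mu = 1.5, beta1 = 100, beta2 = -50,
             alpha = rep(1, K + 1), gamma = rep(1, K + 1),
             phi = seq_len(M) / 10)
  eta <- linear_predictor(st, gene)
  off0 <- gene$r == 0 & gene$s == 0
  if (any(off0)) {
    expect_equal(eta[off0], 1.5 + st$phi[gene$family[off0]])
  }

  # single offspring, single active locus: direct product
  v <- tibble::tibble(variant_id = c("a", "b"), pos = 1:2,
                      maf = c(0.005, 0.004))
  g1 <- collapse_gene(G = rbind(c(0, 1)), GM = rbind(c(0, 1)),
                      GF = rbind(c(0, 0)), family = 1L, y = 0, v)
  expect_equal(g1$r, 2L)
  expect_equal(g1$D_r, 0.5)
  st1 <- list(mu = 0, beta1 = 1.5, beta2 = 0,
              alpha = c(0, 0, 1), gamma = rep(0, 3), phi = 0)
  expect_equal(linear_predictor(st1, g1), 0.75)
})

test_that("log joint matches an independent term-by-term oracle", {
  # oracle writes every density by hand, looping over terms
  oracle <- function(state, gene, control) {
    ldnorm <- function(x, m, s2) -0.5 * log(2 * pi * s2) - (x - m)^2 / (2 * s2)
    K <- attr(gene, "K")
    a <- state$alpha; g <- state$gamma
    total <- 0
    for (j in seq_len(nrow(gene))) {
      eta <- state$mu + state$phi[gene$family[j]]
      if (gene$r[j] > 0) {
        eta <- eta + state$beta1 * a[gene$r[j] + 1] * gene$D_r[j] +
          state$beta2 * g[gene$r[j] + 1] * gene$GE_r[j]
      }
      if (gene$s[j] > 0) {
        eta <- eta + state$beta1 * a[gene$s[j] + 1] * gene$D_s[j] +
          state$beta2 * g[gene$s[j] + 1] * gene$GE_s[j]
      }
      cn <- attr(gene, "covariate_names")
      for (l in seq_along(cn)) {
        eta <- eta + state$covar_coef[l] * gene[[cn[l]]][j]
      }
      total <- total + ldnorm(gene$y[j], eta, state$sigma2_eps)
    }
    for (i in seq_along(state$phi)) {
      total <- total + ldnorm(state$phi[i], 0, state$sigma2_phi)
    }
    for (k in seq_len(K)) {
      total <- total +
        log(ifelse(state$alpha[k + 1] == 1, state$p[k], 1 - state$p[k])) +
        log(ifelse(state$gamma[k + 1] == 1, state$q[k], 1 - state$q[k]))
      # Beta(1,1) log-densities are zero
    }
    s2b <- control$sigma2_beta
    total <- total + ldnorm(state$mu, 0, s2b) +
      ldnorm(state$beta1, 0, s2b) + ldnorm(state$beta2, 0, s2b)
    for (cc in state$covar_coef) total <- total + ldnorm(cc, 0, s2b)
    ig <- function(x, a0, b0) {
      a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(x) - b0 / x
    }
    total + ig(state$sigma2_phi, control$ig_a, control$ig_b) +
      ig(state$sigma2_eps, control$ig_a, control$ig_b)
  }

  ctrl <- mcmc_control(iterations = 100)
  gene <- tiny_gene(M = 4, n = 2, K = 3, seed = 2,
                    covariates = cbind(age = rnorm(8)))
  set.seed(99)
  for (i in 1:100) {
    K <- attr(gene, "K"); M <- attr(gene, "M")
    st <- list(mu = rnorm(1), beta1 = rnorm(1), beta2 = rnorm(1),
               alpha = c(0, rbinom(K, 1, 0.5)),
               gamma = c(0, rbinom(K, 1, 0.5)),
               p = runif(K), q = runif(K),
               phi = rnorm(M), covar_coef = rnorm(1),
               sigma2_phi = rexp(1) + 0.1, sigma2_eps = rexp(1) + 0.1)
    expect_equal(log_joint(st, gene, ctrl), oracle(st, gene, ctrl),
                 tolerance = 1e-8)
  }
})

test_that("log joint decreases as the residual grows and guards variances", {
  gene <- tiny_gene(M = 3, n = 2, K = 2, seed = 3)
  K <- attr(gene, "K"); M <- attr(gene, "M")
  base <- list(mu = 0, beta1 = 0, beta2 = 0,
               alpha = rep(0, K + 1), gamma = rep(0, K + 1),
               p = rep(0.5, K), q = rep(0.5, K),
               phi = rep(0, M), covar_coef = numeric(0),
               sigma2_phi = 1, sigma2_eps = 1)
  lj <- vapply(c(0, 1, 2, 5), function(shift) {
    st <- base; st$mu <- mean(gene$y) + shift
    log_joint(st, gene)
  }, numeric(1))
  expect_true(all(diff(lj) < 0))
  bad <- base; bad$sigma2_eps <- -1
  expect_error(log_joint(bad, gene), "positive")
})

test_that("chains are bit-reproducible given the seed", {
  gene <- tiny_gene(M = 10, n = 2, K = 3, seed = 8)
  ctrl <- mcmc_control(iterations = 200, chains = 2)
  f1 <- fbcm_fit(gene, ctrl, seed = 77)
  f2 <- fbcm_fit(gene, ctrl, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- fbcm_fit(gene, ctrl, seed = 78)
  expect_false(identical(f1$draws$beta1, f3$draws$beta1))
})

test_that("clamped-indicator beta1 posterior matches the conjugate closed form", {
  # all alpha = 1, gamma = 0, no intercept/family effect, known variance:
  # beta1 | y ~ N(v * sum(w y) / s2, v), v = 1 / (sum(w^2)/s2 + 1/s2b)
  set.seed(31)
  cfg <- sim_config(n_families = 60, n_variants = 5, maf = 0.05,
                    beta1 = 1, beta2 = 0, prop_causal = 1,
                    prop_stratified = 0, sigma = diag(2))
  sim <- simulate_gene(cfg, seed = 31)
  gene <- collapse_sim(sim)
  s2 <- 1; s2b <- 1e4
  w <- gene$D_r + gene$D_s
  v <- 1 / (sum(w^2) / s2 + 1 / s2b)
  post_mean <- v * sum(w * gene$y) / s2
  post_sd <- sqrt(v)

  fit <- fbcm_fit(gene,
                  mcmc_control(iterations = 4000, chains = 1,
                               sigma2_beta = s2b),
                  seed = 5, clamp_alpha = 1L, clamp_gamma = 0L,
                  include_phi = FALSE, include_mu = FALSE,
                  fix_sigma2_eps = s2)
  d <- fit$draws$beta1
  mcse <- sd(d) / sqrt(ess_ar1(d))
  expect_lt(abs(mean(d) - post_mean), 3 * mcse)
  expect_lt(abs(sd(d) / post_sd - 1), 0.1)
})

test_that("with no data the sampler reproduces the priors", {
  gene <- empty_gene(K = 2)
  fit <- fbcm_fit(gene, mcmc_control(iterations = 4000, burn_in = 100,
                                     chains = 1),
                  seed = 13, allow_uninformative = TRUE)
  # beta1 draws are iid N(0, sigma_beta^2)
  ks <- stats::ks.test(fit$draws$beta1, "pnorm", 0, 100)
  expect_gt(ks$p.value, 0.01)
  # indicators are marginally Bernoulli(1/2); thin to break the
  # alpha -> p -> alpha autocorrelation
  a <- fit$draws$alpha_1[seq(1, nrow(fit$draws), by = 10)]
  bt <- binom.test(sum(a), length(a), 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("p_k full conditional follows Beta-Bernoulli conjugacy", {
  # with alpha clamped the p draws are iid Beta(1 + alpha, 2 - alpha);
  # check both clamp values through the sampler's own alpha draws: under
  # no data, E[p | alpha = 1] = 2/3 and E[p | alpha = 0] = 1/3, so the
  # stationary chain alternates with lag-1 autocorrelation 1/3
  gene <- empty_gene(K = 1)
  fit <- fbcm_fit(gene, mcmc_control(iterations = 20000, burn_in = 1000,
                                     chains = 1),
                  seed = 3, allow_uninformative = TRUE)
  a <- fit$draws$alpha_1
  # transition P(a' = 1 | a = 1) = E[Beta(2,1)] = 2/3
  p11 <- mean(a[-1][a[-length(a)] == 1])
  p01 <- mean(a[-1][a[-length(a)] == 0])
  expect_lt(abs(p11 - 2 / 3), 0.03)
  expect_lt(abs(p01 - 1 / 3), 0.03)
})

test_that("Gelman-Rubin statistic matches the textbook formula", {
  x <- rnorm(1000)
  n <- length(x)
  expect_equal(gelman_rubin(list(x, x)), sqrt((n - 1) / n), tolerance = 1e-6)

  set.seed(4)
  far <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(far), 2)

  # independent implementation on random inputs
  oracle <- function(chains) {
    m <- length(chains); n <- length(chains[[1]])
    cm <- sapply(chains, mean)
    W <- mean(sapply(chains, var))
    B <- n / (m - 1) * sum((cm - mean(cm))^2)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  for (i in 1:20) {
    chains <- replicate(sample(2:4, 1),
                        rnorm(50, mean = rnorm(1)), simplify = FALSE)
    expect_equal(gelman_rubin(chains), oracle(chains), tolerance = 1e-10)
  }
  expect_error(gelman_rubin(list(rnorm(50))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(50), rnorm(49))), "equal length")
})

test_that("chains converge on a well-specified simulated gene", {
  sim <- simulate_gene(sim_config(n_families = 150, beta1 = 1,
                                  prop_causal = 1), seed = 21)
  gene <- collapse_sim(sim)
  fit <- fbcm_fit(gene, mcmc_control(iterations = 4000, chains = 2), seed = 9)
  expect_true(all(fit$diagnostics$rhat < 1.1))
})

test_that("null pilot recovers the residual scale of exchangeable sib noise", {
  # y ~ N(0, [[2,1],[1,2]]) decomposes into family variance 1 + residual 1
  cfg <- sim_config(n_families = 300, beta1 = 0, beta2 = 0,
                    prop_stratified = 0)
  sim <- simulate_gene(cfg, seed = 17)
  gene <- collapse_sim(sim)
  ctrl <- mcmc_control(iterations = 2000, chains = 1)
  se <- estimate_sigma_eps_null(gene, ctrl, seed = 2)
  expect_lt(abs(se - 1), 0.15)

  # location invariance and scale equivariance
  gene_shift <- gene; gene_shift$y <- gene$y + 100
  se_shift <- estimate_sigma_eps_null(gene_shift, ctrl, seed = 2)
  expect_lt(abs(se_shift / se - 1), 0.05)
  gene_x2 <- gene; gene_x2$y <- gene$y * 2
  se_x2 <- estimate_sigma_eps_null(gene_x2, ctrl, seed = 2)
  expect_lt(abs(se_x2 / (2 * se) - 1), 0.05)
})

test_that("uninformative genes raise a skip condition, not a crash", {
  # no offspring deviates: both parents homozygous everywhere
  v <- tibble::tibble(variant_id = "a", pos = 1L, maf = 0.005)
  gene <- collapse_gene(G = rbind(0, 0), GM = rbind(0, 0), GF = rbind(0, 0),
                        family = c(1L, 2L), y = c(0.5, -0.5), v)
  expect_error(fbcm_fit(gene), class = "fbcm_skip")
})

test_that("tidy and glance summarise fits", {
  gene <- tiny_gene(M = 10, n = 2, K = 2, seed = 14)
  fit <- fbcm_fit(gene, mcmc_control(iterations = 400, chains = 2), seed = 3)
  td <- tidy(fit)
  expect_true(all(c("parameter", "estimate", "conf_low", "conf_high")
                  %in% names(td)))
  # central quantile intervals bracket the mean for continuous parameters
  # (binary indicator means can fall outside their degenerate quantiles)
  cont <- td[td$parameter %in% c("mu", "beta1", "beta2", "sigma2_phi",
                                 "sigma2_eps"), ]
  expect_true(all(cont$conf_low <= cont$estimate &
                    cont$estimate <= cont$conf_high))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_chains, 2L)
  expect_identical(gl$n_draws, 400L)
})
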