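# Small hand-built collapsed genes and fake fit objects used across tests.

# A tiny deterministic gene: M families x n sibs, K loci, genotypes drawn by
# Mendelian transmission from Bern(2 maf) parents; phenotype optional.
tiny_gene <- function(M = 4, n = 2, K = 3, maf = 0.2, seed = 1,
                      y = NULL, covariates = NULL) {
  set.seed(seed)
  GM <- matrix(rbinom(M * K, 1, 2 * maf), M, K)
  GF <- matrix(rbinom(M * K, 1, 2 * maf), M, K)
  G <- do.call(rbind, lapply(seq_len(M), function(i) {
    transmit(GM[i, ], GF[i, ], n)
  }))
  family <- rep(seq_len(M), each = n)
  if (is.null(y)) y <- rnorm(M * n)
  variants <- tibble::tibble(variant_id = paste0("v", seq_len(K)),
                             pos = seq_len(K) * 100L,
                             maf = seq(0.002, 0.009, length.out = K))
  collapse_gene(G, GM, GF, family, y, variants, covariates = covariates)
}

# A collapsed gene with zero offspring (prior-only sampling).
empty_gene <- function(K = 2) {
  variants <- tibble::tibble(variant_id = paste0("v", seq_len(K)),
                             pos = seq_len(K), maf = rep(0.005, K))
  collapse_gene(matrix(integer(0), 0, K),
                matrix(integer(0), 0, K),
                matrix(integer(0), 0, K),
                integer(0), numeric(0), variants)
}

# Fake fit carrying prescribed draws, for Bayes-factor arithmetic tests.
fake_fit <- function(beta1_draws, alpha_mat, sigma2_beta = 1e4) {
  K <- ncol(alpha_mat)
  draws <- dplyr::bind_cols(
    tibble::tibble(chain = 1L, iteration = seq_along(beta1_draws),
                   mu = 0, beta1 = beta1_draws, beta2 = 0,
                   sigma2_phi = 1, sigma2_eps = 1),
    tibble::as_tibble(`colnames<-`(alpha_mat, paste0("alpha_", seq_len(K)))),
    tibble::as_tibble(`colnames<-`(matrix(0L, nrow(alpha_mat), K),
                                   paste0("gamma_", seq_len(K))))
  )
  structure(list(draws = draws,
                 diagnostics = tibble::tibble(parameter = character(0),
                                              rhat = numeric(0),
                                              acf1 = numeric(0)),
                 variant_ids = paste0("v", seq_len(K)),
                 K = K,
                 control = mcmc_control(iterations = 100L,
                                        sigma2_beta = sigma2_beta),
                 seed = NULL, clamped = FALSE),
            class = "fbcm_fit")
}

# Effective sample size from lag-1 autocorrelation (AR(1) approximation);
# used to widen Monte-Carlo standard errors for autocorrelated chains.
ess_ar1 <- function(x) {
  r <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  r <- max(min(r, 0.99), 0)
  length(x) * (1 - r) / (1 + r)
}
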