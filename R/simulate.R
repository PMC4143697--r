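#' Simulation settings for the family study design
#'
#' Defaults reproduce the calibration design: 300 nuclear families of two
#' sibs, 50 rare diallelic loci at MAF 0.005, a stratification effect
#' `beta2 = 0.5` acting through half of the loci, and bivariate-normal
#' sibling noise with variance 2 and covariance 1 (sibling correlation 0.5).
#'
#' @param n_families Number of nuclear families M (default 300).
#' @param n_offspring Sibs per family (default 2; must match `dim(sigma)`).
#' @param n_variants Number of rare loci K (default 50).
#' @param maf Minor-allele frequency shared by all loci (default 0.005).
#' @param beta1 Within-family (transmission) effect size; 0 under the null.
#' @param beta2 Between-family stratification effect (default 0.5).
#' @param prop_causal Proportion of loci that are causal (default 0.2).
#' @param prop_stratified Proportion of loci associated only through
#'   stratification (default 0.5).
#' @param sigma Sibling noise covariance matrix (default
#'   `matrix(c(2, 1, 1, 2), 2)`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 300L, n_offspring = 2L, n_variants = 50L,
                       maf = 0.005, beta1 = 0, beta2 = 0.5,
                       prop_causal = 0.2, prop_stratified = 0.5,
                       sigma = matrix(c(2, 1, 1, 2), 2)) {
  stopifnot(n_families >= 1, n_offspring >= 1, n_variants >= 1,
            maf >= 0, 2 * maf <= 1,
            prop_causal >= 0, prop_causal <= 1,
            prop_stratified >= 0, prop_stratified <= 1)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != n_offspring || ncol(sigma) != n_offspring) {
    stop("`sigma` must be n_offspring x n_offspring", call. = FALSE)
  }
  if (any(abs(sigma - t(sigma)) > 1e-12) ||
      any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`sigma` must be symmetric positive-definite", call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families),
                 n_offspring = as.integer(n_offspring),
                 n_variants = as.integer(n_variants),
                 maf = maf, beta1 = beta1, beta2 = beta2,
                 prop_causal = prop_causal,
                 prop_stratified = prop_stratified,
                 sigma = sigma),
            class = "sim_config")
}

#' Draw parental genotypic scores
#'
#' Each parent's score at each locus is Bernoulli with success probability
#' `2 * maf` (a carrier is heterozygous; homozygous-minor parents are
#' negligible at these frequencies and are not generated).
#'
#' @param K Number of loci.
#' @param maf Per-locus minor-allele frequency (`2 * maf` must be <= 1).
#' @return List with integer vectors `GM` and `GF` of length `K`, values in
#'   `{0, 1}`.
#' @export
simulate_parents <- function(K, maf) {
  if (2 * maf > 1) stop("`maf` must be at most 0.5", call. = FALSE)
  list(GM = rbinom(K, 1, 2 * maf), GF = rbinom(K, 1, 2 * maf))
}

#' Mendelian transmission of parental scores to offspring
#'
#' Each child receives one allele from each parent independently per locus:
#' a heterozygous parent (score 1) transmits the minor allele with
#' probability 1/2, homozygous parents transmit deterministically.
#'
#' @param GM,GF Integer parental score vectors, values in `{0, 1, 2}`.
#' @param n_offspring Number of children to generate.
#' @return Integer matrix, `n_offspring` x `K`, values in `{0, 1, 2}`.
#' @export
transmit <- function(GM, GF, n_offspring) {
  check_genotype(GM, "GM")
  check_genotype(GF, "GF")
  K <- length(GM)
  stopifnot(length(GF) == K, n_offspring >= 1)
  one_parent <- function(g) {
    # allele transmitted by a parent with score g, per child x locus
    gm <- matrix(rep(g, each = n_offspring), n_offspring, K)
    draw <- matrix(rbinom(n_offspring * K, 1, 0.5), n_offspring, K)
    (gm == 2) + (gm == 1) * draw
  }
  one_parent(GM) + one_parent(GF)
}

#' Phenotypes for the sibs of one family
#'
#' Mean `beta1 * (D %*% r) + beta2 * (E %*% s)` per sib plus multivariate
#' normal noise with covariance `sigma` across sibs.
#'
#' @param D Deviation matrix, sibs x loci.
#' @param E Expected-score matrix, sibs x loci (rows identical within a
#'   family).
#' @param r_ind,s_ind 0/1 indicator vectors over loci: causal loci and
#'   stratification-associated loci.
#' @param beta1,beta2 Effect sizes.
#' @param sigma Sib noise covariance matrix.
#' @return Numeric phenotype vector, one per sib.
#' @export
simulate_phenotypes <- function(D, E, r_ind, s_ind, beta1, beta2, sigma) {
  D <- as.matrix(D); E <- as.matrix(E)
  stopifnot(ncol(D) == length(r_ind), ncol(E) == length(s_ind),
            nrow(D) == nrow(E), nrow(sigma) == nrow(D))
  ev <- eigen(as.matrix(sigma), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("`sigma` must be positive semi-definite",
                             call. = FALSE)
  mu <- beta1 * as.numeric(D %*% r_ind) + beta2 * as.numeric(E %*% s_ind)
  mu + as.numeric(MASS::mvrnorm(1, rep(0, nrow(D)), sigma))
}

draw_indicators <- function(cfg) {
  K <- cfg$n_variants
  n_causal <- round(cfg$prop_causal * K)
  n_strat <- round(cfg$prop_stratified * K)
  perm_c <- sample.int(K)
  perm_s <- sample.int(K)       # drawn unconditionally: fixed RNG consumption
  causal <- head(perm_c, n_causal)
  noncausal <- perm_s[!(perm_s %in% causal)]
  strat <- if (length(noncausal) >= n_strat) head(noncausal, n_strat)
           else head(perm_s, n_strat)  # overlap unavoidable: fall back
  r_ind <- as.integer(seq_len(K) %in% causal)
  s_ind <- as.integer(seq_len(K) %in% strat)
  list(r_ind = r_ind, s_ind = s_ind)
}

#' Simulate a full family study for one gene
#'
#' Draws causal and stratification indicator vectors, parental genotypes,
#' Mendelian transmission to the sibs, and sib phenotypes, per
#' [sim_config()].  Stratified loci are drawn from the non-causal complement
#' when it is large enough (they are neutral by construction), falling back
#' to allowing overlap otherwise.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `fbcm_sim`: matrices `GM`, `GF` (family x loci),
#'   `G` (offspring x loci), `family` index, phenotype `y`, a `variants`
#'   tibble (ids, positions, the design MAF), and the `truth` (indicator
#'   vectors and effects).
#' @export
simulate_gene <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  M <- config$n_families; n <- config$n_offspring; K <- config$n_variants
  ind <- draw_indicators(config)

  GM <- matrix(0L, M, K); GF <- matrix(0L, M, K)
  G <- matrix(0L, M * n, K)
  y <- numeric(M * n)
  family <- rep(seq_len(M), each = n)
  for (i in seq_len(M)) {
    par <- simulate_parents(K, config$maf)
    GM[i, ] <- par$GM; GF[i, ] <- par$GF
    rows <- ((i - 1) * n + 1):(i * n)
    Gi <- transmit(par$GM, par$GF, n)
    G[rows, ] <- Gi
    Ei <- matrix(rep((par$GM + par$GF) / 2, each = n), n, K)
    y[rows] <- simulate_phenotypes(Gi - Ei, Ei, ind$r_ind, ind$s_ind,
                                   config$beta1, config$beta2, config$sigma)
  }
  variants <- tibble::tibble(
    variant_id = sprintf("rv%03d", seq_len(K)),
    chrom = "1",
    pos = 1000L * seq_len(K),
    maf = rep(config$maf, K)
  )
  structure(list(GM = GM, GF = GF, G = G, family = family, y = y,
                 variants = variants,
                 truth = list(r_ind = ind$r_ind, s_ind = ind$s_ind,
                              beta1 = config$beta1, beta2 = config$beta2),
                 config = config),
            class = "fbcm_sim")
}

#' Collapse a simulated study
#'
#' Convenience wrapper: runs [collapse_gene()] on a [simulate_gene()]
#' result.
#'
#' @param sim An `fbcm_sim` object.
#' @return A `collapsed_gene` tibble.
#' @export
collapse_sim <- function(sim) {
  collapse_gene(sim$G, sim$GM, sim$GF, sim$family, sim$y, sim$variants)
}

#' Type-I-error / power experiment
#'
#' Repeats the full pipeline — simulate a gene, collapse, pilot estimate of
#' the residual scale, Gibbs fit, hybrid Bayes factor — and reports the
#' fraction of replicates whose gene BF exceeds the cutoff, with an exact
#' binomial confidence interval.  With `beta1 = 0` in `config` this is a
#' type-I-error experiment; with `beta1 > 0` it is a power experiment.
#' A master seed spawns per-replicate sub-seeds so replicates are
#' independent and individually re-runnable; sharing a master seed across
#' configurations yields paired comparisons.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates.
#' @param control An [mcmc_control()] used for the main fit.
#' @param pilot_control Control for the residual-scale pilot run (smaller by
#'   default).
#' @param bf_cutoff Rejection threshold on the gene BF (default 2).
#' @param seed Master seed.
#' @return A tibble of class `fbcm_experiment` with one row per replicate
#'   (`rep`, `bf`, `effect_size`, `reject`, `status`); the rejection rate,
#'   its 95% binomial confidence interval, failure count and settings are
#'   attached as attributes (see [glance.fbcm_experiment()]).
#' @export
run_experiment <- function(config = sim_config(), n_reps = 100L,
                           control = mcmc_control(iterations = 5000L,
                                                  chains = 2L),
                           pilot_control = mcmc_control(iterations = 2000L,
                                                        chains = 1L),
                           bf_cutoff = 2, seed = NULL) {
  stopifnot(n_reps >= 1)
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  rows <- purrr::map(seq_len(n_reps), function(rep) {
    res <- tryCatch({
      sim <- simulate_gene(config, seed = rep_seeds[rep])
      gene <- collapse_sim(sim)
      se <- estimate_sigma_eps_null(gene, pilot_control,
                                    seed = rep_seeds[rep] %% 1000003L + 1L)
      fit <- fbcm_fit(gene, control, seed = rep_seeds[rep] %% 999983L + 1L)
      res <- fbcm_bf(fit, sigma_eps_hat = se)
      tibble::tibble(rep = rep, bf = res$gene_bf,
                     effect_size = res$effect_size,
                     reject = res$gene_bf > bf_cutoff, status = "ok")
    }, fbcm_skip = function(e) {
      tibble::tibble(rep = rep, bf = NA_real_, effect_size = NA_real_,
                     reject = FALSE, status = "skipped_no_information")
    }, error = function(e) {
      tibble::tibble(rep = rep, bf = NA_real_, effect_size = NA_real_,
                     reject = NA, status = paste0("failed: ",
                                                  conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  n_ok <- sum(out$status == "ok")
  n_rej <- sum(out$reject[out$status == "ok"])
  ci <- if (n_ok > 0) as.numeric(binom.test(n_rej, n_ok)$conf.int)
        else c(NA_real_, NA_real_)
  attr(out, "summary") <- list(
    n_reps = n_reps, n_ok = n_ok, n_failed = sum(grepl("^failed", out$status)),
    n_reject = n_rej,
    rate = if (n_ok > 0) n_rej / n_ok else NA_real_,
    conf_low = ci[1], conf_high = ci[2],
    bf_cutoff = bf_cutoff, beta1 = config$beta1,
    prop_causal = config$prop_causal
  )
  class(out) <- c("fbcm_experiment", class(out))
  out
}

#' @rdname run_experiment
#' @param x An `fbcm_experiment`.
#' @param ... Unused.
#' @export
glance.fbcm_experiment <- function(x, ...) {
  tibble::as_tibble(attr(x, "summary"))
}

#' @exportS3Method base::print
print.fbcm_experiment <- function(x, ...) {
  s <- attr(x, "summary")
  cat("Simulation experiment: ", s$n_reps, " replicates (",
      s$n_ok, " ok, ", s$n_failed, " failed)\n", sep = "")
  cat("  beta1 = ", s$beta1, ", prop_causal = ", s$prop_causal,
      ", BF cutoff = ", s$bf_cutoff, "\n", sep = "")
  cat("  rejection rate = ", signif(s$rate, 4), "  [95% CI ",
      signif(s$conf_low, 4), ", ", signif(s$conf_high, 4), "]\n", sep = "")
  invisible(x)
}

#' Power over a grid of effect sizes and causal proportions
#'
#' Runs [run_experiment()] at every combination of `beta1` and
#' `prop_causal`, reusing the same master seed in every cell so that
#' comparisons across cells are paired (same families, same noise; only the
#' effect differs).
#'
#' @param beta1 Vector of within-family effect sizes.
#' @param prop_causal Vector of causal proportions.
#' @param config Base [sim_config()]; `beta1`/`prop_causal` are overridden
#'   cell by cell.
#' @inheritParams run_experiment
#' @return A tibble of class `fbcm_power`: one row per cell with the
#'   rejection rate and confidence bounds.
#' @export
power_grid <- function(beta1 = c(1, 1.5), prop_causal = c(0.2, 0.6, 1),
                       config = sim_config(), n_reps = 50L,
                       control = mcmc_control(iterations = 5000L,
                                              chains = 2L),
                       pilot_control = mcmc_control(iterations = 2000L,
                                                    chains = 1L),
                       bf_cutoff = 2, seed = NULL) {
  grid <- tidyr::expand_grid(beta1 = beta1, prop_causal = prop_causal)
  out <- purrr::pmap(grid, function(beta1, prop_causal) {
    cfg <- config
    cfg$beta1 <- beta1
    cfg$prop_causal <- prop_causal
    exp <- run_experiment(cfg, n_reps = n_reps, control = control,
                          pilot_control = pilot_control,
                          bf_cutoff = bf_cutoff, seed = seed)
    dplyr::mutate(glance(exp), beta1 = beta1, prop_causal = prop_causal,
                  .before = 1)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("fbcm_power", class(out))
  out
}
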