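#' Gene-by-gene association scan
#'
#' For every gene interval: select the variants inside it (0-based
#' half-open, so a 1-based variant position `pos` belongs to a gene when
#' `start < pos <= end`; a variant inside two overlapping genes enters
#' both), keep rare polymorphic variants, build the collapsed per-offspring
#' dataset, estimate the residual scale from a null pilot fit, run the
#' Gibbs sampler, and compute gene and variant Bayes factors.  Genes with
#' no qualifying variant, or no offspring with a nonzero deviation, are
#' reported as skipped; per-gene failures are recorded in `status` and the
#' scan continues.
#'
#' @param study An [load_study()] result.
#' @param control [mcmc_control()] for the main fits.
#' @param pilot_control [mcmc_control()] for the residual-scale pilot runs.
#' @param maf_threshold Rare-variant MAF bound (default 0.01).
#' @param bf_cutoff Reported for convenience in the attributes; no gene is
#'   dropped by it.
#' @param covariate_cols Names of numeric columns of `study$phen` to use as
#'   covariates (default: every numeric column except `phenotype`).
#' @param seed Master seed; per-gene sub-seeds are derived from it.
#' @return A tibble of class `fbcm_scan`, one row per gene, sorted by
#'   descending Bayes factor: `gene_id`, `chrom`, `start`, `end`,
#'   `n_variants`, `n_offspring`, `bf`, `effect_size`, `rhat_max`,
#'   `status`.  Per-variant marginal BFs for fitted genes are attached as
#'   the `variant_results` attribute.
#' @export
scan_genes <- function(study, control = mcmc_control(),
                       pilot_control = mcmc_control(iterations = 2000L,
                                                    chains = 1L),
                       maf_threshold = 0.01, bf_cutoff = 2,
                       covariate_cols = NULL, seed = NULL) {
  stopifnot(inherits(study, "fbcm_study"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_genes <- nrow(study$genes)
  gene_seeds <- if (n_genes > 0) {
    matrix(sample.int(.Machine$integer.max - 1L, 2L * max(n_genes, 1L)),
           ncol = 2L)
  } else matrix(integer(0), ncol = 2L)

  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(
      names(study$phen)[vapply(study$phen, is.numeric, logical(1))],
      "phenotype")
  }

  offspring <- study$offspring
  fam_ids <- unique(offspring$family_id)
  variant_rows <- list()

  rows <- purrr::map(seq_len(n_genes), function(g) {
    gi <- study$genes[g, ]
    base <- tibble::tibble(gene_id = gi$gene_id, chrom = gi$chrom,
                           start = gi$start, end = gi$end,
                           n_variants = 0L, n_offspring = 0L,
                           bf = NA_real_, effect_size = NA_real_,
                           rhat_max = NA_real_, status = "ok")
    vars <- dplyr::filter(study$variants,
                          .data$chrom == gi$chrom,
                          .data$pos > gi$start, .data$pos <= gi$end)
    vars <- filter_rare(vars, maf_threshold)
    base$n_variants <- nrow(vars)
    if (nrow(vars) == 0L) {
      base$status <- "skipped_no_variants"
      return(base)
    }

    built <- build_gene_data(study, offspring, vars, covariate_cols)
    base$n_offspring <- nrow(built$gene)
    result <- tryCatch({
      se <- estimate_sigma_eps_null(built$gene, pilot_control,
                                    seed = gene_seeds[g, 1])
      fit <- fbcm_fit(built$gene, control, seed = gene_seeds[g, 2])
      bf <- fbcm_bf(fit, sigma_eps_hat = se)
      base$bf <- bf$gene_bf
      base$effect_size <- bf$effect_size
      base$rhat_max <- if (all(is.na(fit$diagnostics$rhat))) NA_real_
                       else max(fit$diagnostics$rhat)
      variant_rows[[length(variant_rows) + 1L]] <<- dplyr::mutate(
        dplyr::left_join(bf$variant_bfs,
                         vars[, c("variant_id", "pos", "maf")],
                         by = "variant_id"),
        gene_id = gi$gene_id, .before = 1)
      base
    }, fbcm_skip = function(e) {
      base$status <- "skipped_no_information"
      base
    }, error = function(e) {
      base$status <- paste0("failed: ", conditionMessage(e))
      base
    })
    result
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          n_variants = integer(0), n_offspring = integer(0),
                          bf = numeric(0), effect_size = numeric(0),
                          rhat_max = numeric(0), status = character(0))
  }
  out <- dplyr::arrange(out, dplyr::desc(!is.na(.data$bf)),
                        dplyr::desc(.data$bf))
  attr(out, "variant_results") <- dplyr::bind_rows(variant_rows)
  attr(out, "bf_cutoff") <- bf_cutoff
  class(out) <- c("fbcm_scan", class(out))
  out
}

# Assemble matrices for one gene: GM/GF per family, G/y/covariates per
# offspring, keeping only offspring with complete genotypes at the gene's
# loci (and genotyped parents); families enter in first-appearance order.
build_gene_data <- function(study, offspring, vars, covariate_cols) {
  sc <- study$scores[, vars$variant_id, drop = FALSE]
  child_ok <- complete.cases(sc[offspring$individual_id, , drop = FALSE]) &
    complete.cases(sc[offspring$father_id, , drop = FALSE]) &
    complete.cases(sc[offspring$mother_id, , drop = FALSE])
  off <- offspring[child_ok, ]
  fam_ids <- unique(off$family_id)
  fam_index <- match(off$family_id, fam_ids)
  # parents are shared within a family; take them from the first child
  first <- off[!duplicated(off$family_id), ]
  GM <- sc[first$mother_id, , drop = FALSE]
  GF <- sc[first$father_id, , drop = FALSE]
  G <- sc[off$individual_id, , drop = FALSE]
  phen <- study$phen[match(off$individual_id, study$phen$individual_id), ]
  covar <- if (length(covariate_cols)) {
    as.matrix(phen[, covariate_cols, drop = FALSE])
  } else NULL
  gene <- collapse_gene(G, GM, GF, fam_index, phen$phenotype, vars,
                        covariates = covar, family_ids = fam_ids)
  list(gene = gene)
}

#' @exportS3Method base::print
print.fbcm_scan <- function(x, ...) {
  cat("Gene scan: ", nrow(x), " genes (",
      sum(x$status == "ok"), " fitted)\n", sep = "")
  NextMethod()
}
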