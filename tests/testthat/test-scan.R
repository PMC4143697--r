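# Build a two-gene study on disk: gene A carries a strong within-family
# signal, gene B is pure noise with respect to the same phenotype.
make_two_gene_study <- function(dir, M = 250, K = 8, seed = 303) {
  simA <- simulate_gene(sim_config(n_families = M, n_variants = K,
                                   maf = 0.005, beta1 = 1.5,
                                   prop_causal = 1), seed = seed)
  simB <- simulate_gene(sim_config(n_families = M, n_variants = K,
                                   maf = 0.005, beta1 = 0, beta2 = 0,
                                   prop_stratified = 0), seed = seed + 1)
  merged <- simA
  merged$GM <- cbind(simA$GM, simB$GM)
  merged$GF <- cbind(simA$GF, simB$GF)
  merged$G <- cbind(simA$G, simB$G)
  merged$variants <- dplyr::bind_rows(
    simA$variants,
    dplyr::mutate(simB$variants,
                  variant_id = paste0("b_", .data$variant_id),
                  chrom = "2"))
  write_study_files(merged, dir)
}

test_that("the scan ranks a truly associated gene first", {
  dir <- withr::local_tempdir()
  paths <- make_two_gene_study(dir)
  genes <- tibble::tibble(gene_id = c("geneA", "geneB"),
                          chrom = c("1", "2"),
                          start = c(0L, 0L), end = c(100000L, 100000L))
  study <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"], genes)
  scan <- scan_genes(study,
                     control = mcmc_control(iterations = 3000, chains = 2),
                     pilot_control = mcmc_control(iterations = 1500,
                                                  chains = 1),
                     seed = 77)
  expect_identical(nrow(scan), 2L)
  expect_identical(scan$status, c("ok", "ok"))
  expect_identical(scan$gene_id[1], "geneA")
  expect_gt(scan$bf[1], 2)
  expect_lt(scan$bf[2], 2)
  expect_gt(scan$effect_size[1], 0.5)
  vr <- attr(scan, "variant_results")
  expect_true(all(c("gene_id", "variant_id", "bf", "maf") %in% names(vr)))
  expect_true(all(vr$bf > 0))

  # scans are reproducible given the seed
  scan2 <- scan_genes(study,
                      control = mcmc_control(iterations = 3000, chains = 2),
                      pilot_control = mcmc_control(iterations = 1500,
                                                   chains = 1),
                      seed = 77)
  expect_identical(scan$bf, scan2$bf)
})

test_that("genes with only common or absent variants are skipped", {
  sim <- simulate_gene(sim_config(n_families = 30, n_variants = 4,
                                  maf = 0.3), seed = 5)  # common variants
  dir <- withr::local_tempdir()
  paths <- write_study_files(sim, dir)
  genes <- tibble::tibble(gene_id = c("common", "desert"),
                          chrom = c("1", "1"),
                          start = c(0L, 500000L), end = c(10000L, 600000L))
  study <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"], genes)
  scan <- scan_genes(study, control = mcmc_control(iterations = 200,
                                                   chains = 1),
                     pilot_control = mcmc_control(iterations = 100,
                                                  chains = 1),
                     seed = 1)
  expect_setequal(scan$status, "skipped_no_variants")
  expect_true(all(is.na(scan$bf)))
})

test_that("a variant inside two overlapping genes is analysed in both", {
  # high-MAF loci with a permissive threshold, so the interval logic is
  # exercised without MAF-estimation noise changing the variant count
  sim <- simulate_gene(sim_config(n_families = 60, n_variants = 2,
                                  maf = 0.1), seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_study_files(sim, dir)
  # variants sit at pos 1000 and 2000; both genes cover both variants
  genes <- tibble::tibble(gene_id = c("left", "right"),
                          chrom = c("1", "1"),
                          start = c(0L, 500L), end = c(2500L, 3000L))
  study <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"], genes)
  ctrl <- mcmc_control(iterations = 300, chains = 1)
  pil <- mcmc_control(iterations = 200, chains = 1)
  scan <- scan_genes(study, control = ctrl, pilot_control = pil,
                     maf_threshold = 0.45, seed = 3)
  expect_identical(sort(scan$n_variants), c(2L, 2L))
  # BED half-open semantics: a gene ending at 1000 still contains pos 1000,
  # one starting at 1000 does not
  edge <- tibble::tibble(gene_id = c("upto", "after"), chrom = "1",
                         start = c(0L, 1000L), end = c(1000L, 1500L))
  study2 <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"], edge)
  scan2 <- scan_genes(study2, control = ctrl, pilot_control = pil,
                      maf_threshold = 0.45, seed = 3)
  expect_identical(scan2$n_variants[match(c("upto", "after"),
                                          scan2$gene_id)],
                   c(1L, 0L))
})

test_that("an empty gene list yields an empty result", {
  sim <- simulate_gene(sim_config(n_families = 10, n_variants = 2,
                                  maf = 0.1), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_study_files(sim, dir)
  study <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"],
                      tibble::tibble(gene_id = character(0),
                                     chrom = character(0),
                                     start = integer(0), end = integer(0)))
  scan <- scan_genes(study, seed = 1)
  expect_identical(nrow(scan), 0L)
})

test_that("file-based and in-memory pipelines agree exactly", {
  sim <- simulate_gene(sim_config(n_families = 120, n_variants = 5,
                                  maf = 0.005, beta1 = 1, prop_causal = 1),
                       seed = 41)
  dir <- withr::local_tempdir()
  paths <- write_study_files(sim, dir)
  genes <- tibble::tibble(gene_id = "g", chrom = "1", start = 0L,
                          end = 100000L)
  study <- load_study(paths["vcf"], paths["ped"], paths["phenotypes"], genes)
  ctrl <- mcmc_control(iterations = 1000, chains = 1)
  pil <- mcmc_control(iterations = 500, chains = 1)
  set.seed(11); seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2), 1)
  scan <- scan_genes(study, control = ctrl, pilot_control = pil, seed = 11)

  # in-memory path, repeating the loader's MAF estimation and filtering
  maf_hat <- colMeans(rbind(sim$GM, sim$GF, sim$G)) / 2
  vars <- dplyr::mutate(sim$variants, maf = unname(maf_hat))
  keep <- vars$maf > 0 & vars$maf < 0.01
  gene <- collapse_gene(sim$G[, keep, drop = FALSE],
                        sim$GM[, keep, drop = FALSE],
                        sim$GF[, keep, drop = FALSE],
                        sim$family, sim$y, vars[keep, ])
  se <- estimate_sigma_eps_null(gene, pil, seed = seeds[1, 1])
  fit <- fbcm_fit(gene, ctrl, seed = seeds[1, 2])
  bf <- fbcm_bf(fit, sigma_eps_hat = se)
  expect_identical(scan$bf, bf$gene_bf)
  expect_identical(scan$effect_size, bf$effect_size)
})
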