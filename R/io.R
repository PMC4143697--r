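#' Per-individual phenotype from repeated visit measurements
#'
#' For each individual, takes the highest measurement across visits as the
#' phenotype, log-transforms it (natural log, to tame right skew), and
#' carries along the age at which that maximum was recorded as a covariate.
#' Ties on the maximum take the earliest age, so the result is
#' deterministic.  Individuals with no non-missing visit are dropped with a
#' message.
#'
#' @param visits A tibble with columns `individual_id`, `measurement`,
#'   `age` (one row per visit; a `visit` column is allowed and ignored).
#' @param log_transform Apply `log()` to the maximum (default `TRUE`).
#' @return A tibble: `individual_id`, `phenotype`, `age`.
#' @examples
#' preprocess_phenotype(tibble::tibble(
#'   individual_id = c("a", "a"), measurement = c(120, 140), age = c(40, 50)
#' ))
#' @export
preprocess_phenotype <- function(visits, log_transform = TRUE) {
  stopifnot(all(c("individual_id", "measurement", "age") %in% names(visits)))
  ok <- !is.na(visits$measurement)
  dropped <- setdiff(unique(visits$individual_id),
                     unique(visits$individual_id[ok]))
  if (length(dropped)) {
    message(length(dropped),
            " individual(s) dropped: all visit measurements missing")
  }
  visits[ok, ] |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(dplyr::desc(.data$measurement), .data$age,
                   .by_group = TRUE) |>
    dplyr::summarise(
      phenotype = if (log_transform) log(.data$measurement[1])
                  else .data$measurement[1],
      age = .data$age[1],
      .groups = "drop"
    )
}

gt_to_score <- function(gt) {
  # "0/1", "1|1", "./." ... -> minor-allele count or NA
  score <- function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  out <- vapply(gt, score, integer(1), USE.NAMES = FALSE)
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Read genotypes from a VCF
#'
#' Parses per-sample genotypes (GT) or dosages (DS) from a VCF.  Hard
#' genotypes become minor-allele counts directly; dosages are kept raw for
#' MAF estimation and rounded to the nearest integer in `{0, 1, 2}` for the
#' model scores.  Multi-allelic records are dropped with a warning (split
#' them upstream).
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return List with `scores` (integer matrix, samples x variants),
#'   `dosages` (numeric matrix used for MAF estimation) and `variants`
#'   (tibble: `variant_id`, `chrom`, `pos`).
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped", call. = FALSE)
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, ]
  }
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    scores <- t(gt_to_score(gt))              # samples x variants
    dosages <- scores
  } else if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosages <- t(ds)
    scores <- round(dosages)
    scores[scores < 0] <- 0L; scores[scores > 2] <- 2L
  } else {
    stop("VCF has neither GT nor DS in FORMAT", call. = FALSE)
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  colnames(scores) <- ids
  colnames(dosages) <- ids
  list(scores = scores, dosages = dosages,
       variants = tibble::tibble(variant_id = ids, chrom = fix$CHROM,
                                 pos = as.integer(fix$POS)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 6-column PED/FAM pedigree file
#'
#' Whitespace-delimited: family, individual, father, mother, sex, phenotype;
#' `0` means "no parent recorded".  Duplicate individual ids are an error.
#'
#' @param path Path to the PED/FAM file.
#' @return Tibble: `family_id`, `individual_id`, `father_id`, `mother_id`,
#'   `sex`, `phen` (parent ids `NA` when absent).
#' @export
read_ped <- function(path) {
  ped <- readr::read_table(path,
                           col_names = c("family_id", "individual_id",
                                         "father_id", "mother_id",
                                         "sex", "phen"),
                           col_types = "cccccc", comment = "#")
  dup <- duplicated(ped$individual_id)
  if (any(dup)) {
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(ped$individual_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  self_parent <- !is.na(ped$father_id) & ped$father_id == ped$individual_id |
    !is.na(ped$mother_id) & ped$mother_id == ped$individual_id
  if (any(self_parent)) {
    stop("pedigree cycle: individual listed as own parent", call. = FALSE)
  }
  ped
}

#' Read gene intervals from a BED file
#'
#' Standard 0-based half-open intervals; the optional 4th column names the
#' gene (unnamed genes get `chrom:start-end`).
#'
#' @param path Path to a BED file (3+ columns, no header).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         comment = "#")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  tibble::tibble(
    gene_id = if (ncol(bed) >= 4) as.character(bed[[4]])
              else paste0(bed[[1]], ":", bed[[2]], "-", bed[[3]]),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]])
  )
}

#' Assemble a family study from standard files
#'
#' Reads genotypes (VCF), pedigree (PED/FAM), phenotypes (TSV) and gene
#' intervals (BED), estimates minor-allele frequencies from all genotyped
#' individuals (flipping alleles where the coded allele is the major one),
#' and assembles nuclear families: offspring with both parents genotyped and
#' a non-missing phenotype.  Exclusions are counted, never silent.
#'
#' @param vcf Path to the VCF.
#' @param ped Path to the PED/FAM file.
#' @param phenotypes Path to a TSV, or a tibble.  Visit-level input
#'   (`individual_id`, `measurement`, `age`) is reduced by
#'   [preprocess_phenotype()]; individual-level input must have
#'   `individual_id` and `phenotype`, and any further numeric columns are
#'   used as covariates.
#' @param genes Path to a BED file, or a tibble from [read_bed()].
#' @return A list of class `fbcm_study`: genotype `scores` and `dosages`,
#'   `variants` (with estimated `maf` and `flipped`), `ped`, `phen`,
#'   `genes`, `offspring` (one row per retained child with its parents) and
#'   an `exclusions` count table.
#' @export
load_study <- function(vcf, ped, phenotypes, genes) {
  geno <- read_vcf_genotypes(vcf)
  pedt <- if (is.character(ped)) read_ped(ped) else ped
  phen <- if (is.character(phenotypes)) {
    # read as text and convert with base R, whose float parsing is
    # correctly rounded, so written studies reload bit-exactly
    raw <- readr::read_tsv(phenotypes,
                           col_types = readr::cols(.default = "c"))
    dplyr::mutate(raw, dplyr::across(
      -dplyr::any_of(c("individual_id", "visit")),
      ~ utils::type.convert(.x, as.is = TRUE)))
  } else phenotypes
  if (!"phenotype" %in% names(phen)) phen <- preprocess_phenotype(phen)
  genes <- if (is.character(genes)) read_bed(genes) else genes

  maf_tbl <- estimate_maf(geno$dosages)
  variants <- dplyr::mutate(geno$variants, maf = maf_tbl$maf,
                            flipped = maf_tbl$flipped)
  # orient scores to count the minor allele
  scores <- geno$scores
  if (any(variants$flipped)) {
    scores[, variants$flipped] <- 2L - scores[, variants$flipped]
  }

  samples <- rownames(scores)
  candidates <- dplyr::filter(pedt, !is.na(.data$father_id),
                              !is.na(.data$mother_id))
  has_geno <- candidates$individual_id %in% samples &
    candidates$father_id %in% samples & candidates$mother_id %in% samples
  has_phen <- candidates$individual_id %in%
    phen$individual_id[!is.na(phen$phenotype)]
  offspring <- candidates[has_geno & has_phen, ]
  exclusions <- tibble::tibble(
    reason = c("not_offspring", "missing_parent_genotype",
               "missing_phenotype"),
    n = c(nrow(pedt) - nrow(candidates),
          sum(!has_geno),
          sum(has_geno & !has_phen))
  )

  structure(list(scores = scores, dosages = geno$dosages,
                 variants = variants, ped = pedt, phen = phen,
                 genes = genes, offspring = offspring,
                 exclusions = exclusions),
            class = "fbcm_study")
}

#' @exportS3Method base::print
print.fbcm_study <- function(x, ...) {
  cat("Family study: ", nrow(x$offspring), " offspring in ",
      length(unique(x$offspring$family_id)), " families, ",
      nrow(x$variants), " variants, ", nrow(x$genes), " genes\n", sep = "")
  cat("Exclusions: ",
      paste(x$exclusions$reason, x$exclusions$n, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Greedy LD pruning of a variant set
#'
#' Walks the variants in genomic order and keeps each one unless its
#' squared Pearson correlation with an already-kept variant exceeds the
#' threshold.  Off by default in the scan; supplied for data sets where
#' nearby rare variants are correlated.
#'
#' @param scores Genotype score matrix, samples x variants.
#' @param variants Variant tibble aligned with the columns of `scores`.
#' @param r2_threshold Keep threshold on pairwise r-squared.
#' @return The pruned variant tibble.
#' @export
prune_ld <- function(scores, variants, r2_threshold = 0.5) {
  ord <- order(variants$chrom, variants$pos)
  kept <- integer(0)
  for (i in ord) {
    xi <- scores[, i]
    if (sd(xi, na.rm = TRUE) == 0) { kept <- c(kept, i); next }
    r2 <- if (length(kept)) {
      vapply(kept, function(j) {
        xj <- scores[, j]
        if (sd(xj, na.rm = TRUE) == 0) return(0)
        suppressWarnings(stats::cor(xi, xj, use = "complete.obs"))^2
      }, numeric(1))
    } else numeric(0)
    if (!length(r2) || all(r2 <= r2_threshold, na.rm = TRUE)) {
      kept <- c(kept, i)
    }
  }
  variants[sort(kept), ]
}

#' Write simulated families as VCF + PED + phenotype TSV
#'
#' Emits a minimal VCF 4.2 (GT field), a 6-column PED and a per-individual
#' phenotype TSV for a [simulate_gene()] result, so the full file-based
#' pipeline can be exercised end to end on synthetic data.  Parents are
#' named `F<i>_M` / `F<i>_F` and children `F<i>_C<j>`.
#'
#' @param sim An `fbcm_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File name stem (default `"study"`).
#' @return Invisibly, the three file paths.
#' @export
write_study_files <- function(sim, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- nrow(sim$GM); n <- nrow(sim$G) / M
  mothers <- sprintf("F%d_M", seq_len(M))
  fathers <- sprintf("F%d_F", seq_len(M))
  children <- sprintf("F%d_C%d", rep(seq_len(M), each = n),
                      rep(seq_len(n), M))
  samples <- c(rbind(mothers, fathers,
                     matrix(children, nrow = n, byrow = FALSE)))
  # genotype matrix in sample order: mother, father, children per family
  geno <- matrix(0L, length(samples), ncol(sim$G))
  row <- 1L
  for (i in seq_len(M)) {
    geno[row, ] <- sim$GM[i, ]; row <- row + 1L
    geno[row, ] <- sim$GF[i, ]; row <- row + 1L
    for (j in seq_len(n)) {
      geno[row, ] <- sim$G[(i - 1) * n + j, ]; row <- row + 1L
    }
  }
  gt <- c("0/0", "0/1", "1/1")[geno + 1L]
  dim(gt) <- dim(geno)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  v <- sim$variants
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(k) {
    paste(c(v$chrom[k], v$pos[k], v$variant_id[k], "A", "T", ".", "PASS",
            ".", "GT", gt[, k]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  ped <- rbind(
    data.frame(fam = sprintf("F%d", seq_len(M)), id = mothers,
               fa = "0", mo = "0", sex = 2L, phen = 0L),
    data.frame(fam = sprintf("F%d", seq_len(M)), id = fathers,
               fa = "0", mo = "0", sex = 1L, phen = 0L),
    data.frame(fam = sprintf("F%d", rep(seq_len(M), each = n)), id = children,
               fa = rep(fathers, each = n), mo = rep(mothers, each = n),
               sex = 0L, phen = 0L)
  )
  readr::write_delim(ped, ped_path, delim = " ", col_names = FALSE)

  phen_path <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  # 17 significant digits so the phenotype round-trips bit-exactly
  writeLines(c("individual_id\tphenotype",
               sprintf("%s\t%.17g", children, sim$y)), phen_path)

  invisible(c(vcf = vcf_path, ped = ped_path, phenotypes = phen_path))
}

#' Write scan results to TSV files
#'
#' Writes a gene-level table, a variant-level table, and a Manhattan-ready
#' `(chrom, start, bf)` table.  Skipped genes keep their row (with empty BF
#' fields) so nothing is silently dropped.
#'
#' @param results An `fbcm_scan` tibble from [scan_genes()].
#' @param dir Output directory (created if needed).
#' @param prefix File name stem (default `"scan"`).
#' @return Invisibly, the file paths.
#' @export
write_results <- function(results, dir, prefix = "scan") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_path <- file.path(dir, paste0(prefix, "_genes.tsv"))
  readr::write_tsv(
    results[, c("gene_id", "chrom", "start", "end", "n_variants", "bf",
                "effect_size", "rhat_max", "status")],
    gene_path)
  var_path <- file.path(dir, paste0(prefix, "_variants.tsv"))
  readr::write_tsv(attr(results, "variant_results") %||%
                     tibble::tibble(gene_id = character(0),
                                    variant_id = character(0),
                                    pos = integer(0), maf = numeric(0),
                                    bf = numeric(0)),
                   var_path)
  man_path <- file.path(dir, paste0(prefix, "_manhattan.tsv"))
  readr::write_tsv(results[results$status == "ok",
                           c("chrom", "start", "bf")], man_path)
  invisible(c(genes = gene_path, variants = var_path, manhattan = man_path))
}
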