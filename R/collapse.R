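#' Mendelian expected genotypic score
#'
#' The expected minor-allele count of an offspring given the parental
#' genotypic scores, `(GM + GF) / 2`.  Scores count minor alleles, so each
#' parent contributes half of their own count in expectation under random
#' transmission.
#'
#' @param gm,gf Integer parental scores in `{0, 1, 2}` (mother, father).
#'   Vectorised; recycled to common length.
#' @return Numeric vector of expected scores in `{0, 0.5, 1, 1.5, 2}`.
#' @examples
#' expected_score(1, 0)   # 0.5
#' expected_score(2, 2)   # 2
#' @export
expected_score <- function(gm, gf) {
  check_genotype(gm, "gm")
  check_genotype(gf, "gf")
  (gm + gf) / 2
}

#' Transmission deviation of an offspring score
#'
#' The within-family component of the genotypic score: the observed
#' minor-allele count minus its Mendelian expectation given the parents.
#' Nonzero deviation means over- or under-transmission of the minor allele
#' and is the stratification-resistant signal the model tests.
#'
#' @param g Integer offspring score in `{0, 1, 2}`.
#' @param ge Expected score from [expected_score()].
#' @return Numeric deviation in `[-1, 1]`.
#' @examples
#' deviation(1, 0.5)  # 0.5
#' @export
deviation <- function(g, ge) {
  check_genotype(g, "g")
  if (!is.numeric(ge)) stop("`ge` must be numeric", call. = FALSE)
  g - ge
}

check_genotype <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x != round(x)) ||
      any(x < 0 | x > 2)) {
    stop("invalid genotype in `", name, "`: scores must be integers in 0..2",
         call. = FALSE)
  }
  invisible(x)
}

#' Collapse indices for one offspring
#'
#' Among the loci where an offspring shows nonzero transmission deviation,
#' selects the locus with the smallest minor-allele frequency (`r`) and the
#' one with the second-smallest (`s`).  With fewer than two deviating loci
#' the unused index is 0, the pseudolocus, whose deviation and expected
#' score are identically zero.  Ties in MAF are broken by genomic position,
#' then by variant id, so the selection is deterministic.
#'
#' @param d_row Numeric vector of deviations over the gene's loci
#'   (pseudolocus excluded).
#' @param mafs Minor-allele frequencies aligned with `d_row`.
#' @param pos Optional genomic positions used to break MAF ties.
#' @param ids Optional variant ids used to break remaining ties.
#' @return Integer vector `c(r, s)` of 1-based locus indices, 0 meaning the
#'   pseudolocus.
#' @examples
#' collapse_indices(c(0, 0.5, -0.5), c(0.009, 0.002, 0.004))  # c(2, 3)
#' @export
collapse_indices <- function(d_row, mafs, pos = seq_along(mafs),
                             ids = as.character(seq_along(mafs))) {
  if (length(d_row) != length(mafs)) {
    stop("`d_row` and `mafs` must have the same length", call. = FALSE)
  }
  dev <- which(d_row != 0)
  if (length(dev) == 0L) return(c(r = 0L, s = 0L))
  ord <- dev[order(mafs[dev], pos[dev], ids[dev])]
  c(r = ord[1], s = if (length(ord) >= 2L) ord[2] else 0L)
}

#' Estimate minor-allele frequencies from dosages
#'
#' Per-locus mean dosage divided by 2.  When the estimate exceeds 0.5 the
#' coded allele is actually the major allele; the frequency is reported for
#' the minor allele (`1 - estimate`) and the locus is flagged so that
#' genotype scores can be flipped (`2 - score`) before modelling.
#'
#' @param dosages Numeric matrix, individuals x loci, entries in `[0, 2]`
#'   (hard genotypes or imputed dosages); `NA` entries are ignored.
#' @return A tibble with one row per locus: `locus`, `maf`, `flipped`.
#' @export
estimate_maf <- function(dosages) {
  dosages <- as.matrix(dosages)
  n_ok <- colSums(!is.na(dosages))
  if (any(n_ok == 0L)) {
    stop("no non-missing dosages at locus ",
         paste(which(n_ok == 0L), collapse = ", "), call. = FALSE)
  }
  raw <- unname(colMeans(dosages, na.rm = TRUE)) / 2
  flipped <- raw > 0.5
  tibble::tibble(
    locus = if (is.null(colnames(dosages))) as.character(seq_along(raw))
            else colnames(dosages),
    maf = ifelse(flipped, 1 - raw, raw),
    flipped = flipped
  )
}

#' Filter a variant table down to informative rare variants
#'
#' Keeps variants with `0 < maf < threshold`.  Monomorphic variants carry no
#' information and would inflate the locus count entering the prior odds, so
#' they are dropped even though a plain "MAF below threshold" rule would
#' admit them.
#'
#' @param variants A tibble with at least a `maf` column.
#' @param threshold Upper MAF bound, default 0.01 (rare-variant convention).
#' @return The filtered tibble; possibly zero rows (a skippable gene).
#' @export
filter_rare <- function(variants, threshold = 0.01) {
  dplyr::filter(variants, .data$maf > 0, .data$maf < threshold)
}

#' Probability of carrying minor alleles at more than two loci
#'
#' With K independent rare loci and per-locus carrier probability `p`, the
#' number of carried loci is Binomial(K, p); this returns `P(X > 2)`.  Its
#' smallness justifies collapsing each offspring onto at most two deviating
#' loci.
#'
#' @param k Number of loci (>= 1).
#' @param carrier_prob Per-locus carrier probability in `[0, 1]`
#'   (about `2 * maf` for a rare variant under Hardy-Weinberg).
#' @return `P(X > 2)` for `X ~ Binomial(k, carrier_prob)`.
#' @examples
#' multi_carrier_probability(50, 0.01)  # about 0.0138
#' @export
multi_carrier_probability <- function(k, carrier_prob) {
  stopifnot(k >= 1, carrier_prob >= 0, carrier_prob <= 1)
  pbinom(2, size = k, prob = carrier_prob, lower.tail = FALSE)
}

#' Build the collapsed per-offspring dataset for one gene
#'
#' Decomposes offspring genotypic scores into the between-family Mendelian
#' expectation `GE = (GM + GF) / 2` and the within-family deviation
#' `D = G - GE`, then collapses each offspring onto its (at most) two
#' deviating loci with the smallest MAFs.  Offspring whose genotype is
#' Mendelianly impossible given their parents (for example score 2 from two
#' non-carrier parents) are dropped with a warning.
#'
#' @param G Integer matrix, offspring x loci, minor-allele counts.
#' @param GM,GF Integer matrices, family x loci, parental scores (mother,
#'   father).
#' @param family Integer vector mapping each offspring (row of `G`) to a
#'   family (row of `GM`/`GF`).
#' @param y Numeric phenotype vector, one value per offspring.
#' @param variants Tibble describing the loci, with columns `variant_id`,
#'   `maf` and optionally `pos` (used for deterministic MAF tie-breaks).
#' @param covariates Optional numeric matrix or data frame of per-offspring
#'   covariates (for example age).
#' @param family_ids Optional character vector of family labels.
#' @return A tibble of class `collapsed_gene` with one row per retained
#'   offspring and columns `family_id`, `family`, `offspring`, `y`, `r`,
#'   `s`, `D_r`, `D_s`, `GE_r`, `GE_s` plus any covariates.  The full `GE`
#'   (family x loci) and `D` (offspring x loci) matrices, the variant table
#'   and counts are kept as attributes.
#' @export
collapse_gene <- function(G, GM, GF, family, y, variants,
                          covariates = NULL, family_ids = NULL) {
  G <- as.matrix(G); GM <- as.matrix(GM); GF <- as.matrix(GF)
  K <- ncol(G)
  M <- nrow(GM)
  stopifnot(ncol(GM) == K, ncol(GF) == K, nrow(GF) == M,
            length(family) == nrow(G), length(y) == nrow(G),
            nrow(variants) == K)
  if (is.null(family_ids)) family_ids <- as.character(seq_len(M))
  pos <- if ("pos" %in% names(variants)) variants$pos else seq_len(K)
  ids <- as.character(variants$variant_id)

  GE <- (GM + GF) / 2                       # family x loci
  D <- G - GE[family, , drop = FALSE]       # offspring x loci

  # Mendelian legality: each child allele must be obtainable from its parent
  legal <- function(g, gm, gf) {
    lo <- (gm == 2) + (gf == 2)
    hi <- 2 - ((gm == 0) + (gf == 0))
    g >= lo & g <= hi
  }
  ok_mat <- legal(G, GM[family, , drop = FALSE], GF[family, , drop = FALSE])
  keep <- rowSums(!ok_mat) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " offspring dropped for Mendelian inconsistency",
            call. = FALSE)
    G <- G[keep, , drop = FALSE]
    D <- D[keep, , drop = FALSE]
    family <- family[keep]
    y <- y[keep]
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    }
  }

  rs <- t(vapply(seq_len(nrow(D)), function(j) {
    collapse_indices(D[j, ], variants$maf, pos, ids)
  }, integer(2)))

  idx0 <- function(mat, row, col) {
    # value at (row, col) treating col 0 as the all-zero pseudolocus
    out <- numeric(length(row))
    nz <- col > 0L
    out[nz] <- mat[cbind(row[nz], col[nz])]
    out
  }
  j <- seq_along(y)
  out <- tibble::tibble(
    family_id = family_ids[family],
    family = as.integer(family),
    offspring = stats::ave(j, family, FUN = seq_along),
    y = as.numeric(y),
    r = as.integer(unname(rs[, 1])), s = as.integer(unname(rs[, 2])),
    D_r = idx0(D, j, rs[, 1]),
    D_s = idx0(D, j, rs[, 2]),
    GE_r = idx0(GE, family, rs[, 1]),
    GE_s = idx0(GE, family, rs[, 2])
  )
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(covariates))
    attr(out, "covariate_names") <- colnames(covariates)
  } else {
    attr(out, "covariate_names") <- character(0)
  }
  attr(out, "variants") <- variants
  attr(out, "GE") <- GE
  attr(out, "D") <- D
  attr(out, "K") <- K
  attr(out, "M") <- M
  class(out) <- c("collapsed_gene", class(out))
  out
}

#' @exportS3Method base::print
print.collapsed_gene <- function(x, ...) {
  cat("Collapsed gene: ", attr(x, "K"), " rare loci, ",
      attr(x, "M"), " families, ", nrow(x), " offspring\n", sep = "")
  NextMethod()
}

n_informative <- function(gene) sum(gene$r > 0L)
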