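#' TPM (and FPKM) with library-size exclusions
#'
#' Length-normalized rates are `count / exonic length`; the per-sample
#' denominator sums rates over genes that are neither on chromosomes X, Y
#' or MT nor of biotype rRNA/tRNA, because those distort library-size
#' estimation. Excluded genes still receive TPM values against the
#' included-gene denominator, so TPM over included genes sums to 1e6 per
#' sample.
#'
#' @param counts gene-by-sample integer matrix.
#' @param genes gene-model data frame (`gene_id`, `contig`, `biotype`,
#'   `exon_len`) covering all count rows.
#' @param excluded_contigs contigs omitted from the denominator.
#' @param excluded_biotypes biotypes omitted from the denominator.
#' @return list with `tpm`, `fpkm` matrices and the logical `included`
#'   vector per gene.
#' @export
compute_tpm <- function(counts, genes,
                        excluded_contigs = c("X", "Y", "MT", "chrX", "chrY",
                                             "chrM", "chrMT"),
                        excluded_biotypes = c("rRNA", "tRNA")) {
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx))
    stop("gene metadata missing for: ",
         paste(head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  len <- genes$exon_len[idx]
  if (any(len < 1)) stop("exonic lengths must be >= 1")
  included <- !(genes$contig[idx] %in% excluded_contigs) &
    !(genes$biotype[idx] %in% excluded_biotypes)
  rate <- counts / len
  denom <- colSums(rate[included, , drop = FALSE])
  if (any(denom <= 0)) stop("zero library-size denominator in sample(s): ",
                            paste(colnames(counts)[denom <= 0], collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  lib <- colSums(counts[included, , drop = FALSE])
  fpkm <- sweep(counts / (len / 1e3), 2, lib / 1e6, "/")
  list(tpm = tpm, fpkm = fpkm, included = stats::setNames(included,
                                                          rownames(counts)))
}

#' Immunoglobulin constant-gene expression profile and dominant isotype
#'
#' @param tpm gene-by-sample TPM matrix.
#' @param panel character vector of IG constant gene ids (e.g. IGHM,
#'   IGHG1-4, IGHA1-2, IGHD, IGHE, IGKC, IGLC...).
#' @return list with `profile` (samples x panel, `log2(TPM + 1)`) and
#'   `dominant` (named character; `NA` for an all-zero panel).
#' @export
ig_constant_profile <- function(tpm, panel) {
  missing <- setdiff(panel, rownames(tpm))
  if (length(missing))
    stop("panel gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  prof <- t(log2(tpm[panel, , drop = FALSE] + 1))
  dominant <- apply(prof, 1, function(x)
    if (all(x == 0)) NA_character_ else panel[which.max(x)])
  list(profile = prof, dominant = dominant)
}

#' Emulate the RNA dilution experiment
#'
#' For each contamination fraction f, the expected per-gene profile is
#' `(1 - f) * tumor + f * background` (as proportions), resampled
#' multinomially to the tumor library size to keep counting noise.
#'
#' @param tumor,background named count vectors over the same genes.
#' @param fractions background fractions (default `c(0, .2, .4, .6, .8)`).
#' @param seed integer seed.
#' @return gene x fraction count matrix with columns named `f0`, `f0.2`, ...
#' @export
mix_profiles <- function(tumor, background,
                         fractions = c(0, 0.2, 0.4, 0.6, 0.8), seed = 1) {
  if (!identical(sort(names(tumor)), sort(names(background))))
    stop("tumor and background gene sets differ")
  background <- background[names(tumor)]
  lib <- sum(tumor)
  set.seed(as.integer(seed %% 2147483647))
  out <- vapply(fractions, function(f) {
    p <- (1 - f) * tumor / sum(tumor) + f * background / sum(background)
    as.numeric(stats::rmultinom(1, lib, p))
  }, numeric(length(tumor)))
  dimnames(out) <- list(names(tumor), paste0("f", fractions))
  out
}

#' Estimate the background fraction of a diluted profile
#'
#' Nonnegative regression of the diluted proportions on the tumor and
#' background proportions; the recovered fraction is the background
#' coefficient share.
#'
#' @param mixed,tumor,background count vectors over the same genes.
#' @return estimated background fraction in `[0, 1]`.
#' @export
estimate_dilution_fraction <- function(mixed, tumor, background) {
  A <- cbind(tumor / sum(tumor), background / sum(background))
  fit <- nnls_fit(A, mixed / sum(mixed))
  if (sum(fit$x) == 0) return(NA_real_)
  fit$x[2] / sum(fit$x)
}

#' Z-score gene expression across samples
#'
#' Per gene over samples on the `log2(TPM + 1)` scale, using the sample
#' (n - 1) standard deviation; constant genes get z = 0.
#'
#' @param tpm gene-by-sample TPM matrix.
#' @param gene_set optional subset of genes (default all).
#' @return z matrix over `gene_set`.
#' @export
zscore_genes <- function(tpm, gene_set = rownames(tpm)) {
  if (ncol(tpm) < 2) stop("need at least 2 samples")
  x <- log2(tpm[gene_set, , drop = FALSE] + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
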