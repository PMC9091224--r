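#' The 96 single-base-substitution channels in conventional order
#'
#' Substitutions on the pyrimidine strand (C>A, C>G, C>T, T>A, T>C, T>G),
#' each over the 16 trinucleotide contexts with 5' and 3' flanks ordered
#' A, C, G, T — i.e. A[C>A]A first and T[T>G]T last.
#'
#' @return character vector of 96 channel labels like `"A[C>T]G"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))))
}

# single-base complement lookup
comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Build an SBS96 mutational catalog from SNVs and reference context
#'
#' Each SNV is collapsed to the pyrimidine strand: when the reference base is
#' A or G, reference, alternative and both flanks are reverse-complemented.
#' SNVs whose stated reference base disagrees with the genome sequence, or
#' that sit on a contig edge without both flanks, are skipped and counted in
#' the `discarded` attribute.
#'
#' @param variants a [variant_table()] (indels ignored).
#' @param genome a [genome_ref()] carrying sequences.
#' @return 96 x samples integer matrix (rows in [sbs96_channels()] order)
#'   with attribute `discarded` (named count per reason).
#' @export
build_sbs96_catalog <- function(variants, genome) {
  snv <- variants[variants$class == "SNV", , drop = FALSE]
  samples <- sort(unique(variants$sample))
  channels <- sbs96_channels()
  cat_m <- matrix(0L, 96, length(samples),
                  dimnames = list(channels, samples))
  discarded <- c(ref_mismatch = 0L, contig_edge = 0L)
  if (nrow(snv)) {
    lens <- genome$contigs[snv$contig]
    edge <- snv$pos <= 1L | snv$pos >= lens
    discarded["contig_edge"] <- sum(edge)
    snv <- snv[!edge, , drop = FALSE]
    ctx <- character(nrow(snv))
    for (ctg in unique(snv$contig)) {
      i <- snv$contig == ctg
      ctx[i] <- substring(genome$sequences[[ctg]], snv$pos[i] - 1L,
                          snv$pos[i] + 1L)
    }
    mid <- substr(ctx, 2, 2)
    mism <- mid != snv$ref
    discarded["ref_mismatch"] <- sum(mism)
    snv <- snv[!mism, , drop = FALSE]; ctx <- ctx[!mism]
    if (nrow(snv)) {
      pur <- snv$ref %in% c("A", "G")
      f5 <- substr(ctx, 1, 1); f3 <- substr(ctx, 3, 3)
      ref <- snv$ref; alt <- snv$alt
      ref[pur] <- comp_base(ref[pur]); alt[pur] <- comp_base(alt[pur])
      tmp <- comp_base(f3[pur]); f3[pur] <- comp_base(f5[pur]); f5[pur] <- tmp
      lab <- paste0(f5, "[", ref, ">", alt, "]", f3)
      tab <- table(factor(lab, levels = channels),
                   factor(snv$sample, levels = samples))
      cat_m <- cat_m + matrix(as.integer(tab), 96, length(samples),
                              dimnames = dimnames(cat_m))
    }
  }
  attr(cat_m, "discarded") <- discarded
  cat_m
}

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min || A x - b ||_2` subject to `x >= 0` exactly (KKT conditions
#' hold at convergence to within `tol`).
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol dual-feasibility tolerance.
#' @return list with `x` (solution), `residual` (L2 norm) and `gradient`
#'   (`t(A) %*% (A x - b)`).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  w <- Atb - AtA %*% x
  iter <- 0L; max_iter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    t_in <- cand[which.max(w[cand])]
    passive[t_in] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[P] > tol)) break
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- Atb - AtA %*% x
  }
  list(x = as.numeric(x), residual = sqrt(sum((A %*% x - b)^2)),
       gradient = as.numeric(AtA %*% x - Atb))
}

#' Supervised signature decomposition (linear combination decomposition)
#'
#' Fits each sample's mutational catalog as a nonnegative linear combination
#' of known signatures by non-negative least squares, then applies
#' signature-specific relative-exposure cutoffs: signatures whose share of
#' the total exposure falls below their cutoff are zeroed and the NNLS is
#' re-solved over the survivors. By default this zero-and-refit loop runs to
#' a fixed point (order-independent); `single_pass = TRUE` performs exactly
#' one zero-and-refit round.
#'
#' @param catalog channels x samples count matrix.
#' @param signatures channels x signatures matrix; columns sum to 1. Row
#'   names must match the catalog exactly (names and order).
#' @param cutoffs named numeric vector of minimal relative exposures in
#'   `[0, 1)` per signature; unnamed scalar recycles. Default 0 (no cutoff).
#' @param single_pass apply the cutoff step once instead of iterating.
#' @param max_iter fixed-point iteration cap.
#' @return list with `exposures` (signatures x samples counts), `normalized`
#'   (columns summing to 1, or all zero) and `residuals` per sample.
#' @export
decompose_lcd <- function(catalog, signatures, cutoffs = 0,
                          single_pass = FALSE, max_iter = 20L) {
  catalog <- as.matrix(catalog); signatures <- as.matrix(signatures)
  if (is.null(rownames(catalog)) || is.null(rownames(signatures)) ||
      !identical(rownames(catalog), rownames(signatures))) {
    off <- union(setdiff(rownames(catalog), rownames(signatures)),
                 setdiff(rownames(signatures), rownames(catalog)))
    stop("catalog/signature channel mismatch",
         if (length(off)) paste0(": ", paste(head(off, 5), collapse = ", ")))
  }
  csums <- colSums(signatures)
  if (any(abs(csums - 1) > 1e-6))
    stop("signature columns must sum to 1")
  sig_names <- colnames(signatures)
  if (length(cutoffs) == 1 && is.null(names(cutoffs)))
    cutoffs <- stats::setNames(rep(cutoffs, ncol(signatures)), sig_names)
  if (!all(sig_names %in% names(cutoffs)))
    stop("cutoffs missing for: ",
         paste(setdiff(sig_names, names(cutoffs)), collapse = ", "))
  cutoffs <- cutoffs[sig_names]
  if (any(cutoffs < 0 | cutoffs >= 1)) stop("cutoffs must lie in [0, 1)")
  ns <- ncol(catalog)
  expo <- matrix(0, ncol(signatures), ns,
                 dimnames = list(sig_names, colnames(catalog)))
  resid <- numeric(ns)
  for (s in seq_len(ns)) {
    b <- catalog[, s]
    active <- rep(TRUE, ncol(signatures))
    e <- numeric(ncol(signatures))
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      fit <- nnls_fit(signatures[, active, drop = FALSE], b)
      e[] <- 0; e[active] <- fit$x
      tot <- sum(e)
      drop_i <- if (tot > 0) active & (e / tot < cutoffs) & (cutoffs > 0)
                else rep(FALSE, length(e))
      # signatures at exactly zero exposure stay in the active set unless
      # their cutoff removes them; they cost nothing in the refit
      if (!any(drop_i)) break
      active <- active & !drop_i
      e[drop_i] <- 0
      if (single_pass) {
        fit <- nnls_fit(signatures[, active, drop = FALSE], b)
        e[] <- 0; e[active] <- fit$x
        break
      }
    }
    expo[, s] <- e
    resid[s] <- sqrt(sum((catalog[, s] - signatures %*% e)^2))
  }
  tots <- colSums(expo)
  normalized <- sweep(expo, 2, ifelse(tots > 0, tots, 1), "/")
  list(exposures = expo, normalized = normalized,
       residuals = stats::setNames(resid, colnames(catalog)))
}

#' Compare one signature's normalized exposures between two subgroups
#'
#' Two-sided Mann-Whitney U test on the normalized exposures of the named
#' signature; exact when both groups are small without ties, otherwise the
#' tie-corrected normal approximation.
#'
#' @param normalized signatures x samples matrix of normalized exposures
#'   (the `normalized` element of [decompose_lcd()]).
#' @param labels named character vector sample -> subgroup label.
#' @param signature signature name.
#' @param groupA,groupB subgroup labels to compare.
#' @return list with `p`, `nA`, `nB` and group medians.
#' @export
compare_exposures <- function(normalized, labels, signature, groupA, groupB) {
  if (!signature %in% rownames(normalized))
    stop("unknown signature: ", signature)
  labels <- labels[colnames(normalized)]
  if (!groupA %in% labels || !groupB %in% labels)
    stop("unknown group label")
  xa <- normalized[signature, labels == groupA & !is.na(labels)]
  xb <- normalized[signature, labels == groupB & !is.na(labels)]
  if (length(xa) < 2 || length(xb) < 2)
    stop("need at least 2 samples per group")
  wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                            alternative = "two.sided"))
  list(p = wt$p.value, nA = length(xa), nB = length(xb),
       medianA = stats::median(xa), medianB = stats::median(xb))
}

#' Read a signature matrix from TSV (channel column + one column/signature)
#' @param path TSV file.
#' @export
read_signatures <- function(path) {
  m <- read_matrix_tsv(path)
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop("signature columns must sum to 1")
  m
}
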