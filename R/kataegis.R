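#' Detect kataegis hotspots in the SNVs of one sample
#'
#' A hotspot is a run of at least `min_snvs` consecutive SNV sites whose mean
#' intermutational distance, `(last - first) / (n - 1)`, is at most
#' `max_mean_imd` bp. All qualifying runs are enumerated per contig and
#' overlapping or adjacent qualifying runs are merged into maximal regions;
#' the reported SNV count and mean IMD are recomputed from the final member
#' set. Sites (not alleles) are the spatial unit: SNVs at identical positions
#' count once.
#'
#' @param variants a [variant_table()]; indels are ignored.
#' @param min_snvs minimum number of SNV sites per region (default 6).
#' @param max_mean_imd maximum mean intermutational distance in bp
#'   (default 1000, inclusive).
#' @return data frame `sample, contig, start, end, n_snvs, mean_imd` with
#'   0-based half-open intervals spanning the first to the last member SNV.
#' @export
detect_hotspots <- function(variants, min_snvs = 6, max_mean_imd = 1000) {
  snv <- variants[variants$class == "SNV", , drop = FALSE]
  out <- list()
  for (sm in unique(snv$sample)) {
    for (ctg in unique(snv$contig[snv$sample == sm])) {
      p <- sort(unique(snv$pos[snv$sample == sm & snv$contig == ctg]))
      runs <- qualifying_runs(p, min_snvs, max_mean_imd)
      if (nrow(runs) == 0) next
      runs <- merge_index_runs(runs)
      out[[length(out) + 1L]] <- data.frame(
        sample = sm, contig = ctg,
        start = p[runs$i] - 1L, end = p[runs$j],
        n_snvs = runs$j - runs$i + 1L,
        mean_imd = (p[runs$j] - p[runs$i]) / (runs$j - runs$i),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_snvs = integer(), mean_imd = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# index runs [i, j] over sorted unique positions p that satisfy the rule;
# per start index only the maximal qualifying end is kept — as an index
# interval it contains every shorter qualifying run with the same start, so
# the merged union is unchanged.
qualifying_runs <- function(p, min_snvs, max_mean_imd) {
  n <- length(p)
  if (n < min_snvs) return(data.frame(i = integer(), j = integer()))
  ii <- jj <- integer()
  for (i in seq_len(n - min_snvs + 1L)) {
    js <- (i + min_snvs - 1L):n
    ok <- (p[js] - p[i]) / (js - i) <= max_mean_imd
    if (any(ok)) { ii <- c(ii, i); jj <- c(jj, max(js[ok])) }
  }
  data.frame(i = ii, j = jj)
}

# union of overlapping or adjacent index intervals (sharing an SNV, or
# starting at the SNV right after the previous window ends)
merge_index_runs <- function(runs) {
  runs <- runs[order(runs$i, runs$j), , drop = FALSE]
  mi <- runs$i[1]; mj <- runs$j[1]; out_i <- out_j <- integer()
  for (r in seq_len(nrow(runs))[-1]) {
    if (runs$i[r] <= mj + 1L) mj <- max(mj, runs$j[r])
    else { out_i <- c(out_i, mi); out_j <- c(out_j, mj)
           mi <- runs$i[r]; mj <- runs$j[r] }
  }
  data.frame(i = c(out_i, mi), j = c(out_j, mj))
}

#' Map kataegis regions onto targeted genes
#'
#' A gene is targeted when its body has a nonempty intersection (half-open
#' convention, strand-agnostic) with at least one kataegis region in at
#' least one sample.
#'
#' @param regions output of [detect_hotspots()] over a cohort.
#' @param genes gene-model data frame from [read_gene_models()].
#' @return data frame `gene_id, n_samples, samples` (comma-separated,
#'   deduplicated sample ids), one row per targeted gene.
#' @export
annotate_hotspot_genes <- function(regions, genes) {
  if (nrow(regions) == 0)
    return(data.frame(gene_id = character(), n_samples = integer(),
                      samples = character()))
  gr_reg <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end))
  gr_gen <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gen, gr_reg, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(gene_id = character(), n_samples = integer(),
                      samples = character()))
  by_gene <- split(regions$sample[S4Vectors::subjectHits(hits)],
                   genes$gene_id[S4Vectors::queryHits(hits)])
  res <- data.frame(
    gene_id = names(by_gene),
    n_samples = vapply(by_gene, function(s) length(unique(s)), 0L),
    samples = vapply(by_gene, function(s)
      paste(sort(unique(s)), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

#' Compare hotspot frequency of one gene between two cohorts
#'
#' Two-sided Fisher's exact test (point-probability rule) on the 2x2 table
#' of targeted vs non-targeted samples, with the odds ratio recomputed from
#' Haldane-corrected cell counts when any margin cell is zero.
#'
#' @param kA,nA targeted and total samples in cohort A.
#' @param kB,nB targeted and total samples in cohort B.
#' @return list with `p`, `odds_ratio` and the underlying `table`.
#' @export
compare_hotspot_frequency <- function(kA, nA, kB, nB) {
  if (nA == 0 || nB == 0) stop("cohort sizes must be positive")
  stopifnot(kA <= nA, kB <= nB, kA >= 0, kB >= 0)
  tab <- matrix(c(kA, nA - kA, kB, nB - kB), nrow = 2,
                dimnames = list(c("hotspot", "none"), c("A", "B")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- if (any(tab == 0))
    ((kA + 0.5) * (nB - kB + 0.5)) / ((nA - kA + 0.5) * (kB + 0.5))
  else unname(ft$estimate)
  list(p = ft$p.value, odds_ratio = or, table = tab)
}

#' Test whether hotspot-targeted genes are expressed higher, per biotype
#'
#' Summarizes each gene as `log2(mean TPM + 1)` over samples and runs a
#' one-sided Wilcoxon rank-sum test (hotspot genes greater) within each of
#' the biotypes antisense, lincRNA, miRNA and protein_coding. Biotypes with
#' fewer than two genes in either group are skipped with a notice.
#'
#' @param tpm gene-by-sample TPM matrix.
#' @param hotspot_genes character vector of targeted gene ids.
#' @param genes gene-model data frame supplying biotypes.
#' @return data frame `biotype, n_hotspot, n_other, median_hotspot,
#'   median_other, p`.
#' @export
test_expression_by_kataegis <- function(tpm, hotspot_genes, genes) {
  biotypes <- c("antisense", "lincRNA", "miRNA", "protein_coding")
  expr <- log2(rowMeans(tpm) + 1)
  res <- list()
  for (bt in biotypes) {
    ids <- genes$gene_id[genes$biotype == bt]
    ids <- intersect(ids, rownames(tpm))
    hs <- intersect(ids, hotspot_genes)
    ot <- setdiff(ids, hotspot_genes)
    if (length(hs) < 2 || length(ot) < 2) {
      message("skipping biotype ", bt, ": fewer than 2 genes in a group")
      next
    }
    wt <- suppressWarnings(
      stats::wilcox.test(expr[hs], expr[ot], alternative = "greater"))
    res[[bt]] <- data.frame(
      biotype = bt, n_hotspot = length(hs), n_other = length(ot),
      median_hotspot = stats::median(expr[hs]),
      median_other = stats::median(expr[ot]),
      p = wt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(biotype = character(), n_hotspot = integer(),
                      n_other = integer(), median_hotspot = numeric(),
                      median_other = numeric(), p = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
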