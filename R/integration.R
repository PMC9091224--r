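# alteration categories entering oncoprint recurrence, and the coding effect
# classes that qualify a small variant
ONCOPRINT_CATEGORIES <- c("SNV_coding", "indel_coding", "ncRNA_exonic",
                          "SV_direct", "CNA_focal_gain", "CNA_focal_loss")
CODING_EFFECTS <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                    "frameshift", "nonframeshift")

#' Drop recurrent-artifact indels
#'
#' Somatic indels whose identical call (contig, pos, ref, alt) carries a
#' germline flag in at least two distinct patients are removed from every
#' sample's somatic set.
#'
#' @param variants cohort [variant_table()] (all samples, germline flags
#'   included).
#' @param min_patients germline-recurrence threshold (default 2).
#' @return the variant table without artifact indels (germline records of
#'   the artifact sites are retained; only somatic indel records are
#'   dropped).
#' @export
filter_recurrent_artifact_indels <- function(variants, min_patients = 2) {
  indel <- variants$class %in% c("insertion", "deletion")
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt)
  germ_patients <- tapply(variants$sample[indel & variants$germline],
                          key[indel & variants$germline],
                          function(s) length(unique(s)))
  artifact_keys <- names(germ_patients)[germ_patients >= min_patients]
  drop <- indel & !variants$germline & key %in% artifact_keys
  out <- variants[!drop, , drop = FALSE]
  attr(out, "n_artifact_removed") <- sum(drop)
  rownames(out) <- NULL
  out
}

#' Annotate SV breakpoints to genes (direct / near / closest)
#'
#' Each breakpoint end is annotated independently: `direct` genes contain
#' the breakpoint position; `near` genes lie within 100 kb of it (distance
#' to the gene body, exclusive of containment); `closest` is the single
#' nearest gene on the breakpoint's contig (ties go to the smaller start
#' coordinate). Only `direct` hits feed oncoprint recurrence.
#'
#' @param svs structural-variant data frame ([read_bedpe()] schema).
#' @param genes gene-model data frame.
#' @param near_bp `near` distance threshold in bp (default 100000).
#' @return data frame with one row per breakpoint end: `sample, sv_row,
#'   bp_end, contig, pos, direct, near, closest` (gene ids, comma-separated
#'   for multi-hits).
#' @export
annotate_sv_to_genes <- function(svs, genes, near_bp = 1e5) {
  ends <- rbind(
    data.frame(sample = svs$sample, sv_row = seq_len(nrow(svs)), bp_end = 1L,
               contig = svs$contig1, pos = svs$pos1, stringsAsFactors = FALSE),
    data.frame(sample = svs$sample, sv_row = seq_len(nrow(svs)), bp_end = 2L,
               contig = svs$contig2, pos = svs$pos2, stringsAsFactors = FALSE))
  ends <- ends[order(ends$sv_row, ends$bp_end), , drop = FALSE]
  ends$direct <- ends$near <- ends$closest <- NA_character_
  unannotated <- character()
  for (r in seq_len(nrow(ends))) {
    on <- genes$contig == ends$contig[r]
    if (!any(on)) {
      unannotated <- union(unannotated, ends$contig[r])
      next
    }
    g <- genes[on, , drop = FALSE]
    p0 <- ends$pos[r] - 1L  # 0-based position of the breakpoint base
    inside <- g$start <= p0 & p0 < g$end
    # distance in bp between the breakpoint base and the nearest gene base
    dist <- ifelse(inside, 0L,
                   ifelse(p0 < g$start, g$start - p0, p0 - g$end + 1L))
    ends$direct[r] <- paste(g$gene_id[inside], collapse = ",")
    near <- !inside & dist <= near_bp
    ends$near[r] <- paste(g$gene_id[near], collapse = ",")
    o <- order(dist, g$start)
    ends$closest[r] <- g$gene_id[o[1]]
  }
  if (length(unannotated))
    warning("no gene annotation on contig ",
            paste(unannotated, collapse = ", "))
  rownames(ends) <- NULL
  ends
}

#' Classify focal copy-number events at gene level
#'
#' A gain/loss segment (by the [count_gains_losses()] rounding rules) is
#' focal when it covers at most `max_arm_fraction` of its chromosome arm;
#' genes completely or partially overlapped by a focal segment receive
#' `CNA_focal_gain` / `CNA_focal_loss`.
#'
#' @param seg smoothed segments of one sample.
#' @param genome a [genome_ref()] with arm table.
#' @param genes gene-model data frame.
#' @param ploidy sample ploidy.
#' @param max_arm_fraction focality bound (default 0.30).
#' @return data frame `gene_id, category` for this sample.
#' @export
classify_focal_cna <- function(seg, genome, genes, ploidy,
                               max_arm_fraction = 0.30) {
  if (ploidy <= 0) stop("ploidy must be positive")
  arms <- genome_arms(genome)
  rp <- round_half_away(ploidy)
  r <- round_half_away(seg$tcn)
  kind <- ifelse(r > rp, "CNA_focal_gain",
                 ifelse(r < rp, "CNA_focal_loss", NA))
  out <- list()
  for (i in which(!is.na(kind))) {
    a <- arms[arms$contig == seg$contig[i], , drop = FALSE]
    if (nrow(a) == 0)
      stop("no arm definition for contig ", seg$contig[i])
    # fraction of the arm the segment covers, on the arm holding most of it
    cov <- pmax(0, pmin(seg$end[i], a$end) - pmax(seg$start[i], a$start))
    k <- which.max(cov)
    if (cov[k] / (a$end[k] - a$start[k]) > max_arm_fraction) next
    hit <- genes$contig == seg$contig[i] &
      genes$start < seg$end[i] & genes$end > seg$start[i]
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[hit], category = kind[i],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), category = character()))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Build the gene-by-sample alteration matrix
#'
#' Integrates coding small variants, exonic ncRNA variants, direct SV hits
#' and focal CNAs into a categorical alteration table. `SV_near`/`SV_close`
#' annotations are kept as an auxiliary table and never enter oncoprint
#' recurrence.
#'
#' @param variants cohort [variant_table()] (somatic records only are
#'   used; synonymous and noncoding classes are excluded).
#' @param sv_annot output of [annotate_sv_to_genes()], or `NULL`.
#' @param focal named list sample -> [classify_focal_cna()] output, or
#'   `NULL`.
#' @param samples character vector fixing the cohort (columns).
#' @return list with `long` (gene, sample, category rows), `recurrence`
#'   (named vector: samples altered per gene) and `aux_sv` (near/close
#'   gene-sample pairs).
#' @export
build_alteration_matrix <- function(variants, sv_annot = NULL, focal = NULL,
                                    samples = NULL) {
  if (is.null(samples))
    samples <- sort(unique(c(variants$sample,
                             if (!is.null(sv_annot)) sv_annot$sample,
                             names(focal))))
  som <- variants[!variants$germline & !is.na(variants$gene), , drop = FALSE]
  long <- list()
  snv_cod <- som$class == "SNV" & som$effect %in% CODING_EFFECTS
  ind_cod <- som$class != "SNV" & som$effect %in% CODING_EFFECTS
  ncrna <- som$effect == "ncRNA_exonic"
  add <- function(gene, sample, category) {
    if (!length(gene)) return()
    long[[length(long) + 1L]] <<- data.frame(
      gene = gene, sample = sample, category = category,
      stringsAsFactors = FALSE)
  }
  add(som$gene[snv_cod], som$sample[snv_cod], "SNV_coding")
  add(som$gene[ind_cod], som$sample[ind_cod], "indel_coding")
  add(som$gene[ncrna], som$sample[ncrna], "ncRNA_exonic")
  aux <- list()
  if (!is.null(sv_annot) && nrow(sv_annot)) {
    split_genes <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ",")
    for (r in seq_len(nrow(sv_annot))) {
      d <- split_genes(sv_annot$direct[r])[[1]]
      add(d, rep(sv_annot$sample[r], length(d)), "SV_direct")
      nr <- union(split_genes(sv_annot$near[r])[[1]],
                  stats::na.omit(sv_annot$closest[r]))
      if (length(nr))
        aux[[length(aux) + 1L]] <- data.frame(
          gene = nr, sample = sv_annot$sample[r], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(focal))
    for (sm in names(focal))
      if (nrow(focal[[sm]]))
        add(focal[[sm]]$gene_id, sm, focal[[sm]]$category)
  long <- if (length(long)) unique(do.call(rbind, long)) else
    data.frame(gene = character(), sample = character(),
               category = character())
  stopifnot(all(long$category %in% ONCOPRINT_CATEGORIES))
  rec <- if (nrow(long)) tapply(long$sample, long$gene,
                                function(s) length(unique(s)))
         else stats::setNames(integer(), character())
  aux <- if (length(aux)) unique(do.call(rbind, aux)) else
    data.frame(gene = character(), sample = character())
  rownames(long) <- NULL
  list(long = long,
       recurrence = rec[order(names(rec))],
       samples = samples,
       aux_sv = aux)
}

# gene -> altered sample set from the long table
altered_samples <- function(am, gene)
  unique(am$long$sample[am$long$gene == gene])

#' Compare per-gene alteration frequency between two subgroups
#'
#' Per gene: two-sided Fisher's exact test on altered counts and a
#' Haldane-Anscombe log2 fold change,
#' `log2(((kA + 0.5)/(nA + 1)) / ((kB + 0.5)/(nB + 1)))`. No
#' multiple-testing correction is applied.
#'
#' @param am [build_alteration_matrix()] result.
#' @param labels named character vector sample -> subgroup.
#' @param groupA,groupB subgroup labels.
#' @return data frame `gene, kA, nA, kB, nB, log2fc, p`.
#' @export
recurrence_compare <- function(am, labels, groupA, groupB) {
  sA <- names(labels)[labels == groupA]
  sB <- names(labels)[labels == groupB]
  if (!length(sA) || !length(sB)) stop("empty subgroup")
  genes <- sort(unique(am$long$gene))
  res <- lapply(genes, function(g) {
    sm <- altered_samples(am, g)
    kA <- sum(sA %in% sm); kB <- sum(sB %in% sm)
    nA <- length(sA); nB <- length(sB)
    p <- stats::fisher.test(matrix(c(kA, nA - kA, kB, nB - kB), 2))$p.value
    lfc <- log2(((kA + 0.5) / (nA + 1)) / ((kB + 0.5) / (nB + 1)))
    data.frame(gene = g, kA = kA, nA = nA, kB = kB, nB = nB,
               log2fc = lfc, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise mutual-exclusivity and co-occurrence statistics
#'
#' For every unordered pair of genes altered in at least `min_recurrence`
#' samples: a 2x2 table of alteration co-membership over the cohort,
#' Fisher's right-tail p (co-occurrence) and left-tail p (exclusivity),
#' each Benjamini-Hochberg adjusted across all tested pairs per tail.
#'
#' @param am [build_alteration_matrix()] result.
#' @param samples cohort sample ids (defaults to `am$samples`).
#' @param min_recurrence minimal per-gene recurrence (default 5).
#' @return data frame `geneA, geneB, both, onlyA, onlyB, neither, p_right,
#'   p_left, q_right, q_left`.
#' @export
mutual_exclusivity <- function(am, samples = am$samples, min_recurrence = 5) {
  rec <- am$recurrence
  pass <- names(rec)[rec >= min_recurrence]
  if (length(pass) < 2)
    stop("fewer than 2 genes reach recurrence ", min_recurrence)
  pass <- sort(pass)
  pairs <- utils::combn(pass, 2)
  n <- length(samples)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- samples %in% altered_samples(am, pairs[1, i])
    b <- samples %in% altered_samples(am, pairs[2, i])
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2)
    data.frame(geneA = pairs[1, i], geneB = pairs[2, i],
               both = tab[1, 1], onlyA = tab[2, 1], onlyB = tab[1, 2],
               neither = tab[2, 2],
               p_right = stats::fisher.test(tab,
                                            alternative = "greater")$p.value,
               p_left = stats::fisher.test(tab,
                                           alternative = "less")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_right <- stats::p.adjust(out$p_right, method = "BH")
  out$q_left <- stats::p.adjust(out$p_left, method = "BH")
  rownames(out) <- NULL
  out
}
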