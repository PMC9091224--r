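#' @importFrom utils read.delim write.table head tail
NULL

# enumerated vocabularies shared across stages
EFFECT_CLASSES <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                    "frameshift", "nonframeshift", "ncRNA_exonic",
                    "synonymous", "noncoding_other")
VARIANT_CLASSES <- c("SNV", "insertion", "deletion")
SV_CLASSES <- c("deletion", "duplication", "inversion", "translocation")
BIOTYPES <- c("protein_coding", "lincRNA", "antisense", "miRNA", "rRNA",
              "tRNA", "other")

#' Construct and validate a somatic variant table
#'
#' The common in-memory representation of somatic SNV/indel calls: one row
#' per called ALT allele with 1-based positions and optional supporting
#' read counts for tumor and control.
#'
#' @param sample,contig,pos,ref,alt vectors defining the calls (pos 1-based).
#' @param effect effect class, one of
#'   `r paste0('"', EFFECT_CLASSES, '"', collapse = ", ")`.
#' @param gene optional gene id (NA when intergenic/unannotated).
#' @param t_alt,t_dp,c_alt,c_dp optional alt-supporting and total read counts
#'   for the tumor and control sample.
#' @param germline logical, TRUE when the caller classified the variant as
#'   germline.
#' @return data frame with class column `class` derived from allele lengths
#'   (`SNV`, `insertion`, `deletion`).
#' @export
variant_table <- function(sample, contig, pos, ref, alt,
                          effect = "noncoding_other", gene = NA_character_,
                          t_alt = NA_integer_, t_dp = NA_integer_,
                          c_alt = NA_integer_, c_dp = NA_integer_,
                          germline = FALSE) {
  n <- max(length(sample), length(contig), length(pos), length(ref),
           length(alt))
  if (length(pos) == 0) n <- 0
  r <- function(x) rep_len(x, n)
  df <- data.frame(sample = r(as.character(sample)),
                   contig = r(as.character(contig)),
                   pos = r(as.integer(pos)), ref = r(toupper(ref)),
                   alt = r(toupper(alt)), effect = r(as.character(effect)),
                   gene = r(as.character(gene)),
                   t_alt = r(as.integer(t_alt)), t_dp = r(as.integer(t_dp)),
                   c_alt = r(as.integer(c_alt)), c_dp = r(as.integer(c_dp)),
                   germline = r(as.logical(germline)),
                   stringsAsFactors = FALSE)
  df$effect[!df$effect %in% EFFECT_CLASSES] <- "noncoding_other"
  df$class <- ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1, "SNV",
              ifelse(nchar(df$alt) > nchar(df$ref), "insertion", "deletion"))
  snv <- df$class == "SNV"
  bad <- snv & (!df$ref %in% c("A", "C", "G", "T") |
                !df$alt %in% c("A", "C", "G", "T") | df$ref == df$alt)
  if (any(bad)) stop("invalid SNV alleles at row(s) ",
                     paste(which(bad), collapse = ", "))
  if (any(df$pos < 1)) stop("positions must be >= 1")
  ok_counts <- function(a, d) all(is.na(a) | is.na(d) | a <= d)
  if (!ok_counts(df$t_alt, df$t_dp) || !ok_counts(df$c_alt, df$c_dp))
    stop("alt read count exceeds total depth")
  df
}

## ---- VCF subset -----------------------------------------------------------

#' Write somatic variants as a VCF 4.2 subset
#'
#' One record per ALT allele; effect class, gene, variant class and the
#' germline flag travel in INFO; read counts in FORMAT AD/DP with a CONTROL
#' and a TUMOR column.
#'
#' @param variants a [variant_table()] for one sample.
#' @param path output file.
#' @param genome optional [genome_ref()] supplying `##contig` header lines.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(genome))
             sprintf("##contig=<ID=%s,length=%d>", names(genome$contigs),
                     as.integer(genome$contigs)),
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
           "##INFO=<ID=GERMLINE,Number=0,Type=Flag,Description=\"Classified germline\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "CONTROL", "TUMOR", sep = "\t"))
  v <- variants[order(match(variants$contig, unique(variants$contig)),
                      variants$pos), , drop = FALSE]
  info <- paste0("EFFECT=", v$effect,
                 ifelse(is.na(v$gene), "", paste0(";GENE=", v$gene)),
                 ifelse(v$germline, ";GERMLINE", ""))
  fmt_col <- function(alt, dp) ifelse(is.na(alt) | is.na(dp), ".:.",
                                      paste0(dp - alt, ",", alt, ":", dp))
  body <- if (nrow(v)) paste(v$contig, v$pos, ".", v$ref, v$alt, ".",
                             "PASS", info, "AD:DP",
                             fmt_col(v$c_alt, v$c_dp),
                             fmt_col(v$t_alt, v$t_dp), sep = "\t")
          else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF 4.x subset into a somatic variant table
#'
#' @param path VCF file (plain text or bgzipped) with INFO key `EFFECT`
#'   (optional `GENE`, `GERMLINE`) and FORMAT `AD`/`DP` over a CONTROL
#'   (optional) and TUMOR sample column.
#' @param sample_id sample id to stamp on every record.
#' @return a [variant_table()]; unknown effect strings map to
#'   `noncoding_other`. Non-monotone positions within a contig raise a parse
#'   error naming the offending line.
#' @export
read_variants <- function(path, sample_id) {
  first <- readLines(path, n = 5000L)
  if (!any(!startsWith(first, "#")))
    return(variant_table(character(), character(), integer(), character(),
                         character()))
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e)))
  n_header <- sum(startsWith(readLines(path, n = 5000L), "#"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0)
    return(variant_table(character(), character(), integer(), character(),
                         character()))
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  for (ctg in unique(contig)) {
    p <- pos[contig == ctg]
    if (is.unsorted(p)) {
      i <- which(contig == ctg)[which(diff(p) < 0)[1] + 1L]
      stop("non-monotone position on ", ctg, " at line ", n_header + i,
           " of ", path)
    }
  }
  alt_l <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_l)
  idx <- rep(seq_along(rr), n_alt)
  info <- VariantAnnotation::info(vcf)
  eff <- if ("EFFECT" %in% names(info)) as.character(info$EFFECT) else
    rep(NA_character_, length(rr))
  eff[is.na(eff)] <- "noncoding_other"
  gene <- if ("GENE" %in% names(info)) as.character(info$GENE) else
    rep(NA_character_, length(rr))
  germ <- if ("GERMLINE" %in% names(info)) as.logical(info$GERMLINE) else
    rep(FALSE, length(rr))
  g <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  pick <- function(field, col) {
    if (!field %in% names(g) || !col %in% samples)
      return(rep(NA_integer_, length(rr)))
    x <- g[[field]][, col]
    if (field == "AD")
      vapply(x, function(a) if (length(a) >= 2 && !all(is.na(a)))
        as.integer(a[2]) else NA_integer_, 0L)
    else as.integer(unlist(x))
  }
  t_alt <- pick("AD", "TUMOR");  t_dp <- pick("DP", "TUMOR")
  c_alt <- pick("AD", "CONTROL"); c_dp <- pick("DP", "CONTROL")
  variant_table(sample = sample_id, contig = contig[idx], pos = pos[idx],
                ref = as.character(VariantAnnotation::ref(vcf))[idx],
                alt = as.character(unlist(alt_l)),
                effect = eff[idx], gene = gene[idx],
                t_alt = t_alt[idx], t_dp = t_dp[idx],
                c_alt = c_alt[idx], c_dp = c_dp[idx],
                germline = germ[idx])
}

## ---- gene models ----------------------------------------------------------

#' Read gene models from a GTF subset or an extended BED
#'
#' GTF `gene` features (1-based inclusive) are converted to the internal
#' 0-based half-open convention; exonic length is the sum of `exon` feature
#' widths when present, else the gene width. The BED dialect uses columns
#' chrom, start, end, name, score, strand, biotype and optionally exonic
#' length and symbol.
#'
#' @param path `.gtf` or `.bed` file.
#' @return data frame with columns `gene_id`, `symbol`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `biotype`, `exon_len`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    genes <- gr[gr$type == "gene"]
    ex <- gr[gr$type == "exon"]
    exlen <- tapply(GenomicRanges::width(ex), ex$gene_id, sum)
    df <- data.frame(
      gene_id = genes$gene_id,
      symbol = if (!is.null(genes$gene_name)) genes$gene_name else genes$gene_id,
      contig = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes) - 1L,
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      biotype = if (!is.null(genes$gene_type)) genes$gene_type else "other",
      stringsAsFactors = FALSE)
    df$exon_len <- ifelse(df$gene_id %in% names(exlen),
                          as.integer(exlen[df$gene_id]), df$end - df$start)
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 7) stop("BED gene models need >= 7 columns")
    df <- data.frame(gene_id = raw[[4]],
                     symbol = if (ncol(raw) >= 9) raw[[9]] else raw[[4]],
                     contig = as.character(raw[[1]]),
                     start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
                     strand = raw[[6]], biotype = raw[[7]],
                     exon_len = if (ncol(raw) >= 8) as.integer(raw[[8]])
                                else as.integer(raw[[3]]) - as.integer(raw[[2]]),
                     stringsAsFactors = FALSE)
  }
  bad <- df$start >= df$end
  if (any(bad)) {
    warning(sum(bad), " gene record(s) rejected (start >= end)")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  df$biotype[!df$biotype %in% BIOTYPES] <- "other"
  if (any(df$exon_len < 1)) stop("exonic length must be >= 1")
  rownames(df) <- NULL
  df
}

#' Write gene models in the extended BED dialect read by [read_gene_models()]
#' @param genes gene-model data frame.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(genes$contig, genes$start, genes$end, genes$gene_id, 0L,
                    genes$strand, genes$biotype, genes$exon_len, genes$symbol)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## ---- copy-number segments -------------------------------------------------

#' Read allele-specific copy-number segments
#'
#' @param path TSV with header `sample chrom start end tcn A B`
#'   (start/end 0-based half-open).
#' @return data frame sorted by sample, contig, start. Overlapping segments
#'   within one sample and contig raise an error naming the pair.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "tcn", "A", "B")
  if (!all(need %in% names(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  seg <- data.frame(sample = as.character(df$sample),
                    contig = as.character(df$chrom),
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    tcn = as.numeric(df$tcn), A = as.numeric(df$A),
                    B = as.numeric(df$B), stringsAsFactors = FALSE)
  validate_segments(seg)
}

validate_segments <- function(seg) {
  if (any(seg$end - seg$start < 1)) stop("segment length must be >= 1")
  if (any(seg$tcn < 0 | seg$A < 0 | seg$B < 0))
    stop("copy numbers must be >= 0")
  if (any(abs(seg$A + seg$B - seg$tcn) > 0.75))
    stop("A + B deviates from tcn by more than 0.75")
  seg <- seg[order(seg$sample, seg$contig, seg$start), , drop = FALSE]
  key <- paste(seg$sample, seg$contig)
  for (k in unique(key)) {
    s <- seg[key == k, , drop = FALSE]
    ov <- which(s$start[-1] < s$end[-nrow(s)])
    if (length(ov))
      stop("overlapping segments in ", k, ": [", s$start[ov[1]], ",",
           s$end[ov[1]], ") and [", s$start[ov[1] + 1], ",",
           s$end[ov[1] + 1], ")")
  }
  rownames(seg) <- NULL
  seg
}

#' Write copy-number segments in the schema read by [read_segments()]
#' @param seg segment data frame.
#' @param path output file.
#' @export
write_segments <- function(seg, path) {
  out <- data.frame(sample = seg$sample, chrom = seg$contig,
                    start = seg$start, end = seg$end,
                    tcn = seg$tcn, A = seg$A, B = seg$B)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- structural variants --------------------------------------------------

#' Read structural-variant breakpoint pairs from BEDPE
#'
#' Columns chrom1, start1, end1, chrom2, start2, end2, name, score, strand1,
#' strand2, svclass; positions are taken as start + 1 (1-based breakpoint).
#'
#' @param path BEDPE file (no header).
#' @param sample_id sample id stamped on each record, or `NA` to take it from
#'   the name column.
#' @return data frame `sample, contig1, pos1, contig2, pos2, svclass`.
#' @export
read_bedpe <- function(path, sample_id = NA) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 11) stop("BEDPE needs 11 columns")
  sv <- data.frame(
    sample = if (is.na(sample_id)) as.character(raw[[7]]) else sample_id,
    contig1 = as.character(raw[[1]]), pos1 = as.integer(raw[[2]]) + 1L,
    contig2 = as.character(raw[[4]]), pos2 = as.integer(raw[[5]]) + 1L,
    svclass = as.character(raw[[11]]), stringsAsFactors = FALSE)
  validate_svs(sv)
}

validate_svs <- function(sv) {
  if (any(!sv$svclass %in% SV_CLASSES))
    stop("unknown SV class: ",
         paste(setdiff(sv$svclass, SV_CLASSES), collapse = ", "))
  inter <- sv$contig1 != sv$contig2
  if (any(inter != (sv$svclass == "translocation")))
    stop("translocation class must coincide with inter-contig breakpoints")
  bad <- !inter & sv$pos1 >= sv$pos2
  if (any(bad)) stop("intra-contig SV with pos1 >= pos2 at row(s) ",
                     paste(which(bad), collapse = ", "))
  sv
}

#' Write breakpoint pairs as BEDPE
#' @param sv structural-variant data frame.
#' @param path output file.
#' @export
write_bedpe <- function(sv, path) {
  out <- data.frame(sv$contig1, sv$pos1 - 1L, sv$pos1, sv$contig2,
                    sv$pos2 - 1L, sv$pos2, sv$sample, 0L, "+", "+", sv$svclass)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## ---- matrices and sequences ----------------------------------------------

#' Read a gene-by-sample counts (or expression) matrix from TSV
#' @param path TSV whose first column holds gene ids and whose header names
#'   the samples.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a gene-by-sample matrix as TSV
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_col header for the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genome sequences as FASTA
#' @param genome a [genome_ref()] with sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeRef"), !is.null(genome$sequences))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequences[names(genome$contigs)]), path)
  invisible(path)
}

#' Read genome sequences from FASTA into a [genome_ref()]
#' @param path FASTA file.
#' @param arms optional arm table.
#' @export
read_genome_fasta <- function(path, arms = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  genome_ref(contigs = stats::setNames(Biostrings::width(ss), names(ss)),
             sequences = seqs, arms = arms)
}

#' Write reads as FASTQ
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ into a named character vector of sequences
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(ss)), names(ss))
}
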