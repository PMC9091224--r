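#' Genome reference for a cohort analysis
#'
#' Bundles contig lengths, contig sequences and a chromosome-arm table into
#' the shared coordinate model used by every stage. All internal coordinates
#' are 0-based half-open; converters to the 1-based inclusive conventions of
#' VCF/GTF live only at the I/O boundary.
#'
#' @param contigs named numeric vector of contig lengths in bp, in display
#'   order.
#' @param sequences named character vector of uppercase DNA sequences, one per
#'   contig, or `NULL` when sequence context is not needed.
#' @param arms data frame with columns `contig`, `arm` (`"p"` or `"q"`),
#'   `start`, `end` (0-based half-open). The p and q intervals of a contig
#'   must be disjoint and lie within the contig; a centromere gap between
#'   them is allowed.
#' @return an object of class `GenomeRef`.
#' @export
genome_ref <- function(contigs, sequences = NULL, arms = NULL) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must be a uniquely named vector of lengths")
  contigs <- vapply(contigs, as.numeric, 0)
  if (any(contigs < 1)) stop("contig lengths must be >= 1")
  if (!is.null(sequences)) {
    missing <- setdiff(names(contigs), names(sequences))
    if (length(missing))
      stop("sequences missing for contigs: ", paste(missing, collapse = ", "))
    bad <- names(contigs)[nchar(sequences[names(contigs)]) != contigs]
    if (length(bad))
      stop("sequence length disagrees with contig length for: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(arms)) {
    stopifnot(all(c("contig", "arm", "start", "end") %in% names(arms)))
    for (ctg in unique(arms$contig)) {
      if (!ctg %in% names(contigs))
        stop("arm table references unknown contig: ", ctg)
      a <- arms[arms$contig == ctg, , drop = FALSE]
      if (any(a$start < 0) || any(a$end > contigs[[ctg]]) ||
          any(a$start >= a$end))
        stop("arm interval outside contig ", ctg)
      if (nrow(a) == 2) {
        a <- a[order(a$start), ]
        if (a$end[1] > a$start[2]) stop("p and q arms overlap on ", ctg)
      }
    }
  }
  structure(list(contigs = contigs, sequences = sequences, arms = arms),
            class = "GenomeRef")
}

#' Extract reference sequence for an interval
#'
#' @param genome a [genome_ref()] object carrying sequences.
#' @param contig contig name (exact match; no prefix normalization).
#' @param start,end 0-based half-open interval.
#' @return uppercase DNA string of length `end - start`.
#' @export
genome_seq <- function(genome, contig, start, end) {
  stopifnot(inherits(genome, "GenomeRef"))
  if (is.null(genome$sequences)) stop("genome carries no sequences")
  if (!contig %in% names(genome$contigs)) stop("unknown contig: ", contig)
  if (start < 0 || end > genome$contigs[[contig]] || start >= end)
    stop("interval [", start, ",", end, ") outside contig ", contig)
  substr(genome$sequences[[contig]], start + 1L, end)
}

#' @export
print.GenomeRef <- function(x, ...) {
  cat("GenomeRef:", length(x$contigs), "contig(s),",
      format(sum(x$contigs), big.mark = ","), "bp total;",
      if (is.null(x$sequences)) "no sequence;" else "with sequence;",
      if (is.null(x$arms)) "no arm table\n" else "with arm table\n")
  invisible(x)
}

#' Arm interval lookup
#'
#' @param genome a [genome_ref()] object with an arm table.
#' @return data frame of arm definitions (`contig`, `arm`, `start`, `end`).
#' @export
genome_arms <- function(genome) {
  stopifnot(inherits(genome, "GenomeRef"))
  if (is.null(genome$arms)) stop("genome carries no arm table")
  genome$arms
}

# reverse complement of an uppercase DNA string (vectorized)
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), ""))
}
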