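# the four most common telomeric repeat types and their reverse complements
TELOMERE_REPEATS <- c("TTAGGG", "TCAGGG", "TGAGGG", "TTGGGG")

#' Scan reads for telomeric repeat content
#'
#' A read is eligible when it is unmapped or its mapping quality is below
#' `max_mapq` (all reads are eligible when no mapping information is
#' given). An eligible read of length L is telomeric when the number of
#' non-overlapping occurrences (greedy, left to right) of the four common
#' telomeric repeat types or their reverse complements reaches
#' `round(threshold_per_100bp * L / 100)` (half rounds up). The GC-matched
#' denominator counts all reads (regardless of eligibility) whose GC
#' percentage lies in `[gc_low, gc_high]` inclusive.
#'
#' @param reads character vector of read sequences (length >= 30 each).
#' @param mapq optional numeric vector of mapping qualities (NA = unmapped).
#' @param threshold_per_100bp repeat occurrences required per 100 bp
#'   (default 6).
#' @param max_mapq mapping-quality bound for eligibility (default 8,
#'   exclusive).
#' @param gc_low,gc_high inclusive GC% bounds for the denominator
#'   (default 48-52).
#' @return list `n_telomeric`, `n_gc_matched`, `n_total`, plus the logical
#'   vectors `telomeric` and `gc_matched`.
#' @export
scan_telomeric_reads <- function(reads, mapq = NULL,
                                 threshold_per_100bp = 6, max_mapq = 8,
                                 gc_low = 48, gc_high = 52) {
  if (!length(reads)) stop("empty read set")
  L <- nchar(reads)
  if (any(L < 30)) stop("reads must be at least 30 bp")
  eligible <- if (is.null(mapq)) rep(TRUE, length(reads))
              else is.na(mapq) | mapq < max_mapq
  pat <- paste(c(TELOMERE_REPEATS, revcomp(TELOMERE_REPEATS)),
               collapse = "|")
  hits <- integer(length(reads))
  idx <- which(eligible)
  if (length(idx)) {
    m <- gregexpr(pat, reads[idx])
    hits[idx] <- vapply(m, function(x) sum(x[1] != -1L, length(x) - 1L), 0L)
  }
  need <- floor(threshold_per_100bp * L / 100 + 0.5)
  telomeric <- eligible & hits >= need
  gc <- vapply(strsplit(reads, ""), function(b)
    sum(b %in% c("G", "C")), 0L) / L * 100
  gc_matched <- gc >= gc_low & gc <= gc_high
  list(n_telomeric = sum(telomeric), n_gc_matched = sum(gc_matched),
       n_total = length(reads), telomeric = telomeric,
       gc_matched = gc_matched)
}

#' Telomere content: telomeric reads per million GC-matched reads
#' @param tel telomeric read count.
#' @param gc GC-matched read count (> 0).
#' @export
telomere_content <- function(tel, gc) {
  if (gc <= 0) stop("GC-matched read count must be positive")
  tel / gc * 1e6
}

#' Tumor-cell-content correction of telomere content
#'
#' Removes the contribution of admixed non-malignant cells, assuming they
#' share the control sample's telomere content:
#' `T_corrected = (T - C * (1 - TCC)) / TCC`. The result can be negative
#' when the tumor content is below the control expectation; it is returned
#' as-is with a `negative` attribute flag.
#'
#' @param T_content tumor telomere content (per million GC-matched reads).
#' @param C_content control telomere content (same units).
#' @param tcc tumor cell content in `(0, 1]`.
#' @export
tcc_correct <- function(T_content, C_content, tcc) {
  if (any(tcc <= 0 | tcc > 1)) stop("TCC must lie in (0, 1]")
  out <- (T_content - C_content * (1 - tcc)) / tcc
  attr(out, "negative") <- out < 0
  out
}

#' Correlate telomere content with the expression of one gene
#'
#' @param contents named numeric vector of (corrected) telomere contents.
#' @param expression named numeric vector of the gene's expression, same
#'   samples.
#' @return list `r`, `p`, `n` (Pearson, two-sided t-based p, no
#'   multiple-testing correction).
#' @export
correlate_with_expression <- function(contents, expression) {
  common <- intersect(names(contents), names(expression))
  if (length(common) < 3) stop("need at least 3 paired samples")
  x <- contents[common]; y <- expression[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in contents or expression")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
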