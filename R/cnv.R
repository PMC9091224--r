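#' Parameters of the segment-smoothing cascade
#'
#' Stage 1 merges neighboring segments that round to the same copy-number
#' state — the rounded minor/major allele copy numbers (and hence the total)
#' agree — and whose totals deviate by less than `d1` copies when the
#' smaller is shorter than `l1`, else by less than `d2`. Matching the
#' rounded allele pair rather than the total alone keeps copy-neutral LOH
#' boundaries intact. Stage 2 merges every segment shorter than
#' `l2` with its closer neighbor. Stage 3 merges segments shorter than `l3`
#' deviating by less than `d3` copies from a neighbor.
#'
#' @param l1 small-segment length bound for stage 1 (bp).
#' @param d1 copy-number deviation bound applied below `l1`.
#' @param d2 deviation bound applied otherwise in stage 1.
#' @param l2 length bound below which stage 2 forces a merge (bp).
#' @param l3 length bound for stage 3 (bp).
#' @param d3 deviation bound for stage 3.
#' @export
smoothing_params <- function(l1 = 20e3, d1 = 0.5, d2 = 0.3, l2 = 500e3,
                             l3 = 2e6, d3 = 0.4) {
  p <- list(l1 = l1, d1 = d1, d2 = d2, l2 = l2, l3 = l3, d3 = d3)
  if (any(unlist(p) <= 0)) stop("all smoothing bounds must be positive")
  structure(p, class = "SmoothingParams")
}

# round half away from zero: 2.5 -> 3, -2.5 -> -3
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# L1 distance over (tcn, A, B) between two segment rows
seg_distance <- function(s, i, j) {
  abs(s$tcn[i] - s$tcn[j]) + abs(s$A[i] - s$A[j]) + abs(s$B[i] - s$B[j])
}

# merge rows i and i+1 of a sorted segment frame: interval union,
# length-weighted mean copy numbers
merge_pair <- function(s, i) {
  w1 <- s$end[i] - s$start[i]; w2 <- s$end[i + 1] - s$start[i + 1]
  for (f in c("tcn", "A", "B"))
    s[[f]][i] <- (w1 * s[[f]][i] + w2 * s[[f]][i + 1]) / (w1 + w2)
  s$end[i] <- s$end[i + 1]
  s[-(i + 1), , drop = FALSE]
}

#' Smooth copy-number segments of one sample and contig
#'
#' Applies the three-stage merging cascade. Within a stage the leftmost
#' applicable merge is applied first and the scan restarts; the cascade of
#' the three stages then repeats until a global fixed point, so the result
#' is idempotent and independent of traversal details. Merged segments take
#' the
#' length-weighted mean of total and allele-specific copy numbers and the
#' union of the intervals, so covered length and the length-weighted mean
#' copy number are conserved exactly.
#'
#' @param seg data frame of non-overlapping sorted segments for one sample
#'   and contig (columns `start`, `end`, `tcn`, `A`, `B`; extra columns such
#'   as `sample`/`contig` are carried through from the first member).
#' @param params a [smoothing_params()] object.
#' @return smoothed segment data frame.
#' @export
smooth_segments <- function(seg, params = smoothing_params()) {
  stopifnot(inherits(params, "SmoothingParams"))
  if (nrow(seg) <= 1) return(seg)
  if (length(unique(seg$contig)) > 1 || length(unique(seg$sample)) > 1)
    stop("smooth_segments operates on one sample and contig at a time")
  seg <- seg[order(seg$start), , drop = FALSE]
  if (any(seg$start[-1] < seg$end[-nrow(seg)]))
    stop("overlapping input segments")

  # the merge order is part of the contract: within each stage the LEFTMOST
  # applicable merge is applied first and the scan restarts, until no merge
  # applies; the three-stage cascade then repeats until a global fixpoint
  # (a stage-2/3 merge can create a pair stage 1 would merge), which makes
  # the result implementation-independent and idempotent
  repeat {
  n_before <- nrow(seg)

  # stage 1: same rounded copy number and small deviation
  repeat {
    at <- NA_integer_
    for (i in seq_len(nrow(seg) - 1L)) {
      len_min <- min(seg$end[i] - seg$start[i],
                     seg$end[i + 1] - seg$start[i + 1])
      dbound <- if (len_min < params$l1) params$d1 else params$d2
      st <-
        round_half_away(pmin(seg$A[i], seg$B[i])) ==
          round_half_away(pmin(seg$A[i + 1], seg$B[i + 1])) &&
        round_half_away(pmax(seg$A[i], seg$B[i])) ==
          round_half_away(pmax(seg$A[i + 1], seg$B[i + 1]))
      if (st &&
          round_half_away(seg$tcn[i]) == round_half_away(seg$tcn[i + 1]) &&
          abs(seg$tcn[i] - seg$tcn[i + 1]) < dbound) { at <- i; break }
    }
    if (is.na(at)) break
    seg <- merge_pair(seg, at)
  }

  # stage 2: short segments merge with the closer neighbor
  # (L1 distance over tcn/A/B; ties go left)
  while (nrow(seg) > 1) {
    at <- NA_integer_
    for (i in seq_len(nrow(seg))) {
      if (seg$end[i] - seg$start[i] >= params$l2) next
      dl <- if (i > 1) seg_distance(seg, i, i - 1) else Inf
      dr <- if (i < nrow(seg)) seg_distance(seg, i, i + 1) else Inf
      at <- if (dl <= dr) i - 1L else i
      break
    }
    if (is.na(at)) break
    seg <- merge_pair(seg, at)
  }

  # stage 3: sub-l3 segments deviating by < d3 from the closer neighbor of
  # the same rounded allele state
  same_state <- function(i, j)
    round_half_away(pmin(seg$A[i], seg$B[i])) ==
      round_half_away(pmin(seg$A[j], seg$B[j])) &&
    round_half_away(pmax(seg$A[i], seg$B[i])) ==
      round_half_away(pmax(seg$A[j], seg$B[j]))
  while (nrow(seg) > 1) {
    at <- NA_integer_
    for (i in seq_len(nrow(seg))) {
      if (seg$end[i] - seg$start[i] >= params$l3) next
      dl <- if (i > 1 && same_state(i, i - 1))
        abs(seg$tcn[i] - seg$tcn[i - 1]) else Inf
      dr <- if (i < nrow(seg) && same_state(i, i + 1))
        abs(seg$tcn[i] - seg$tcn[i + 1]) else Inf
      if (dl <= dr && dl < params$d3) { at <- i - 1L; break }
      if (dr < dl && dr < params$d3) { at <- i; break }
    }
    if (is.na(at)) break
    seg <- merge_pair(seg, at)
  }

  if (nrow(seg) == n_before) break
  }
  rownames(seg) <- NULL
  seg
}

#' Smooth all segments of a cohort, sample by sample and contig by contig
#' @param seg cohort segment data frame (with `sample` and `contig`).
#' @param params a [smoothing_params()].
#' @export
smooth_cohort_segments <- function(seg, params = smoothing_params()) {
  parts <- split(seg, list(seg$sample, seg$contig), drop = TRUE)
  out <- do.call(rbind, lapply(parts, smooth_segments, params = params))
  out <- out[order(out$sample, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count gained and lost segments relative to sample ploidy
#'
#' A segment is a gain when its rounded total copy number exceeds the
#' rounded ploidy and a loss when it falls below it.
#'
#' @param seg smoothed segments of one sample.
#' @param ploidy sample ploidy (> 0).
#' @return named vector `c(n_gain, n_loss)`.
#' @export
count_gains_losses <- function(seg, ploidy) {
  if (ploidy <= 0) stop("ploidy must be positive")
  r <- round_half_away(seg$tcn); rp <- round_half_away(ploidy)
  c(n_gain = sum(r > rp), n_loss = sum(r < rp))
}

#' Call chromosome-arm-level copy-number events
#'
#' Per arm (or per whole chromosome with `level = "chromosome"`), the
#' altered fraction is the covered proportion classified as gain, loss or
#' copy-neutral LOH; an event is emitted when the fraction exceeds 0.30
#' (strictly). cnLOH means the minor allele rounds to 0 while the rounded
#' total matches the rounded ploidy.
#'
#' @param seg smoothed segments of one sample.
#' @param genome a [genome_ref()] with an arm table.
#' @param ploidy sample ploidy.
#' @param level `"arm"` (default) or `"chromosome"`.
#' @param min_fraction event threshold (strict), default 0.30.
#' @return data frame `contig, arm, event, fraction` (events only).
#' @export
call_arm_events <- function(seg, genome, ploidy, level = c("arm", "chromosome"),
                            min_fraction = 0.30) {
  level <- match.arg(level)
  arms <- genome_arms(genome)
  miss <- setdiff(unique(seg$contig), arms$contig)
  if (length(miss))
    stop("no arm definition for contig(s): ", paste(miss, collapse = ", "))
  if (level == "chromosome") {
    arms <- do.call(rbind, lapply(split(arms, arms$contig), function(a)
      data.frame(contig = a$contig[1], arm = "chrom", start = min(a$start),
                 end = max(a$end), stringsAsFactors = FALSE)))
  }
  rp <- round_half_away(ploidy)
  r <- round_half_away(seg$tcn)
  is_gain <- r > rp
  is_loss <- r < rp
  is_cnloh <- round_half_away(pmin(seg$A, seg$B)) == 0 & r == rp
  out <- list()
  for (k in seq_len(nrow(arms))) {
    a <- arms[k, ]
    on <- seg$contig == a$contig
    cov <- pmax(0, pmin(seg$end[on], a$end) - pmax(seg$start[on], a$start))
    alen <- a$end - a$start
    for (ev in c("gain", "loss", "cnLOH")) {
      sel <- switch(ev, gain = is_gain, loss = is_loss, cnLOH = is_cnloh)[on]
      frac <- sum(cov[sel]) / alen
      if (frac > min_fraction)
        out[[length(out) + 1L]] <- data.frame(
          contig = a$contig, arm = a$arm, event = ev, fraction = frac,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), arm = character(),
                      event = character(), fraction = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of aberrant genome
#'
#' The proportion of the covered genome whose total copy number deviates
#' from the ploidy by more than 0.7 copies, or that is in loss of
#' heterozygosity (minor allele below 0.5 while total at least 0.5).
#'
#' @param seg smoothed segments of one sample covering the analyzable
#'   genome.
#' @param ploidy sample ploidy.
#' @return fraction in `[0, 1]`.
#' @export
fraction_aberrant_genome <- function(seg, ploidy) {
  len <- seg$end - seg$start
  total <- sum(len)
  if (total <= 0) stop("zero total segment length")
  aberrant <- abs(seg$tcn - ploidy) > 0.7 |
    (pmin(seg$A, seg$B) < 0.5 & seg$tcn >= 0.5)
  sum(len[aberrant]) / total
}
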