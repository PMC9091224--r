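# independent oracles kept deliberately naive: they re-derive expectations
# by enumeration or by a second, plainly-written implementation

# kataegis: enumerate every window of >= min_snvs consecutive sorted sites,
# keep those with mean gap <= max_imd, union overlapping index intervals
# via IRanges::reduce
oracle_hotspots <- function(pos, min_snvs = 6, max_imd = 1000) {
  p <- sort(unique(pos))
  n <- length(p)
  wins <- list()
  if (n >= min_snvs)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i + 1 < min_snvs) next
      if ((p[j] - p[i]) / (j - i) <= max_imd)
        wins[[length(wins) + 1L]] <- c(i, j)
    }
  if (!length(wins))
    return(data.frame(start = integer(), end = integer(),
                      n_snvs = integer(), mean_imd = numeric()))
  ir <- IRanges::reduce(IRanges::IRanges(
    start = vapply(wins, `[`, 0, 1), end = vapply(wins, `[`, 0, 2)))
  data.frame(start = p[IRanges::start(ir)] - 1L, end = p[IRanges::end(ir)],
             n_snvs = IRanges::end(ir) - IRanges::start(ir) + 1L,
             mean_imd = (p[IRanges::end(ir)] - p[IRanges::start(ir)]) /
               (IRanges::end(ir) - IRanges::start(ir)))
}

# two-sided Fisher by full hypergeometric enumeration with the
# point-probability rule (same 1e-7 relative tie tolerance R uses)
oracle_fisher_two_sided <- function(k_a, n_a, k_b, n_b) {
  m <- k_a + k_b
  lo <- max(0, m - n_b); hi <- min(m, n_a)
  d <- stats::dhyper(lo:hi, n_a, n_b, m)
  sum(d[d <= stats::dhyper(k_a, n_a, n_b, m) * (1 + 1e-7)])
}

# smoothing cascade: a second straightforward implementation that restarts
# the scan from the beginning after every single merge
oracle_smooth <- function(seg, params = smoothing_params()) {
  rha <- function(x) sign(x) * floor(abs(x) + 0.5)
  len <- function(s, i) s$end[i] - s$start[i]
  fuse <- function(s, i) {
    w1 <- len(s, i); w2 <- len(s, i + 1)
    s$tcn[i] <- (w1 * s$tcn[i] + w2 * s$tcn[i + 1]) / (w1 + w2)
    s$A[i] <- (w1 * s$A[i] + w2 * s$A[i + 1]) / (w1 + w2)
    s$B[i] <- (w1 * s$B[i] + w2 * s$B[i + 1]) / (w1 + w2)
    s$end[i] <- s$end[i + 1]
    s[-(i + 1), , drop = FALSE]
  }
  s <- seg[order(seg$start), , drop = FALSE]
  repeat {
  n0 <- nrow(s)
  # stage 1
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(s) - 1)) {
      bound <- if (min(len(s, i), len(s, i + 1)) < params$l1) params$d1
               else params$d2
      if (rha(min(s$A[i], s$B[i])) == rha(min(s$A[i + 1], s$B[i + 1])) &&
          rha(max(s$A[i], s$B[i])) == rha(max(s$A[i + 1], s$B[i + 1])) &&
          rha(s$tcn[i]) == rha(s$tcn[i + 1]) &&
          abs(s$tcn[i] - s$tcn[i + 1]) < bound) {
        s <- fuse(s, i); done <- FALSE; break
      }
    }
    if (done) break
  }
  # stage 2
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(s))) {
      if (nrow(s) < 2) break
      if (len(s, i) >= params$l2) next
      d_of <- function(j) abs(s$tcn[i] - s$tcn[j]) + abs(s$A[i] - s$A[j]) +
        abs(s$B[i] - s$B[j])
      dl <- if (i > 1) d_of(i - 1) else Inf
      dr <- if (i < nrow(s)) d_of(i + 1) else Inf
      s <- fuse(s, if (dl <= dr) i - 1L else i)
      done <- FALSE; break
    }
    if (done) break
  }
  # stage 3
  repeat {
    done <- TRUE
    same <- function(i, j)
      rha(min(s$A[i], s$B[i])) == rha(min(s$A[j], s$B[j])) &&
      rha(max(s$A[i], s$B[i])) == rha(max(s$A[j], s$B[j]))
    for (i in seq_len(nrow(s))) {
      if (nrow(s) < 2) break
      if (len(s, i) >= params$l3) next
      dl <- if (i > 1 && same(i, i - 1)) abs(s$tcn[i] - s$tcn[i - 1]) else Inf
      dr <- if (i < nrow(s) && same(i, i + 1)) abs(s$tcn[i] - s$tcn[i + 1])
            else Inf
      at <- if (dl <= dr && dl < params$d3) i - 1L
            else if (dr < dl && dr < params$d3) i else NA
      if (is.na(at)) next
      s <- fuse(s, at); done <- FALSE; break
    }
    if (done) break
  }
  if (nrow(s) == n0) break
  }
  rownames(s) <- NULL
  s
}

# random segment chain for cascade comparisons
random_chain <- function(n, seed) {
  set.seed(seed)
  bounds <- sort(sample.int(5e7, n + 1))
  tcn <- pmax(0, 2 + stats::rnorm(n, 0, 0.8))
  B <- pmin(tcn, pmax(0, tcn / 2 + stats::rnorm(n, 0, 0.2)))
  data.frame(sample = "s1", contig = "chr1",
             start = head(bounds, -1), end = tail(bounds, -1),
             tcn = tcn, A = tcn - B, B = B, stringsAsFactors = FALSE)
}
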