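seg_row <- function(start, end, tcn, A = tcn / 2, B = tcn / 2,
                    sample = "s1", contig = "chr1")
  data.frame(sample = sample, contig = contig, start = start, end = end,
             tcn = tcn, A = A, B = B, stringsAsFactors = FALSE)

test_that("stage-1 merge reproduces the hand-traced weighted mean", {
  seg <- rbind(seg_row(0, 1e4, 2.2, 1.2, 1.0),
               seg_row(1e4, 3e4, 2.4, 1.4, 1.0))
  out <- smooth_segments(seg)
  expect_equal(nrow(out), 1)
  expect_equal(out$tcn, (1 / 3) * 2.2 + (2 / 3) * 2.4, tolerance = 1e-12)
  expect_equal(c(out$start, out$end), c(0, 3e4))
})

test_that("well-separated long segments never merge", {
  seg <- rbind(seg_row(0, 5e6, 2.0), seg_row(5e6, 1e7, 3.0))
  expect_equal(smooth_segments(seg), seg, ignore_attr = TRUE)
  single <- seg_row(0, 1e6, 2.5)
  expect_equal(smooth_segments(single), single, ignore_attr = TRUE)
})

test_that("cascade equals an independent re-implementation and is
          idempotent on random chains", {
  for (seed in 1:200) {
    seg <- random_chain(sample(5:50, 1), seed = seed)
    a <- smooth_segments(seg)
    b <- oracle_smooth(seg)
    expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE,
                 label = paste("seed", seed))
    expect_equal(smooth_segments(a), a, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("merging conserves covered length and mean copy number", {
  for (seed in c(3, 17, 99)) {
    seg <- random_chain(40, seed = seed)
    out <- smooth_segments(seg)
    expect_equal(sum(out$end - out$start), sum(seg$end - seg$start))
    expect_equal(sum((out$end - out$start) * out$tcn),
                 sum((seg$end - seg$start) * seg$tcn),
                 tolerance = 1e-9 * sum((seg$end - seg$start) * seg$tcn))
  }
})

test_that("overlapping input is rejected", {
  seg <- rbind(seg_row(0, 100, 2), seg_row(50, 150, 2))
  expect_error(smooth_segments(seg), "overlap")
})

test_that("gain/loss counting rounds against ploidy", {
  expect_equal(count_gains_losses(seg_row(0, 1e6, 3.1), 2),
               c(n_gain = 1L, n_loss = 0L))
  expect_equal(count_gains_losses(seg_row(0, 1e6, 2.0), 2),
               c(n_gain = 0L, n_loss = 0L))
  seg <- rbind(seg_row(0, 1e6, 1, 0.5, 0.5), seg_row(1e6, 2e6, 2),
               seg_row(2e6, 3e6, 4, 2, 2))
  expect_equal(count_gains_losses(seg, 2), c(n_gain = 1L, n_loss = 1L))
  expect_error(count_gains_losses(seg, 0), "positive")
})

test_that("arm events require strictly more than 30% of the arm", {
  g <- tiny_genome(strrep("ACGT", 2500))  # 10 kb, q arm 4500..10000
  # gain over 40% of the q arm
  seg <- rbind(seg_row(4500, 4500 + 0.4 * 5500, 3, 2, 1),
               seg_row(4500 + 0.4 * 5500, 10000, 2))
  ev <- call_arm_events(seg, g, ploidy = 2)
  expect_equal(ev$event, "gain")
  expect_equal(ev$fraction, 0.4, tolerance = 1e-9)
  # exactly 30% is not an event
  seg30 <- rbind(seg_row(4500, 4500 + 0.3 * 5500, 3, 2, 1),
                 seg_row(4500 + 0.3 * 5500, 10000, 2))
  expect_equal(nrow(call_arm_events(seg30, g, ploidy = 2)), 0)
  # copy-neutral LOH: minor allele rounds to zero at ploidy total
  segl <- seg_row(4500, 4500 + 0.5 * 5500, 2, 2, 0)
  evl <- call_arm_events(segl, g, ploidy = 2)
  expect_equal(evl$event, "cnLOH")
  expect_error(call_arm_events(transform(segl, contig = "chrZ"), g, 2),
               "arm definition")
})

test_that("fraction of aberrant genome follows the 0.7/LOH rule", {
  balanced <- seg_row(0, 1e6, 2)
  expect_equal(fraction_aberrant_genome(balanced, 2), 0)
  gained <- seg_row(0, 1e6, 3, 1.5, 1.5)
  expect_equal(fraction_aberrant_genome(gained, 2), 1)
  half <- rbind(seg_row(0, 1e6, 2.8, 1.4, 1.4), seg_row(1e6, 2e6, 2))
  expect_equal(fraction_aberrant_genome(half, 2), 0.5)
  # LOH counts even at neutral total copy number
  loh <- rbind(seg_row(0, 1e6, 2, 2, 0), seg_row(1e6, 2e6, 2))
  expect_equal(fraction_aberrant_genome(loh, 2), 0.5)
  expect_error(fraction_aberrant_genome(balanced[0, ], 2), "zero total")
})

test_that("implanted arm events are recovered and quiet arms stay quiet", {
  # full-length arms: the smoothing length bounds (500 kb / 2 Mb) are
  # genome-scale quantities, so this check runs on 10 Mb contigs
  b <- simulate_cohort(small_spec(
    seed = 8, snv_rate_per_mb = 1,
    genome = list(n_contigs = 2, contig_length = 1e7, arm_split = 0.45,
                  gc = 0.5),
    cnv = list(ploidy = 2, tcc_range = c(0.5, 0.95), arm_gain_prob = 0.25,
               arm_loss_prob = 0.25, arm_cnloh_prob = 0.15,
               arm_fraction_range = c(0.4, 1), focal_per_sample = 2,
               focal_length_range = c(3e5, 1e6), jitter_sd = 0.05,
               extra_breakpoints = 4)))
  smoothed <- smooth_cohort_segments(b$segments)
  truth <- b$truth$arm_events
  skip_if(is.null(truth), "no arm events implanted at this seed")
  for (i in seq_len(nrow(truth))) {
    if (truth$fraction[i] <= 0.35) next
    sm <- truth$sample[i]
    ev <- call_arm_events(smoothed[smoothed$sample == sm, ], b$genome,
                          ploidy = 2)
    hit <- any(ev$contig == truth$contig[i] & ev$arm == truth$arm[i] &
                 ev$event == truth$event[i])
    expect_true(hit, label = paste("implant", i))
  }
  # arms without an implanted event yield none (focal events are too small)
  for (sm in b$meta$sample) {
    ev <- call_arm_events(smoothed[smoothed$sample == sm, ], b$genome,
                          ploidy = 2)
    if (nrow(ev) == 0) next
    for (j in seq_len(nrow(ev))) {
      planted <- !is.null(truth) && any(
        truth$sample == sm & truth$contig == ev$contig[j] &
          truth$arm == ev$arm[j] & truth$event == ev$event[j])
      expect_true(planted, label = paste("spurious event", sm, j))
    }
  }
})
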