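test_that("channel order runs A[C>A]A through T[T>G]T", {
  ch <- sbs96_channels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)
})

test_that("catalog channelization collapses to the pyrimidine strand", {
  g <- genome_ref(c(chr1 = 3L, chr2 = 3L),
                  sequences = c(chr1 = "ACA", chr2 = "TGT"))
  v <- rbind(
    variant_table("s1", "chr1", 2, "C", "T"),   # A[C>T]A directly
    variant_table("s1", "chr2", 2, "G", "A"))   # TGT revcomps to A[C>T]A
  m <- build_sbs96_catalog(v, g)
  expect_equal(unname(m["A[C>T]A", "s1"]), 2L)
  expect_equal(sum(m), 2L)
})

test_that("reference mismatches and contig-edge SNVs are discarded, counted", {
  g <- genome_ref(c(chr1 = 5L), sequences = c(chr1 = "ACGTA"))
  v <- rbind(
    variant_table("s1", "chr1", 3, "G", "A"),  # matches
    variant_table("s1", "chr1", 3, "T", "A"),  # ref mismatch
    variant_table("s1", "chr1", 1, "A", "T"))  # edge, no 5' flank
  m <- build_sbs96_catalog(v, g)
  expect_equal(sum(m), 1L)
  expect_equal(attr(m, "discarded"),
               c(ref_mismatch = 1L, contig_edge = 1L))
})

test_that("catalog simulated from one channel lands entirely in it", {
  S <- matrix(0, 96, 1, dimnames = list(sbs96_channels(), "one"))
  S["T[C>G]A", 1] <- 1
  cat1 <- simulate_catalog(S, 1, 100, seed = 4)
  expect_equal(unname(cat1["T[C>G]A"]), 100L)
  expect_equal(sum(cat1), 100L)
})

test_that("NNLS satisfies KKT and beats random feasible vectors", {
  set.seed(9)
  S <- default_signatures()
  b <- as.numeric(S %*% c(700, 200, 100)) + rnorm(96, 0, 0.5)
  fit <- nnls_fit(S, b)
  g <- fit$gradient
  expect_true(all(g[fit$x == 0] >= -1e-6))
  expect_true(all(abs(g[fit$x > 0]) <= 1e-6))
  tot <- sum(fit$x)
  for (i in 1:1000) {
    e <- runif(3); e <- e / sum(e) * tot
    expect_gte(sqrt(sum((S %*% e - b)^2)) + 1e-9, fit$residual)
  }
})

test_that("NNLS agrees with the Lawson-Hanson reference implementation", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:20) {
    A <- matrix(runif(40 * 5), 40, 5)
    b <- runif(40)
    expect_equal(nnls_fit(A, b)$x, as.numeric(pracma::lsqnonneg(A, b)$x),
                 tolerance = 1e-8)
  }
})

test_that("identity signatures return the catalog itself", {
  S <- diag(96)
  dimnames(S) <- list(sbs96_channels(), sbs96_channels())
  catal <- matrix(rpois(96, 5), 96, 1,
                  dimnames = list(sbs96_channels(), "s1"))
  lcd <- decompose_lcd(catal, S)
  expect_equal(unname(lcd$exposures[, 1]), as.numeric(catal),
               tolerance = 1e-8)
})

test_that("noiseless catalogs are decomposed exactly", {
  S <- default_signatures()
  e_true <- c(SBS_flat = 400, SBS_CtoT = 250, SBS_TtoC = 350)
  catal <- matrix(as.numeric(S %*% e_true), 96,
                  dimnames = list(rownames(S), "s1"))
  lcd <- decompose_lcd(catal, S)
  expect_equal(lcd$exposures[, 1], e_true, tolerance = 1e-6)
  expect_lt(lcd$residuals[["s1"]], 1e-6)
})

test_that("cutoffs zero weak signatures and keep strong ones accurate", {
  S <- default_signatures()
  err <- matrix(NA_real_, 25, 2)
  third <- numeric(25)
  for (s in 1:25) {
    cat1 <- simulate_catalog(S, c(900, 100, 0), 5000, seed = 100 + s)
    lcd <- decompose_lcd(matrix(cat1, 96, dimnames = list(names(cat1), "x")),
                         S, cutoffs = 0.05)
    third[s] <- lcd$exposures[3, 1]
    err[s, ] <- abs(lcd$exposures[1:2, 1] - c(4500, 500)) / c(4500, 500)
  }
  expect_true(all(third == 0))
  expect_lt(median(err[, 1]), 0.10)
  expect_lt(median(err[, 2]), 0.10)
})

test_that("raising cutoffs never increases the active signature count", {
  S <- default_signatures()
  cat1 <- simulate_catalog(S, c(500, 300, 200), 3000, seed = 5)
  catal <- matrix(cat1, 96, dimnames = list(names(cat1), "s1"))
  n_active <- vapply(c(0, 0.05, 0.15, 0.30, 0.60), function(cut)
    sum(decompose_lcd(catal, S, cutoffs = cut)$exposures[, 1] > 0), 0)
  expect_true(all(diff(n_active) <= 0))
})

test_that("normalized exposures sum to one per mutated sample", {
  b <- simulate_cohort(small_spec(seed = 6))
  cat96 <- build_sbs96_catalog(b$variants, b$genome)
  lcd <- decompose_lcd(cat96, b$spec$signatures)
  sums <- colSums(lcd$normalized)
  expect_true(all(abs(sums[colSums(cat96) > 0] - 1) < 1e-9))
})

test_that("channel mismatch is reported with the offending channels", {
  S <- default_signatures()
  catal <- matrix(0, 95, 1, dimnames = list(rownames(S)[-1], "s1"))
  expect_error(decompose_lcd(catal, S, 0), "mismatch")
})

test_that("exposure comparison gives the exact extreme-separation p", {
  norm <- matrix(c(6:10, 1:5) / 10, 1,
                 dimnames = list("SBS_CtoT", paste0("s", 1:10)))
  labels <- stats::setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  res <- compare_exposures(norm, labels, "SBS_CtoT", "A", "B")
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-9)
  # identical groups are indistinguishable
  norm2 <- matrix(rep(c(1, 2, 3), 2) / 6, 1,
                  dimnames = list("SBS_CtoT", paste0("s", 1:6)))
  labels2 <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  expect_equal(compare_exposures(norm2, labels2, "SBS_CtoT", "A", "B")$p, 1)
  expect_error(compare_exposures(norm[, 1:6, drop = FALSE],
                                 stats::setNames(c("A", rep("B", 5)),
                                                 paste0("s", 1:6)),
                                 "SBS_CtoT", "A", "B"), "2 samples")
})
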