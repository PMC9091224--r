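mini_genes <- function() {
  data.frame(gene_id = c("G1", "G2", "G3"), symbol = c("G1", "G2", "G3"),
             contig = "chr1", start = c(4000, 100000, 300000),
             end = c(6000, 200000, 310000), strand = "+",
             biotype = "protein_coding", exon_len = 1000L,
             stringsAsFactors = FALSE)
}

test_that("recurrent germline indels are removed from every somatic set", {
  mk <- function(sample, germline)
    variant_table(sample, "chr1", 500, "AT", "A", germline = germline)
  v <- rbind(mk("p1", TRUE), mk("p2", TRUE), mk("p3", FALSE),
             mk("p4", FALSE), mk("p5", FALSE))
  out <- filter_recurrent_artifact_indels(v)
  expect_equal(sum(!out$germline), 0)
  expect_equal(attr(out, "n_artifact_removed"), 3L)
  # one germline patient only: retained
  v1 <- rbind(mk("p1", TRUE), mk("p3", FALSE))
  expect_equal(nrow(filter_recurrent_artifact_indels(v1)), 2)
  # no germline flags: identity
  v2 <- rbind(mk("p3", FALSE), mk("p4", FALSE))
  expect_equal(filter_recurrent_artifact_indels(v2), v2,
               ignore_attr = TRUE)
})

test_that("SV breakpoints annotate as direct, near and closest", {
  svs <- data.frame(sample = "s1", contig1 = "chr1", pos1 = 5000L,
                    contig2 = "chr1", pos2 = 250000L,
                    svclass = "deletion", stringsAsFactors = FALSE)
  ann <- annotate_sv_to_genes(svs, mini_genes())
  end1 <- ann[ann$bp_end == 1, ]
  expect_equal(end1$direct, "G1")              # inside [4000, 6000)
  # distance 100000 - 4999 = 95001 <= 100 kb: near; closest is G1 (0)
  expect_true(grepl("G2", end1$near))
  expect_equal(end1$closest, "G1")
  end2 <- ann[ann$bp_end == 2, ]
  expect_equal(end2$direct, "")
  # gene G2 ends at 200000, G3 starts at 300000: both within 100 kb
  expect_setequal(strsplit(end2$near, ",")[[1]], c("G2", "G3"))
  expect_equal(end2$closest, "G2")             # 50000 vs 50001 bp away
})

test_that("breakpoints on unannotated contigs warn and stay blank", {
  svs <- data.frame(sample = "s1", contig1 = "chrZ", pos1 = 10L,
                    contig2 = "chrZ", pos2 = 20L, svclass = "deletion",
                    stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_sv_to_genes(svs, mini_genes()),
                 "chrZ")
  expect_true(all(is.na(ann$closest)))
})

test_that("near/closest ties follow the brute-force answer on random cases", {
  set.seed(14)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      symbol = sprintf("g%02d", 1:20), contig = "chr1",
                      start = sort(sample.int(1e6, 20)) * 3L,
                      strand = "+", biotype = "protein_coding",
                      exon_len = 100L, stringsAsFactors = FALSE)
  genes$end <- genes$start + 2000L
  for (i in 1:30) {
    pos <- sample.int(3e6, 1)
    svs <- data.frame(sample = "s", contig1 = "chr1", pos1 = pos,
                      contig2 = "chr1", pos2 = pos + 10L,
                      svclass = "deletion", stringsAsFactors = FALSE)
    ann <- annotate_sv_to_genes(svs, genes)[1, ]
    p0 <- pos - 1L
    d <- ifelse(genes$start <= p0 & p0 < genes$end, 0L,
                ifelse(p0 < genes$start, genes$start - p0,
                       p0 - genes$end + 1L))
    expect_equal(ann$closest, genes$gene_id[order(d, genes$start)][1])
    expect_setequal(
      if (ann$near == "") character() else strsplit(ann$near, ",")[[1]],
      genes$gene_id[d > 0 & d <= 1e5])
  }
})

test_that("focal CNA classification respects the 30% arm bound", {
  g <- genome_ref(c(chr1 = 1e8),
                  arms = data.frame(contig = "chr1", arm = c("p", "q"),
                                    start = c(0, 5e7), end = c(5e7, 1e8)))
  genes <- mini_genes()
  # 1 Mb deletion on a 50 Mb arm overlapping G2 (partially is enough)
  seg <- data.frame(sample = "s1", contig = "chr1", start = 150000,
                    end = 1150000, tcn = 1, A = 0.5, B = 0.5,
                    stringsAsFactors = FALSE)
  res <- classify_focal_cna(seg, g, genes, ploidy = 2)
  expect_true(all(c("G2", "G3") %in% res$gene_id))
  expect_true(all(res$category == "CNA_focal_loss"))
  expect_false("G1" %in% res$gene_id)
  # a whole-arm gain is not focal
  seg2 <- data.frame(sample = "s1", contig = "chr1", start = 0, end = 5e7,
                     tcn = 3, A = 2, B = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(classify_focal_cna(seg2, g, genes, ploidy = 2)), 0)
})

test_that("alteration matrix applies coding classes and set semantics", {
  v <- rbind(
    variant_table("s1", "chr1", 4500, "A", "T", effect = "synonymous",
                  gene = "G1"),
    variant_table("s2", "chr1", 4500, "A", "T", effect = "nonsynonymous",
                  gene = "G1"),
    variant_table("s2", "chr1", 4600, "C", "G", effect = "nonsynonymous",
                  gene = "G1"),
    variant_table("s3", "chr1", 150000, "A", "T", effect = "ncRNA_exonic",
                  gene = "G2"))
  focal <- list(s2 = data.frame(gene_id = "G1",
                                category = "CNA_focal_loss",
                                stringsAsFactors = FALSE))
  am <- build_alteration_matrix(v, focal = focal,
                                samples = c("s1", "s2", "s3"))
  # synonymous-only gene/sample never enters; SNV + focal count once
  expect_equal(unname(am$recurrence["G1"]), 1L)
  expect_equal(unname(am$recurrence["G2"]), 1L)
  expect_false("s1" %in% am$long$sample)
})

test_that("SV_near annotations never enter oncoprint recurrence", {
  svs <- data.frame(sample = "s1", contig1 = "chr1", pos1 = 7000L,
                    contig2 = "chr1", pos2 = 205000L,
                    svclass = "deletion", stringsAsFactors = FALSE)
  ann <- annotate_sv_to_genes(svs, mini_genes())
  v <- variant_table(character(), character(), integer(), character(),
                     character())
  am <- build_alteration_matrix(v, sv_annot = ann, samples = "s1")
  expect_equal(length(am$recurrence), 0)   # no direct hits anywhere
  expect_true(nrow(am$aux_sv) > 0)         # near/closest kept separately
})

test_that("recurrence comparison reproduces the printed driver contrast", {
  # 18 of 30 vs 2 of 13 altered
  labels <- stats::setNames(rep(c("A", "B"), c(30, 13)),
                            sprintf("s%02d", 1:43))
  v <- variant_table(sample = sprintf("s%02d", c(1:18, 31, 32)),
                     contig = "chr1", pos = 4500, ref = "A", alt = "T",
                     effect = "nonsynonymous", gene = "BTG2")
  am <- build_alteration_matrix(v, samples = names(labels))
  rc <- recurrence_compare(am, labels, "A", "B")
  expect_equal(signif(rc$p, 1), 0.009)
  expect_gt(rc$log2fc, 1)
  # degenerate all-zero case through the Haldane correction
  v0 <- variant_table("s01", "chr1", 4500, "A", "T",
                      effect = "nonsynonymous", gene = "X")
  am0 <- build_alteration_matrix(v0, samples = names(labels)[1:20])
  lab0 <- stats::setNames(rep(c("A", "B"), each = 10),
                          sprintf("s%02d", 1:20))
  rc0 <- recurrence_compare(am0, lab0, "A", "B")
  expect_true(is.finite(rc0$log2fc))
})

test_that("mutual exclusivity: disjoint and identical gene pairs", {
  samples <- sprintf("s%02d", 1:20)
  mkv <- function(g, who) variant_table(who, "chr1", 4500, "A", "T",
                                        effect = "nonsynonymous", gene = g)
  # disjoint: ga in s1..s10, gb in s11..s20
  v <- rbind(mkv("ga", samples[1:10]), mkv("gb", samples[11:20]))
  am <- build_alteration_matrix(v, samples = samples)
  me <- mutual_exclusivity(am, samples = samples, min_recurrence = 5)
  expect_equal(me$p_left, 1 / choose(20, 10), tolerance = 1e-9)
  expect_equal(me$p_right, 1, tolerance = 1e-12)
  # identical vectors: right tail minimal, left tail 1
  v2 <- rbind(mkv("ga", samples[1:10]), mkv("gb", samples[1:10]))
  am2 <- build_alteration_matrix(v2, samples = samples)
  me2 <- mutual_exclusivity(am2, samples = samples, min_recurrence = 5)
  expect_equal(me2$p_right, 1 / choose(20, 10), tolerance = 1e-9)
  expect_equal(me2$p_left, 1, tolerance = 1e-12)
  # genes below the recurrence threshold are not tested
  v3 <- rbind(mkv("ga", samples[1:10]), mkv("gb", samples[1:10]),
              mkv("gc", samples[1:4]))
  am3 <- build_alteration_matrix(v3, samples = samples)
  me3 <- mutual_exclusivity(am3, samples = samples, min_recurrence = 5)
  expect_false("gc" %in% c(me3$geneA, me3$geneB))
})

test_that("Fisher tails match hypergeometric closed forms and BH is
          monotone", {
  samples <- sprintf("s%02d", 1:16)
  set.seed(15)
  vs <- lapply(sprintf("g%d", 1:5), function(g)
    variant_table(sample(samples, 8), "chr1", 4500, "A", "T",
                  effect = "nonsynonymous", gene = g))
  am <- build_alteration_matrix(do.call(rbind, vs), samples = samples)
  me <- mutual_exclusivity(am, samples = samples, min_recurrence = 5)
  for (i in seq_len(nrow(me))) {
    tab <- matrix(c(me$both[i], me$onlyA[i], me$onlyB[i], me$neither[i]), 2)
    expect_equal(me$p_right[i],
                 stats::phyper(me$both[i] - 1, me$both[i] + me$onlyA[i],
                               me$onlyB[i] + me$neither[i],
                               me$both[i] + me$onlyB[i],
                               lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(me$p_left[i],
                 stats::phyper(me$both[i], me$both[i] + me$onlyA[i],
                               me$onlyB[i] + me$neither[i],
                               me$both[i] + me$onlyB[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(me$q_right >= me$p_right - 1e-12))
  o <- order(me$p_right)
  expect_true(all(diff(me$q_right[o]) >= -1e-12))
})
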