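test_that("variant table enforces allele and read-count invariants", {
  v <- variant_table("s1", "chr1", 100, "A", "T", effect = "nonsynonymous")
  expect_equal(v$class, "SNV")
  expect_equal(variant_table("s1", "chr1", 5, "A", "AGG")$class, "insertion")
  expect_equal(variant_table("s1", "chr1", 5, "ACT", "A")$class, "deletion")
  expect_error(variant_table("s1", "chr1", 5, "A", "A"), "SNV")
  expect_error(variant_table("s1", "chr1", 5, "A", "T", t_alt = 10,
                             t_dp = 5), "exceeds")
  expect_equal(variant_table("s1", "chr1", 5, "A", "T",
                             effect = "garbled")$effect, "noncoding_other")
})

test_that("VCF subset round-trips field by field", {
  g <- tiny_genome()
  v <- variant_table(
    sample = "s1", contig = "chr1", pos = c(10, 50, 200),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
    effect = c("nonsynonymous", "synonymous", "stopgain"),
    gene = c("G1", NA, "G2"),
    t_alt = c(86, 5, 0), t_dp = c(170, 40, 30),
    c_alt = c(3, 0, 0), c_dp = c(47, 20, 25),
    germline = c(TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, f, g)
  v2 <- read_variants(f, "s1")
  expect_equal(v2[, names(v)], v, ignore_attr = TRUE)
})

test_that("paired AD/DP read support maps to control and tumor counts", {
  # the worked contamination example: 3 of 47 control, 86 of 170 tumor
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "CONTROL", "TUMOR", sep = "\t"),
    paste("chr1", "1000", ".", "A", "T", ".", "PASS",
          "EFFECT=nonsynonymous", "AD:DP", "44,3:47", "84,86:170",
          sep = "\t")), f)
  v <- read_variants(f, "s1")
  expect_equal(v$c_alt, 3L); expect_equal(v$c_dp, 47L)
  expect_equal(v$t_alt, 86L); expect_equal(v$t_dp, 170L)
  expect_equal(v$effect, "nonsynonymous")
})

test_that("empty VCF body yields an empty variant set", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(variant_table(character(), character(), integer(),
                                   character(), character()), f,
                     tiny_genome())
  expect_equal(nrow(read_variants(f, "s1")), 0)
})

test_that("non-monotone positions raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "500", ".", "A", "T", ".", "PASS", "EFFECT=synonymous",
          sep = "\t"),
    paste("chr1", "100", ".", "C", "G", ".", "PASS", "EFFECT=synonymous",
          sep = "\t")), f)
  expect_error(read_variants(f, "s1"), "line 6")
})

test_that("GTF gene coordinates convert to 0-based half-open and back", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste(
    "chr1", "src", "gene", "101", "200", ".", "+", ".",
    "gene_id \"G1\"; gene_name \"GENE1\"; gene_type \"protein_coding\";",
    sep = "\t"), f)
  g <- read_gene_models(f)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(g$biotype, "protein_coding")
  # involution: internal half-open back to 1-based inclusive
  expect_equal(c(g$start + 1L, g$end), c(101L, 200L))
})

test_that("extended BED gene models pass through with biotype", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t0\t500\tG9\t0\t+\tmiRNA", f)
  g <- read_gene_models(f)
  expect_equal(g$biotype, "miRNA")
  expect_equal(g$start, 0L); expect_equal(g$end, 500L)
})

test_that("duplicate gene ids are rejected by name", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tGdup\t0\t+\tother",
               "chr1\t200\t300\tGdup\t0\t+\tother"), f)
  expect_error(read_gene_models(f), "Gdup")
})

test_that("segment reader accepts abutting rows, rejects overlaps, keeps
          homozygous deletions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttcn\tA\tB",
               "s1\tchr1\t0\t1000000\t2.1\t1.1\t1.0",
               "s1\tchr1\t1000000\t2000000\t3.9\t2.9\t1.0",
               "s1\tchr2\t0\t5000\t0\t0\t0"), f)
  seg <- read_segments(f)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$tcn[seg$contig == "chr2"], 0)
  writeLines(c("sample\tchrom\tstart\tend\ttcn\tA\tB",
               "s1\tchr1\t0\t10\t2\t1\t1",
               "s1\tchr1\t5\t15\t2\t1\t1"), f)
  expect_error(read_segments(f), "overlap")
})

test_that("BEDPE round-trips and enforces breakpoint conventions", {
  sv <- data.frame(sample = "s1", contig1 = c("chr1", "chr1"),
                   pos1 = c(100L, 5000L), contig2 = c("chr1", "chr2"),
                   pos2 = c(900L, 70L),
                   svclass = c("deletion", "translocation"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(sv, f)
  sv2 <- read_bedpe(f, "s1")
  expect_equal(sv2, sv, ignore_attr = TRUE)
  bad2 <- transform(sv, pos1 = c(900L, 5000L), pos2 = c(100L, 70L))
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(bad2, f2)
  expect_error(read_bedpe(f2, "s1"), "pos1")
})

test_that("matrix and FASTQ writers round-trip", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m, ignore_attr = FALSE,
               tolerance = 0)
  reads <- c(r1 = strrep("ACGT", 10), r2 = strrep("TTAGGG", 7))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)
})

test_that("genome FASTA round-trips through Biostrings", {
  g <- tiny_genome(arms = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- read_genome_fasta(f)
  expect_equal(g2$contigs, g$contigs)
  expect_equal(g2$sequences, g$sequences)
})
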