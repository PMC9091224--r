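# shared fixtures: a desk-sized cohort spec and deterministic toy genomes

small_spec <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    subgroups = c(PCNSL = 3, ABC_DLBCL = 2),
    genome = list(n_contigs = 2, contig_length = 5e5, arm_split = 0.45,
                  gc = 0.5),
    genes = list(protein_coding = 12, lincRNA = 4, antisense = 4, miRNA = 3,
                 rRNA = 2, tRNA = 2, mean_length = 8e3),
    snv_rate_per_mb = 30,
    cnv = list(ploidy = 2, tcc_range = c(0.5, 0.95), arm_gain_prob = 0.10,
               arm_loss_prob = 0.10, arm_cnloh_prob = 0.05,
               arm_fraction_range = c(0.4, 1), focal_per_sample = 2,
               focal_length_range = c(2e4, 6e4), jitter_sd = 0.05,
               extra_breakpoints = 4),
    tinda = list(contamination = 0.1, n_germline = 300, n_somatic = 50,
                 hom_fraction = 0.2, depth = 100, tumor_vaf = 0.5),
    telomere = list(content_tumor = 20000, content_control = 10000,
                    read_length = 100, n_background = 400,
                    variant_repeat_prob = 0.1))
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

# a fixed tiny genome whose sequence is known literally
tiny_genome <- function(seq1 = strrep("ACGT", 250), arms = TRUE) {
  n <- nchar(seq1)
  genome_ref(
    contigs = c(chr1 = n),
    sequences = c(chr1 = seq1),
    arms = if (arms) data.frame(contig = "chr1", arm = c("p", "q"),
                                start = c(0, round(0.45 * n)),
                                end = c(round(0.45 * n), n))
    else NULL)
}

snv_at <- function(pos, sample = "s1", contig = "chr1", ref = "A",
                   alt = "T", ...) {
  variant_table(sample = sample, contig = contig, pos = pos, ref = ref,
                alt = alt, ...)
}
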