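#' Specification of a synthetic cohort
#'
#' Collects every parameter the cohort generator needs. Defaults emulate a
#' desk-scale version of a CNS-lymphoma WGS/RNAseq cohort: two subgroups
#' sized like the primary comparison (30 vs 13 samples), a 3 x 10 Mb toy
#' genome with arms split at 45%/55%, a background somatic SNV rate of
#' 6/Mb (the order of magnitude implied by ~20k SNVs over a human genome),
#' implanted kataegis clusters that satisfy the detection rule by
#' construction, arm-level and focal copy-number events, tumor-in-normal
#' contamination at 10%, telomeric/background read sets and
#' negative-binomial expression with an IGHM-high subgroup.
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the spec including this seed.
#' @param subgroups named integer vector subgroup -> number of samples.
#' @param genome list: `n_contigs`, `contig_length`, `arm_split`, `gc`.
#' @param genes list of panel sizes per biotype and `mean_length`.
#' @param snv_rate_per_mb background somatic SNV rate.
#' @param signatures channel x signature reference matrix (columns sum
#'   to 1).
#' @param exposure_props named list subgroup -> normalized exposure vector.
#' @param kataegis list: `clusters_per_sample`, `n_snvs_range` (within
#'   [6, 30]), `spacing_mean` (bp, <= 500), `context_bias` (probability of
#'   snapping an implanted SNV to a TpC context), `n_target_genes`.
#' @param cnv list: `ploidy`, `tcc_range`, `arm_gain_prob`, `arm_loss_prob`,
#'   `arm_cnloh_prob`, `arm_fraction_range`, `focal_per_sample`,
#'   `focal_length_range`, `jitter_sd`, `extra_breakpoints`.
#' @param sv list: `per_sample` and `class_mix`.
#' @param tinda list: `contamination`, `n_germline`, `n_somatic`,
#'   `hom_fraction`, `depth`, `tumor_vaf`.
#' @param telomere list: `content_tumor`, `content_control` (telomeric reads
#'   per million GC-matched reads), `read_length`, `n_background`,
#'   `variant_repeat_prob`.
#' @param expression list: `mean_log`, `sd_log`, `dispersion`,
#'   `ighm_factor`, `n_signature_genes`, `signature_shift`.
#' @return object of class `CohortSpec`.
#' @export
cohort_spec <- function(
    seed = 1,
    subgroups = c(PCNSL = 30, ABC_DLBCL = 13),
    genome = list(n_contigs = 3, contig_length = 1e7, arm_split = 0.45,
                  gc = 0.5),
    genes = list(protein_coding = 60, lincRNA = 15, antisense = 15,
                 miRNA = 10, rRNA = 3, tRNA = 3, mean_length = 2e4),
    snv_rate_per_mb = 6,
    signatures = default_signatures(),
    exposure_props = list(PCNSL = c(SBS_flat = 0.2, SBS_CtoT = 0.5,
                                    SBS_TtoC = 0.3),
                          ABC_DLBCL = c(SBS_flat = 0.4, SBS_CtoT = 0.3,
                                        SBS_TtoC = 0.3)),
    kataegis = list(clusters_per_sample = 2, n_snvs_range = c(6, 18),
                    spacing_mean = 200, context_bias = 0.8,
                    n_target_genes = 8),
    cnv = list(ploidy = 2, tcc_range = c(0.5, 0.95), arm_gain_prob = 0.10,
               arm_loss_prob = 0.10, arm_cnloh_prob = 0.05,
               arm_fraction_range = c(0.4, 1), focal_per_sample = 2,
               focal_length_range = c(3e5, 1e6), jitter_sd = 0.05,
               extra_breakpoints = 4),
    sv = list(per_sample = 4,
              class_mix = c(deletion = 0.3, duplication = 0.2,
                            inversion = 0.2, translocation = 0.3)),
    tinda = list(contamination = 0.1, n_germline = 2000, n_somatic = 200,
                 hom_fraction = 0.2, depth = 100, tumor_vaf = 0.5),
    telomere = list(content_tumor = 20000, content_control = 10000,
                    read_length = 100, n_background = 3000,
                    variant_repeat_prob = 0.1),
    expression = list(mean_log = 3, sd_log = 1.2, dispersion = 0.3,
                      ighm_factor = 30, n_signature_genes = 10,
                      signature_shift = 2)) {
  spec <- list(seed = seed, subgroups = subgroups, genome = genome,
               genes = genes, snv_rate_per_mb = snv_rate_per_mb,
               signatures = signatures, exposure_props = exposure_props,
               kataegis = kataegis, cnv = cnv, sv = sv, tinda = tinda,
               telomere = telomere, expression = expression)
  stopifnot(all(subgroups >= 0),
            kataegis$n_snvs_range[1] >= 6, kataegis$n_snvs_range[2] <= 30,
            kataegis$spacing_mean <= 500,
            tinda$contamination >= 0, tinda$contamination < 1)
  for (g in names(exposure_props))
    if (abs(sum(exposure_props[[g]]) - 1) > 1e-9)
      stop("exposure proportions for ", g, " must sum to 1")
  structure(spec, class = "CohortSpec")
}

#' A small synthetic signature reference (three distinguishable signatures)
#'
#' Entirely synthetic stand-ins for real single-base-substitution
#' signatures: one flat signature, one concentrated on C>T channels and one
#' on T>C channels (with mild within-block structure so the columns are far
#' from collinear).
#'
#' @return 96 x 3 matrix, columns summing to 1.
#' @export
default_signatures <- function() {
  ch <- sbs96_channels()
  sub <- sub(".*\\[(.*)\\].*", "\\1", ch)
  s1 <- rep(1 / 96, 96)
  shape <- rep(c(3, 2, 1, 2), 4)  # fixed within-block profile
  s2 <- ifelse(sub == "C>T", shape, 0.05); s2 <- s2 / sum(s2)
  s3 <- ifelse(sub == "T>C", rev(shape), 0.05); s3 <- s3 / sum(s3)
  m <- cbind(SBS_flat = s1, SBS_CtoT = s2, SBS_TtoC = s3)
  rownames(m) <- ch
  m
}

#' Draw a mutational catalog from known signatures and exposures
#'
#' A multinomial draw of `n_mutations` channels from the probability vector
#' `signatures %*% (exposures / sum(exposures))`.
#'
#' @param signatures channel x signature matrix (columns sum to 1).
#' @param exposures nonnegative exposure vector (one per signature).
#' @param n_mutations catalog size.
#' @param seed integer seed.
#' @return named integer vector of channel counts.
#' @export
simulate_catalog <- function(signatures, exposures, n_mutations, seed = 1) {
  if (sum(exposures) <= 0) stop("total exposure must be positive")
  if (any(exposures < 0)) stop("exposures must be nonnegative")
  p <- as.numeric(signatures %*% (exposures / sum(exposures)))
  set.seed(as.integer(seed %% 2147483647))
  counts <- if (n_mutations > 0) as.integer(stats::rmultinom(1, n_mutations, p))
            else integer(nrow(signatures))
  stats::setNames(counts, rownames(signatures))
}

#' Simulate paired tumor/control B-allele frequencies with contamination
#'
#' Germline heterozygous points concentrate at (0.5, 0.5) and homozygous
#' points at (1, 1); somatic points misclassified as germline due to
#' tumor-in-normal contamination have tumor VAF near `tumor_vaf` and
#' control VAF near `contamination * tumor_vaf`, all with binomial
#' counting noise at the stated depth.
#'
#' @param n_germline,n_somatic point counts.
#' @param contamination tumor-in-normal fraction in `[0, 1)`.
#' @param depth sequencing depth for the binomial draws.
#' @param tumor_vaf expected somatic tumor VAF.
#' @param hom_fraction fraction of germline points that are homozygous.
#' @param seed integer seed.
#' @return data frame `vaf_control, vaf_tumor, class, truth, common`.
#' @export
simulate_tinda_points <- function(n_germline = 2000, n_somatic = 200,
                                  contamination = 0.1, depth = 100,
                                  tumor_vaf = 0.5, hom_fraction = 0.2,
                                  seed = 1) {
  if (contamination < 0 || contamination >= 1)
    stop("contamination must lie in [0, 1)")
  set.seed(as.integer(seed %% 2147483647))
  n_hom <- round(n_germline * hom_fraction)
  n_het <- n_germline - n_hom
  vc <- c(stats::rbinom(n_het, depth, 0.5),
          stats::rbinom(n_hom, depth, 0.995),
          stats::rbinom(n_somatic, depth, contamination * tumor_vaf)) / depth
  vt <- c(stats::rbinom(n_het, depth, 0.5),
          stats::rbinom(n_hom, depth, 0.995),
          stats::rbinom(n_somatic, depth, tumor_vaf)) / depth
  data.frame(
    vaf_control = vc, vaf_tumor = vt,
    class = "germline",
    truth = c(rep("germline", n_germline),
              rep("contaminated_somatic", n_somatic)),
    common = FALSE, stringsAsFactors = FALSE)
}

#' Simulate telomeric and background reads
#'
#' Telomeric reads are tandem TTAGGG repeats with each repeat unit replaced
#' by one of the variant repeat types (TCAGGG/TGAGGG/TTGGGG) with
#' probability `variant_repeat_prob`; background reads are i.i.d. bases at
#' the requested GC content.
#'
#' @param n_telomeric,n_background read counts.
#' @param read_length read length L >= 30.
#' @param gc background GC fraction.
#' @param variant_repeat_prob per-repeat variant substitution probability.
#' @param seed integer seed.
#' @return list `reads` (named character vector, telomeric first) and
#'   `truth` (planted telomeric read names).
#' @export
simulate_telomere_reads <- function(n_telomeric, n_background,
                                    read_length = 100, gc = 0.5,
                                    variant_repeat_prob = 0.1, seed = 1) {
  if (read_length < 30) stop("read length must be >= 30")
  set.seed(as.integer(seed %% 2147483647))
  n_rep <- ceiling(read_length / 6)
  tel <- vapply(seq_len(n_telomeric), function(i) {
    reps <- ifelse(stats::runif(n_rep) < variant_repeat_prob,
                   sample(TELOMERE_REPEATS[-1], n_rep, replace = TRUE),
                   TELOMERE_REPEATS[1])
    substr(paste(reps, collapse = ""), 1, read_length)
  }, "")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bg <- vapply(seq_len(n_background), function(i)
    paste(sample(names(p), read_length, replace = TRUE, prob = p),
          collapse = ""), "")
  reads <- c(tel, bg)
  names(reads) <- c(sprintf("tel%04d", seq_len(n_telomeric)),
                    sprintf("bg%05d", seq_len(n_background)))
  list(reads = reads, truth = names(reads)[seq_len(n_telomeric)])
}

## ---- full cohort ----------------------------------------------------------

# random toy genome with uniform base composition at the requested GC
random_genome <- function(gspec) {
  lens <- stats::setNames(rep(gspec$contig_length, gspec$n_contigs),
                          as.character(seq_len(gspec$n_contigs)))
  p <- c(A = (1 - gspec$gc) / 2, C = gspec$gc / 2, G = gspec$gc / 2,
         T = (1 - gspec$gc) / 2)
  seqs <- vapply(lens, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
  split_at <- round(gspec$arm_split * lens)
  arms <- do.call(rbind, lapply(names(lens), function(ctg)
    data.frame(contig = ctg, arm = c("p", "q"),
               start = c(0, split_at[[ctg]]),
               end = c(split_at[[ctg]], lens[[ctg]]),
               stringsAsFactors = FALSE)))
  genome_ref(contigs = lens, sequences = seqs, arms = arms)
}

# non-overlapping gene panel over the toy genome
random_gene_panel <- function(genome, gpanel) {
  biotypes <- rep(names(gpanel)[names(gpanel) %in% BIOTYPES],
                  unlist(gpanel[names(gpanel) %in% BIOTYPES]))
  n <- length(biotypes)
  lens <- pmax(500, round(stats::rexp(n, 1 / gpanel$mean_length)))
  lens[biotypes == "miRNA"] <- pmax(80, round(stats::rexp(
    sum(biotypes == "miRNA"), 1 / 500)))
  contigs <- sample(names(genome$contigs), n, replace = TRUE)
  starts <- integer(n)
  occupied <- lapply(genome$contigs, function(...) cbind(start = 0,
                                                         end = 0)[0, ])
  for (i in order(-lens)) {
    ctg <- contigs[i]
    for (try in 1:200) {
      s <- sample.int(genome$contigs[[ctg]] - lens[i] - 2L, 1)
      occ <- occupied[[ctg]]
      if (!nrow(occ) || all(s + lens[i] <= occ[, 1] | s >= occ[, 2])) break
      s <- NA
    }
    if (is.na(s)) stop("gene panel too dense for the toy genome")
    starts[i] <- s
    occupied[[ctg]] <- rbind(occupied[[ctg]], c(s, s + lens[i]))
  }
  ids <- sprintf("G%04d", seq_len(n))
  data.frame(gene_id = ids, symbol = ids, contig = contigs, start = starts,
             end = starts + lens,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = biotypes,
             exon_len = pmax(80L, as.integer(round(lens * 0.6))),
             stringsAsFactors = FALSE)
}

# draw a genome-consistent alt allele for each position given the mixture;
# returns ref/alt vectors (ref always matches the genome)
draw_alts <- function(ctx, mix_p, channels) {
  mid <- substr(ctx, 2, 2)
  pur <- mid %in% c("A", "G")
  pyr_ctx <- ctx
  pyr_ctx[pur] <- revcomp(ctx[pur])
  f5 <- substr(pyr_ctx, 1, 1); mid_p <- substr(pyr_ctx, 2, 2)
  f3 <- substr(pyr_ctx, 3, 3)
  alts_for <- function(m) setdiff(c("A", "C", "G", "T"), m)
  alt <- character(length(ctx))
  for (i in seq_along(ctx)) {
    cand <- alts_for(mid_p[i])
    labs <- paste0(f5[i], "[", mid_p[i], ">", cand, "]", f3[i])
    w <- mix_p[match(labs, channels)]
    if (all(w == 0) || anyNA(w)) w <- rep(1, 3)
    a <- sample(cand, 1, prob = w)
    alt[i] <- if (pur[i]) comp_base(a) else a
  }
  list(ref = mid, alt = alt)
}

# assign gene and effect class by position
assign_effects <- function(contig, pos, genes) {
  gene <- rep(NA_character_, length(pos))
  effect <- rep("noncoding_other", length(pos))
  for (i in seq_along(pos)) {
    hit <- which(genes$contig == contig[i] & genes$start < pos[i] &
                   pos[i] <= genes$end)
    if (!length(hit)) next
    g <- hit[1]
    gene[i] <- genes$gene_id[g]
    effect[i] <- if (genes$biotype[g] == "protein_coding")
      sample(c("nonsynonymous", "synonymous", "stopgain", "splicing"), 1,
             prob = c(0.55, 0.3, 0.07, 0.08))
    else "ncRNA_exonic"
  }
  list(gene = gene, effect = effect)
}

#' Simulate a complete synthetic cohort
#'
#' Deterministic for a fixed spec (including its seed). Produces per-sample
#' somatic SNV/indel calls whose channels follow the subgroup signature
#' mixture (drawn genome-consistently), implanted kataegis clusters that
#' satisfy the detection rule by construction, noisy allele-specific
#' copy-number segments with implanted arm-level and focal events,
#' structural-variant breakpoints, paired-BAF point sets with
#' tumor-in-normal contamination, telomeric/background read sets and a
#' negative-binomial expression matrix with subgroup structure — plus a
#' ground-truth ledger for every implant.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `CohortBundle` with elements `genome`, `genes`,
#'   `meta`, `variants`, `segments`, `svs`, `tinda_points`,
#'   `telomere_reads`, `counts`, `background_profile` and `truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(as.integer(spec$seed %% 2147483647))
  genome <- random_genome(spec$genome)
  genes <- random_gene_panel(genome, spec$genes)
  channels <- rownames(spec$signatures)

  samples <- unlist(lapply(names(spec$subgroups), function(g)
    sprintf("%s_%02d", g, seq_len(spec$subgroups[[g]]))))
  subgroup <- rep(names(spec$subgroups), spec$subgroups)
  meta <- data.frame(sample = samples, subgroup = subgroup,
                     ploidy = spec$cnv$ploidy,
                     tcc = stats::runif(length(samples),
                                        spec$cnv$tcc_range[1],
                                        spec$cnv$tcc_range[2]),
                     stringsAsFactors = FALSE)

  # kataegis target genes: the widest protein-coding genes
  pc <- genes[genes$biotype == "protein_coding", ]
  targets <- pc$gene_id[order(-(pc$end - pc$start))][
    seq_len(min(spec$kataegis$n_target_genes, nrow(pc)))]
  if (length(targets) < spec$kataegis$clusters_per_sample)
    stop("gene panel too small for the requested kataegis implants")

  variants <- list(); kat_truth <- list()
  seg_all <- list(); arm_truth <- list(); sv_all <- list()
  tinda_points <- list(); telomere_reads <- list(); tel_truth <- list()
  genome_mb <- sum(genome$contigs) / 1e6
  arms <- genome_arms(genome)

  for (si in seq_along(samples)) {
    sm <- samples[si]
    props <- spec$exposure_props[[subgroup[si]]]
    mix_p <- as.numeric(spec$signatures %*% props)

    ## --- kataegis implants -------------------------------------------------
    kpos <- list()
    tg <- sample(targets, spec$kataegis$clusters_per_sample)
    for (g in tg) {
      gi <- genes[genes$gene_id == g, ]
      n_k <- sample(seq(spec$kataegis$n_snvs_range[1],
                        spec$kataegis$n_snvs_range[2]), 1)
      repeat {
        gaps <- pmax(1, round(stats::rexp(n_k - 1,
                                          1 / spec$kataegis$spacing_mean)))
        if (mean(gaps) <= 1000) break
      }
      start <- gi$start + sample.int(max(1, gi$end - gi$start -
                                           sum(gaps) - 2L), 1)
      pos <- cumsum(c(start + 1L, gaps))  # 1-based positions
      # TpC context bias: snap to a nearby TpC (or GpA) site
      for (j in seq_along(pos)) {
        if (stats::runif(1) > spec$kataegis$context_bias) next
        win <- genome_seq(genome, gi$contig, max(0, pos[j] - 16),
                          min(genome$contigs[[gi$contig]], pos[j] + 15))
        hit <- regexpr("TC|GA", win)
        if (hit > 0)
          pos[j] <- max(0, pos[j] - 16) + as.integer(hit) +
            (if (substr(win, hit, hit + 1) == "TC") 1L else 0L)
      }
      pos <- sort(unique(pos))
      if (length(pos) < 6) next
      kpos[[g]] <- data.frame(contig = gi$contig, pos = pos,
                              stringsAsFactors = FALSE)
      kat_truth[[length(kat_truth) + 1L]] <- data.frame(
        sample = sm, gene_id = g, contig = gi$contig,
        start = min(pos) - 1L, end = max(pos),
        n_snvs = length(pos),
        mean_imd = (max(pos) - min(pos)) / (length(pos) - 1),
        stringsAsFactors = FALSE)
    }
    kat <- do.call(rbind, kpos)

    ## --- background SNVs (outside implanted clusters) ----------------------
    n_bg <- stats::rpois(1, spec$snv_rate_per_mb * genome_mb)
    bg_ctg <- sample(names(genome$contigs), n_bg, replace = TRUE,
                     prob = genome$contigs)
    bg_pos <- vapply(bg_ctg, function(ctg)
      1L + sample.int(genome$contigs[[ctg]] - 2L, 1), 0L)
    if (!is.null(kat)) {
      drop <- rep(FALSE, n_bg)
      for (kt in kat_truth[vapply(kat_truth, function(x)
        x$sample[1] == sm, TRUE)])
        drop <- drop | (bg_ctg == kt$contig & bg_pos > kt$start &
                          bg_pos <= kt$end)
      bg_ctg <- bg_ctg[!drop]; bg_pos <- bg_pos[!drop]
    }
    all_ctg <- c(bg_ctg, if (!is.null(kat)) kat$contig)
    all_pos <- c(bg_pos, if (!is.null(kat)) kat$pos)
    keep <- !duplicated(paste(all_ctg, all_pos))
    all_ctg <- all_ctg[keep]; all_pos <- all_pos[keep]
    ctx <- vapply(seq_along(all_pos), function(i)
      genome_seq(genome, all_ctg[i], all_pos[i] - 2L, all_pos[i] + 1L), "")
    ra <- draw_alts(ctx, mix_p, channels)
    ef <- assign_effects(all_ctg, all_pos, genes)
    dp_t <- stats::rpois(length(all_pos), 80) + 10L
    dp_c <- stats::rpois(length(all_pos), 45) + 5L
    vt <- variant_table(
      sample = sm, contig = all_ctg, pos = all_pos, ref = ra$ref,
      alt = ra$alt, effect = ef$effect, gene = ef$gene,
      t_alt = stats::rbinom(length(all_pos), dp_t, meta$tcc[si] / 2),
      t_dp = dp_t, c_alt = 0L, c_dp = dp_c, germline = FALSE)

    ## --- a few somatic indels ---------------------------------------------
    n_ind <- 10L
    ic <- sample(names(genome$contigs), n_ind, replace = TRUE)
    ip <- vapply(ic, function(ctg)
      1L + sample.int(genome$contigs[[ctg]] - 10L, 1), 0L)
    iref <- vapply(seq_len(n_ind), function(i)
      genome_seq(genome, ic[i], ip[i] - 1L, ip[i] + sample(1:3, 1)), "")
    ins <- stats::runif(n_ind) < 0.5
    ialt <- ifelse(ins, paste0(substr(iref, 1, 1),
                               vapply(seq_len(n_ind), function(i)
                                 paste(sample(c("A", "C", "G", "T"),
                                              sample(1:3, 1), TRUE),
                                       collapse = ""), "")),
                   substr(iref, 1, 1))
    iref <- ifelse(ins, substr(iref, 1, 1), iref)
    ief <- assign_effects(ic, ip, genes)
    ief$effect[!is.na(ief$gene) & ief$effect != "ncRNA_exonic"] <-
      sample(c("frameshift", "nonframeshift"),
             sum(!is.na(ief$gene) & ief$effect != "ncRNA_exonic"),
             replace = TRUE)
    vi <- variant_table(sample = sm, contig = ic, pos = ip, ref = iref,
                        alt = ialt, effect = ief$effect, gene = ief$gene,
                        germline = FALSE)
    variants[[sm]] <- rbind(vt, vi)

    ## --- copy-number segments ---------------------------------------------
    sseg <- list(); struth <- list(); arm_regions <- list()
    for (ai in seq_len(nrow(arms))) {
      a <- arms[ai, ]
      u <- stats::runif(1)
      ev <- if (u < spec$cnv$arm_gain_prob) "gain"
            else if (u < spec$cnv$arm_gain_prob + spec$cnv$arm_loss_prob)
              "loss"
            else if (u < spec$cnv$arm_gain_prob + spec$cnv$arm_loss_prob +
                       spec$cnv$arm_cnloh_prob) "cnLOH"
            else "none"
      frac <- if (ev == "none") 0
        else if (ev == "cnLOH") stats::runif(1, 0.75, 1)
        else stats::runif(1, spec$cnv$arm_fraction_range[1],
                          spec$cnv$arm_fraction_range[2])
      alen <- a$end - a$start
      ev_len <- round(frac * alen)
      anchor_left <- stats::runif(1) < 0.5
      ev_start <- if (anchor_left) a$start else a$end - ev_len
      ev_end <- ev_start + ev_len
      if (ev != "none") {
        struth[[length(struth) + 1L]] <- data.frame(
          sample = sm, contig = a$contig, arm = a$arm, event = ev,
          fraction = frac, stringsAsFactors = FALSE)
        arm_regions[[length(arm_regions) + 1L]] <- data.frame(
          contig = a$contig, start = ev_start, end = ev_end,
          stringsAsFactors = FALSE)
      }
      # breakpoints: event boundaries plus jittered extras
      bp <- sort(unique(c(a$start, a$end,
                          if (ev != "none") c(ev_start, ev_end),
                          a$start + sample.int(alen,
                                               spec$cnv$extra_breakpoints))))
      st <- head(bp, -1); en <- tail(bp, -1)
      base_t <- rep(spec$cnv$ploidy, length(st))
      base_b <- rep(spec$cnv$ploidy / 2, length(st))
      inside <- st >= ev_start & en <= ev_end
      if (ev == "gain") base_t[inside] <- base_t[inside] + 1
      if (ev == "loss") { base_t[inside] <- base_t[inside] - 1
                          base_b[inside] <- pmax(0, base_b[inside] - 1) }
      if (ev == "cnLOH") base_b[inside] <- 0
      tcn <- pmax(0, base_t + stats::rnorm(length(st), 0,
                                           spec$cnv$jitter_sd))
      B <- pmin(pmax(0, base_b + stats::rnorm(length(st), 0,
                                              spec$cnv$jitter_sd / 2)), tcn)
      sseg[[length(sseg) + 1L]] <- data.frame(
        sample = sm, contig = a$contig, start = st, end = en, tcn = tcn,
        A = tcn - B, B = B, stringsAsFactors = FALSE)
    }
    seg <- do.call(rbind, sseg)
    ## focal events on top (placed outside implanted arm events so the
    ## ledger fractions stay exact): replace the local stretch
    for (f in seq_len(spec$cnv$focal_per_sample)) {
      ctg <- sample(names(genome$contigs), 1)
      flen <- round(stats::runif(1, spec$cnv$focal_length_range[1],
                                 spec$cnv$focal_length_range[2]))
      flen <- min(flen, floor(genome$contigs[[ctg]] / 5))
      fstart <- NA
      for (try in 1:50) {
        cand <- sample.int(genome$contigs[[ctg]] - flen, 1)
        clash <- any(vapply(arm_regions, function(rg)
          rg$contig == ctg && cand < rg$end && cand + flen > rg$start,
          TRUE))
        if (!clash) { fstart <- cand; break }
      }
      if (is.na(fstart)) next
      kind <- sample(c("gain", "loss"), 1)
      seg <- punch_segment(seg, sm, ctg, fstart, fstart + flen,
                           delta = if (kind == "gain") 1 else -1,
                           jitter_sd = spec$cnv$jitter_sd)
    }
    seg_all[[sm]] <- seg
    if (length(struth)) arm_truth[[sm]] <- do.call(rbind, struth)

    ## --- structural variants ----------------------------------------------
    n_sv <- spec$sv$per_sample
    if (n_sv > 0) {
      cls <- sample(names(spec$sv$class_mix), n_sv, replace = TRUE,
                    prob = spec$sv$class_mix)
      sv <- lapply(cls, function(cl) {
        if (cl == "translocation") {
          cc <- sample(names(genome$contigs), 2)
          data.frame(sample = sm, contig1 = cc[1],
                     pos1 = sample.int(genome$contigs[[cc[1]]], 1),
                     contig2 = cc[2],
                     pos2 = sample.int(genome$contigs[[cc[2]]], 1),
                     svclass = cl, stringsAsFactors = FALSE)
        } else {
          ctg <- sample(names(genome$contigs), 1)
          pp <- sort(sample.int(genome$contigs[[ctg]], 2))
          data.frame(sample = sm, contig1 = ctg, pos1 = pp[1],
                     contig2 = ctg, pos2 = pp[2], svclass = cl,
                     stringsAsFactors = FALSE)
        }
      })
      sv_all[[sm]] <- do.call(rbind, sv)
    }

    ## --- tumor-in-normal points -------------------------------------------
    tinda_points[[sm]] <- simulate_tinda_points(
      n_germline = spec$tinda$n_germline, n_somatic = spec$tinda$n_somatic,
      contamination = spec$tinda$contamination, depth = spec$tinda$depth,
      tumor_vaf = spec$tinda$tumor_vaf,
      hom_fraction = spec$tinda$hom_fraction,
      seed = (spec$seed * 1000 + si) %% 2147483647)

    ## --- telomere reads ----------------------------------------------------
    # plant telomeric reads so the content (telomeric reads per million
    # GC-matched reads) matches the spec value in expectation; the expected
    # GC-matched fraction of the i.i.d. background is binomial mass on
    # [48, 52]% at the read length
    L <- spec$telomere$read_length
    gc_rate <- sum(stats::dbinom(ceiling(0.48 * L):floor(0.52 * L), L, 0.5))
    for (kind in c("tumor", "control")) {
      content <- if (kind == "tumor") spec$telomere$content_tumor
                 else spec$telomere$content_control
      rs <- simulate_telomere_reads(
        n_telomeric = max(1, round(content * spec$telomere$n_background *
                                     gc_rate / 1e6)),
        n_background = spec$telomere$n_background,
        read_length = L,
        variant_repeat_prob = spec$telomere$variant_repeat_prob,
        seed = (spec$seed * 2000 + si * 2 + (kind == "tumor")) %% 2147483647)
      telomere_reads[[paste0(sm, ".", kind)]] <- rs$reads
      tel_truth[[paste0(sm, ".", kind)]] <- length(rs$truth)
    }
  }

  ## --- expression ----------------------------------------------------------
  ex <- spec$expression
  ig_panel <- c("IGHM", paste0("IGHG", 1:4), "IGHA1", "IGHA2", "IGHD",
                "IGHE", "IGKC", "IGLC2")
  gene_ids <- c(genes$gene_id, ig_panel)
  base_mu <- stats::setNames(
    stats::rlnorm(length(gene_ids), ex$mean_log, ex$sd_log), gene_ids)
  sig_genes <- sample(genes$gene_id[genes$biotype == "protein_coding"],
                      ex$n_signature_genes)
  counts <- matrix(0L, length(gene_ids), length(samples),
                   dimnames = list(gene_ids, samples))
  first_group <- names(spec$subgroups)[1]
  for (si in seq_along(samples)) {
    mu <- base_mu
    mu[ig_panel] <- mean(base_mu) * 0.2
    if (subgroup[si] == first_group) {
      mu["IGHM"] <- mu["IGHM"] * ex$ighm_factor
      mu[sig_genes] <- mu[sig_genes] * ex$signature_shift
    } else {
      mu["IGHG1"] <- mu["IGHG1"] * ex$ighm_factor / 2
    }
    counts[, si] <- stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / ex$dispersion)
  }
  # brain-background profile for the dilution emulator: distinct profile
  # concentrated on its own highly-expressed gene set
  bg_mu <- base_mu
  bg_mu[sample(seq_along(bg_mu), round(length(bg_mu) / 3))] <-
    mean(base_mu) * 5
  bg_mu[ig_panel] <- mean(base_mu) * 0.01
  background_profile <- stats::rnbinom(length(bg_mu), mu = bg_mu,
                                       size = 1 / ex$dispersion)
  names(background_profile) <- gene_ids
  # expression gene metadata: IG panel genes are bookkeeping entries off
  # the toy genome (contig "IG")
  gene_meta <- rbind(genes,
                     data.frame(gene_id = ig_panel, symbol = ig_panel,
                                contig = "IG", start = 0,
                                end = 1000 * seq_along(ig_panel),
                                strand = "+", biotype = "protein_coding",
                                exon_len = 1500L, stringsAsFactors = FALSE))

  truth <- list(
    kataegis = if (length(kat_truth)) do.call(rbind, kat_truth) else NULL,
    exposures = spec$exposure_props,
    arm_events = if (length(arm_truth)) do.call(rbind, arm_truth) else NULL,
    tinda = lapply(tinda_points, function(p) p$truth),
    telomere_reads = unlist(tel_truth),
    telomere_content = c(tumor = spec$telomere$content_tumor,
                         control = spec$telomere$content_control),
    signature_genes = sig_genes,
    ig_dominant = stats::setNames(
      ifelse(subgroup == first_group, "IGHM", "IGHG1"), samples))

  structure(list(genome = genome, genes = genes, gene_meta = gene_meta,
                 meta = meta,
                 variants = do.call(rbind, variants),
                 segments = do.call(rbind, seg_all),
                 svs = if (length(sv_all)) do.call(rbind, sv_all) else NULL,
                 tinda_points = tinda_points,
                 telomere_reads = telomere_reads,
                 counts = counts,
                 background_profile = background_profile,
                 truth = truth, spec = spec),
            class = "CohortBundle")
}

# carve a focal interval out of an existing per-sample segment chain,
# shifting its copy number by delta
punch_segment <- function(seg, sm, ctg, start, end, delta, jitter_sd) {
  on <- seg$sample == sm & seg$contig == ctg
  keep <- seg[!on, , drop = FALSE]
  s <- seg[on, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(s))) {
    lo <- max(s$start[i], start); hi <- min(s$end[i], end)
    if (lo >= hi) { out[[length(out) + 1L]] <- s[i, ]; next }
    if (s$start[i] < lo)
      out[[length(out) + 1L]] <- transform(s[i, ], end = lo)
    mid <- s[i, ]
    mid$start <- lo; mid$end <- hi
    mid$tcn <- max(0, mid$tcn + delta + stats::rnorm(1, 0, jitter_sd))
    mid$B <- min(mid$B, mid$tcn)
    mid$A <- max(0, mid$tcn - mid$B)
    out[[length(out) + 1L]] <- mid
    if (hi < s$end[i])
      out[[length(out) + 1L]] <- transform(s[i, ], start = hi)
  }
  res <- rbind(keep, do.call(rbind, out))
  res[order(res$sample, res$contig, res$start), , drop = FALSE]
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat("CohortBundle:", nrow(x$meta), "samples,",
      nrow(x$variants), "variant records,",
      nrow(x$segments), "CN segments,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Write a cohort bundle to disk in the standard exchange formats
#'
#' Emits per-sample VCFs, the gene panel (extended BED), segments TSV,
#' BEDPE, sample metadata TSV, counts TSV, FASTA, per-sample FASTQ read
#' sets, paired-BAF TSVs and the ground-truth ledger TSVs.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest of written files.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "fastq"), showWarnings = FALSE)
  dir.create(file.path(dir, "baf"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  for (sm in unique(bundle$variants$sample)) {
    f <- file.path(dir, "vcf", paste0(sm, ".vcf"))
    write_variants_vcf(bundle$variants[bundle$variants$sample == sm, ],
                       f, bundle$genome)
    add(f)
  }
  add(write_gene_models(bundle$genes, file.path(dir, "genes.bed")))
  add(write_segments(bundle$segments, file.path(dir, "segments.tsv")))
  if (!is.null(bundle$svs))
    add(write_bedpe(bundle$svs, file.path(dir, "svs.bedpe")))
  f <- file.path(dir, "meta.tsv")
  write.table(bundle$meta, f, sep = "\t", quote = FALSE, row.names = FALSE)
  add(f)
  add(write_matrix_tsv(bundle$counts, file.path(dir, "counts.tsv")))
  add(write_genome_fasta(bundle$genome, file.path(dir, "genome.fa")))
  f <- file.path(dir, "arms.tsv")
  write.table(genome_arms(bundle$genome), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  add(f)
  for (nm in names(bundle$telomere_reads)) {
    f <- file.path(dir, "fastq", paste0(nm, ".fastq"))
    write_fastq(bundle$telomere_reads[[nm]], f)
    add(f)
  }
  for (nm in names(bundle$tinda_points)) {
    f <- file.path(dir, "baf", paste0(nm, ".tsv"))
    write.table(bundle$tinda_points[[nm]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(f)
  }
  if (!is.null(bundle$truth$kataegis)) {
    f <- file.path(dir, "truth", "kataegis.tsv")
    write.table(bundle$truth$kataegis, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(f)
  }
  if (!is.null(bundle$truth$arm_events)) {
    f <- file.path(dir, "truth", "arm_events.tsv")
    write.table(bundle$truth$arm_events, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add(f)
  }
  invisible(files)
}
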