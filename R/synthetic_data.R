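#' Derive a per-generator substream seed from a root seed
#'
#' Every generator in the package draws its randomness from a substream
#' seed computed as `(root * 1009 + 9973 * stream) mod (2^31 - 1)`, with
#' a fixed `stream` counter per generator. Adding a generator therefore
#' never perturbs the fixtures of existing ones.
#'
#' @param root Integer root seed.
#' @param stream Small integer stream counter.
#' @return Integer seed.
#' @export
substream_seed <- function(root, stream) {
  as.integer((as.numeric(root) * 1009 + 9973 * as.numeric(stream)) %%
               2147483647)
}

.random_rna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Synthetic transcript with one planted miRNA site and a site-internal SNP
#'
#' Generates a random-background transcript carrying exactly one planted
#' seed heptamer (pairing guide nt 2-8), a single-nucleotide variant at a
#' chosen offset inside the heptamer, and a guide whose seed
#' reverse-complements the planted heptamer. Accidental seed matches in
#' the background, on either allele, are scrubbed by re-randomizing
#' their cores, so the reference allele carries exactly the planted site
#' and (for offsets that hit the 6-mer core, 2-7) the alternate allele
#' carries none.
#'
#' @param utr_len Transcript length, nt.
#' @param seed_heptamer 7-nt site sequence planted on the transcript
#'   (default the miR-224-style heptamer `GUGACUU`).
#' @param snp_offset_in_site 1-based offset of the variant inside the
#'   heptamer (1-7).
#' @param flank Number of background nt 5' of the planted heptamer; the
#'   site occupies `flank + 1 .. flank + 7`.
#' @param seed Integer seed.
#' @param alt_base Alternate allele; default picks a base breaking the
#'   seed pairing (G unless the reference base is G, else C).
#' @param gc Background GC fraction.
#' @return List with `transcript`, `variant`, `mirna`, `site_start`,
#'   `site_end`.
#' @export
synth_transcript_with_site <- function(utr_len = 2000L,
                                       seed_heptamer = "GUGACUU",
                                       snp_offset_in_site = 5L,
                                       flank = 1053L, seed = 1L,
                                       alt_base = NULL, gc = 0.5) {
  seed_heptamer <- normalize_to_rna(seed_heptamer)
  stopifnot(nchar(seed_heptamer) == 7L)
  utr_len <- as.integer(utr_len); flank <- as.integer(flank)
  snp_offset_in_site <- as.integer(snp_offset_in_site)
  if (snp_offset_in_site < 1L || snp_offset_in_site > 7L)
    stop("snp_offset_in_site must be within 1-7", call. = FALSE)
  site_start <- flank + 1L
  site_end <- flank + 7L
  if (flank < 0L || site_end > utr_len)
    stop("geometry impossible: heptamer does not fit the transcript", call. = FALSE)
  set.seed(substream_seed(seed, 1L))
  ref_base <- substr(seed_heptamer, snp_offset_in_site, snp_offset_in_site)
  if (is.null(alt_base)) alt_base <- if (ref_base == "G") "C" else "G"
  guide <- paste0("C", reverse_complement(seed_heptamer), "UAGUGGUUCCGUU")
  m <- mirna("synthetic-mir", guide)
  snp_pos <- flank + snp_offset_in_site

  build <- function() {
    s <- .random_rna(utr_len, gc)
    substr(s, site_start, site_end) <- seed_heptamer
    s
  }
  seq <- build()
  for (iter in 1:100) {
    t_ref <- transcript("synthetic-utr", seq)
    v <- variant("synthetic-utr", snp_pos, ref_base, alt_base, "rs0")
    t_alt <- apply_allele(t_ref, v, "alt")
    offending <- integer(0)
    sites_ref <- find_seed_sites(m, t_ref)
    extra <- sites_ref[!(sites_ref$start <= snp_pos & sites_ref$end >= snp_pos), ,
                       drop = FALSE]
    sites_alt <- find_seed_sites(m, t_alt)
    extra_alt <- sites_alt[!(sites_alt$start >= site_start - 1L &
                               sites_alt$end <= site_end), , drop = FALSE]
    offending <- unique(c(extra$start, extra_alt$start))
    offending <- setdiff(offending, site_start - 1L)
    if (length(offending) == 0L) break
    for (p in offending) {
      # re-randomize one background base inside the accidental core,
      # avoiding the planted interval
      cand <- setdiff(p:(p + 6L), site_start:site_end)
      cand <- cand[cand >= 1L & cand <= utr_len]
      pos <- cand[1]
      substr(seq, pos, pos) <- sample(c("A", "C", "G", "U"), 1L)
    }
    if (iter == 100L)
      stop("could not scrub accidental seed matches", call. = FALSE)
  }
  t_ref <- transcript("synthetic-utr", seq)
  v <- variant("synthetic-utr", snp_pos, ref_base, alt_base, "rs0")
  list(transcript = t_ref, variant = v, mirna = m,
       site_start = site_start, site_end = site_end)
}

#' Synthetic allelic-imbalance cohort
#'
#' Heterozygous samples whose gDNA allelic ratios are lognormal around 1
#' and whose cDNA ratios are lognormal around `fold`, both with
#' coefficient of variation `noise_cv`.
#'
#' @param n Number of samples.
#' @param fold Planted cDNA fold-imbalance (1 = null).
#' @param noise_cv Multiplicative noise CV (0 = every normalized ratio
#'   exactly `fold`).
#' @param seed Integer seed.
#' @return List of [aei_sample()] objects.
#' @export
synth_aei_cohort <- function(n = 22L, fold = 2, noise_cv = 0.10, seed = 1L) {
  stopifnot(n >= 1L, fold > 0, noise_cv >= 0)
  set.seed(substream_seed(seed, 2L))
  draw_ratio <- function(center) {
    if (noise_cv == 0) return(rep(center, n))
    sdlog <- sqrt(log(1 + noise_cv^2))
    center * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  r_g <- draw_ratio(1)
  r_c <- draw_ratio(fold)
  lapply(seq_len(n), function(i)
    aei_sample(sprintf("S%02d", i),
               signal_a_cdna = r_c[i] * 100, signal_b_cdna = 100,
               signal_a_gdna = r_g[i] * 100, signal_b_gdna = 100))
}

#' Synthetic genome tracks with configurable SNP co-occurrence
#'
#' Builds a toy single-chromosome genome with disjoint region slots for
#' TF-binding intervals, miRNA-site intervals, and co-located TF+miR
#' regions, then places SNPs so that configured fractions fall in TF-only
#' regions, miR-only regions, both, or the background. An LD table links
#' extra proxy SNPs to a subset of catalog SNPs.
#'
#' @param genome_len Genome length, bp.
#' @param n_tf,n_mir Number of TF / miR intervals.
#' @param n_snps Number of catalog SNPs.
#' @param co_occurrence Named fractions `c(tf = , mir = , both = )` of
#'   SNPs placed in TF-only, miR-only and shared regions (the remainder
#'   lands in the background).
#' @param region_width Width of every region interval, bp.
#' @param n_ld Number of LD pairs to emit.
#' @param seed Integer seed.
#' @return List with `tf` and `mir` (BED-style data.frames), `snps`
#'   (`id`, `chrom`, `pos`), `ld` (`snp_a`, `snp_b`, `r2`) and
#'   `genome_len`.
#' @export
synth_tracks <- function(genome_len = 1e6L, n_tf = 60L, n_mir = 40L,
                         n_snps = 2000L,
                         co_occurrence = c(tf = 0.15, mir = 0.05, both = 0.05),
                         region_width = 200L, n_ld = 50L, seed = 1L) {
  stopifnot(all(c("tf", "mir", "both") %in% names(co_occurrence)),
            sum(co_occurrence) <= 1)
  set.seed(substream_seed(seed, 3L))
  n_both_regions <- max(1L, min(n_tf, n_mir) %/% 2L)
  n_tf_only <- n_tf - n_both_regions
  n_mir_only <- n_mir - n_both_regions
  n_slots <- n_tf_only + n_mir_only + n_both_regions
  pitch <- genome_len %/% (n_slots + 1L)
  if (pitch <= region_width)
    stop("densities infeasible: regions do not fit the genome", call. = FALSE)
  slot_start <- (seq_len(n_slots) - 1L) * pitch + pitch %/% 4L
  slot_class <- sample(rep(c("tf", "mir", "both"),
                           c(n_tf_only, n_mir_only, n_both_regions)))
  bed <- function(classes) {
    idx <- which(slot_class %in% classes)
    data.frame(chrom = "chr1", start = slot_start[idx],
               end = slot_start[idx] + region_width,
               name = paste0(classes[1], "_", seq_along(idx)),
               score = NA_real_, stringsAsFactors = FALSE)
  }
  tf <- bed(c("tf", "both")); mir <- bed(c("mir", "both"))
  n_in <- round(n_snps * co_occurrence)
  n_bg <- n_snps - sum(n_in)
  place_in <- function(classes, count) {
    if (count == 0L) return(integer(0))
    idx <- which(slot_class %in% classes)
    slots <- sample(idx, count, replace = TRUE)
    slot_start[slots] + sample.int(region_width, count, replace = TRUE) - 1L
  }
  in_any_region <- function(pos) {
    hit <- rep(FALSE, length(pos))
    for (s in slot_start)
      hit <- hit | (pos >= s & pos < s + region_width)
    hit
  }
  bg <- integer(0)
  while (length(bg) < n_bg) {
    cand <- sample.int(genome_len, n_bg - length(bg)) - 1L
    bg <- c(bg, cand[!in_any_region(cand)])
  }
  pos <- c(place_in("tf", n_in[["tf"]]), place_in("mir", n_in[["mir"]]),
           place_in("both", n_in[["both"]]), bg)
  snps <- data.frame(id = sprintf("rs%05d", seq_along(pos)), chrom = "chr1",
                     pos = as.integer(pos), stringsAsFactors = FALSE)
  ld <- data.frame(
    snp_a = sample(snps$id, n_ld, replace = TRUE),
    snp_b = sprintf("rsP%04d", seq_len(n_ld)),
    r2 = round(runif(n_ld, 0.5, 1), 3), stringsAsFactors = FALSE)
  list(tf = tf, mir = mir, snps = snps, ld = ld, genome_len = genome_len)
}

#' Synthetic series pair with a target Pearson correlation
#'
#' Bivariate normal construction `y = r x + sqrt(1 - r^2) z` with x, z
#' independent standard normals, so the population correlation equals
#' `target_r` (exactly degenerate at +-1).
#'
#' @param n Series length, >= 3.
#' @param target_r Target correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return List with numeric vectors `x` and `y`.
#' @export
synth_correlated_series <- function(n, target_r, seed = 1L) {
  stopifnot(n >= 3L, abs(target_r) <= 1)
  set.seed(substream_seed(seed, 4L))
  x <- rnorm(n)
  z <- rnorm(n)
  y <- target_r * x + sqrt(max(0, 1 - target_r^2)) * z
  list(x = x, y = y)
}

#' Write a synthetic fixture directory
#'
#' Materializes the generators as files (FASTA/BED/TSV) plus a manifest
#' JSON recording the configuration and seed, so a whole pipeline run is
#' reproducible from disk.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @param utr_len,aei_n,aei_fold,aei_noise_cv,genome_len Generator knobs
#'   passed through.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_dir <- function(dir, seed = 1L, utr_len = 2000L, aei_n = 22L,
                              aei_fold = 2, aei_noise_cv = 0.10,
                              genome_len = 1e6L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syn <- synth_transcript_with_site(utr_len = utr_len,
                                    flank = utr_len %/% 2L - 4L, seed = seed)
  write_fasta(list(syn$transcript), file.path(dir, "utr.fa"))
  write_fasta(list(transcript(syn$mirna$id, syn$mirna$guide)),
              file.path(dir, "mirna.fa"))
  v <- syn$variant
  write.table(data.frame(transcript_id = v$transcript_id, pos = v$pos,
                         ref = v$ref, alt = v$alt, rsid = v$rsid),
              file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cohort <- synth_aei_cohort(aei_n, aei_fold, aei_noise_cv, seed)
  aei_df <- do.call(rbind, lapply(cohort, function(s)
    data.frame(sample_id = s$sample_id, signal_a_cdna = s$signal_a_cdna,
               signal_b_cdna = s$signal_b_cdna, signal_a_gdna = s$signal_a_gdna,
               signal_b_gdna = s$signal_b_gdna)))
  write.table(aei_df, file.path(dir, "aei.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tracks <- synth_tracks(genome_len = genome_len, seed = seed)
  write_bed(tracks$tf, file.path(dir, "tf.bed"))
  write_bed(tracks$mir, file.path(dir, "mir.bed"))
  write.table(tracks$snps, file.path(dir, "snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tracks$ld, file.path(dir, "ld.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(seed = seed, utr_len = utr_len, aei_n = aei_n,
                   aei_fold = aei_fold, aei_noise_cv = aei_noise_cv,
                   genome_len = genome_len,
                   site_start = syn$site_start, site_end = syn$site_end)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
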