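#' Read a linkage-disequilibrium pair table
#'
#' TSV columns `snp_a`, `snp_b`, `r2`; pairs are symmetrized on load and
#' r-squared values outside \[0, 1\] are errors.
#'
#' @param path TSV path with header.
#' @return Data.frame with columns `snp_a`, `snp_b`, `r2` containing both
#'   orientations of every pair.
#' @export
read_ld_table <- function(path) {
  df <- read_table_schema(path, c(snp_a = "character", snp_b = "character",
                                  r2 = "numeric"))
  if (any(df$r2 < 0 | df$r2 > 1))
    stop(path, ": r2 values must lie in [0, 1]", call. = FALSE)
  sym <- rbind(df[, c("snp_a", "snp_b", "r2")],
               setNames(df[, c("snp_b", "snp_a", "r2")],
                        c("snp_a", "snp_b", "r2")))
  unique(sym)
}

#' Expand a SNP set with LD proxies
#'
#' Adds, in a single hop, every partner whose r-squared with a member of
#' the input set is strictly greater than `r2_min` (no transitive
#' closure). Monotone (output contains input) and idempotent for a fixed
#' table.
#'
#' @param snps Character vector of SNP ids.
#' @param ld LD table as from [read_ld_table()] (any data.frame with
#'   `snp_a`, `snp_b`, `r2`; treated as symmetric).
#' @param r2_min Threshold; partners are added when `r2 > r2_min`
#'   (default 0.8, strict inequality).
#' @return Character vector: the expanded SNP set (unique, input order
#'   first).
#' @export
expand_ld <- function(snps, ld, r2_min = 0.8) {
  stopifnot(r2_min >= 0, r2_min <= 1)
  if (is.null(ld) || nrow(ld) == 0L) return(unique(as.character(snps)))
  hits <- ld$r2 > r2_min & (ld$snp_a %in% snps | ld$snp_b %in% snps)
  partners <- unique(c(ld$snp_a[hits], ld$snp_b[hits]))
  unique(c(as.character(snps), partners))
}

#' Flag SNPs overlapping a track
#'
#' A SNP occupies the single base `[pos, pos + 1)` in BED coordinates
#' (`pos` 0-based); it overlaps a track interval `[start, end)` iff
#' `start <= pos < end`. Chromosome names must match exactly; SNPs on
#' chromosomes absent from the track are non-overlaps.
#'
#' @param snps Data.frame with columns `id`, `chrom`, `pos` (0-based).
#' @param track Data.frame of intervals as from [read_bed()].
#' @return Logical vector parallel to `snps` rows.
#' @export
snps_in_track <- function(snps, track) {
  out <- logical(nrow(snps))
  if (nrow(track) == 0L || nrow(snps) == 0L) return(out)
  for (chr in unique(snps$chrom)) {
    si <- which(snps$chrom == chr)
    ti <- which(track$chrom == chr)
    if (length(ti) == 0L) next
    q <- IRanges::IRanges(start = snps$pos[si] + 1L, width = 1L)
    s <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    out[si] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Venn summary of a SNP set against TF and miRNA tracks
#'
#' Counts SNPs falling in transcription-factor binding regions, in
#' predicted miRNA binding sites, and in both, with fractions
#' denominated by the total SNP count. `n_in_tf` / `n_in_mir` include
#' the double-counted `n_in_both` members, matching a Venn read-out.
#'
#' @param snps SNP data.frame (`id`, `chrom`, `pos`).
#' @param tf_track,mir_track Interval data.frames as from [read_bed()].
#' @return List of class `overlap_summary` with `n_snps`, `n_in_tf`,
#'   `n_in_mir`, `n_in_both`, `frac_in_tf`, `frac_in_mir`,
#'   `frac_in_both`.
#' @export
overlap_venn <- function(snps, tf_track, mir_track) {
  in_tf <- snps_in_track(snps, tf_track)
  in_mir <- snps_in_track(snps, mir_track)
  n <- nrow(snps)
  res <- list(n_snps = n,
              n_in_tf = sum(in_tf), n_in_mir = sum(in_mir),
              n_in_both = sum(in_tf & in_mir))
  res$frac_in_tf <- if (n) res$n_in_tf / n else 0
  res$frac_in_mir <- if (n) res$n_in_mir / n else 0
  res$frac_in_both <- if (n) res$n_in_both / n else 0
  structure(res, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "<overlap summary: %d SNPs; TF %d (%.2f%%), miR %d (%.2f%%), both %d (%.2f%%)>\n",
    x$n_snps, x$n_in_tf, 100 * x$frac_in_tf, x$n_in_mir,
    100 * x$frac_in_mir, x$n_in_both, 100 * x$frac_in_both))
  invisible(x)
}

#' Fraction of site intervals with any overlap against another track
#'
#' Secondary statistic: proportion of `sites` intervals sharing at least
#' one base with any `track` interval.
#'
#' @param sites,track Interval data.frames as from [read_bed()].
#' @return Fraction in \[0, 1\].
#' @export
sites_overlapping_track <- function(sites, track) {
  if (nrow(sites) == 0L) return(0)
  hit <- logical(nrow(sites))
  for (chr in unique(sites$chrom)) {
    si <- which(sites$chrom == chr)
    ti <- which(track$chrom == chr)
    if (length(ti) == 0L) next
    q <- IRanges::IRanges(start = sites$start[si] + 1L, end = sites$end[si])
    s <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    hit[si] <- IRanges::overlapsAny(q, s)
  }
  mean(hit)
}

#' Binomial enrichment of region hits against a genome background
#'
#' Upper-tail probability that at least `n_hits` of `n_regions` test
#' regions fall in an annotation covering fraction `f` of the background
#' genome: `p = P(X >= n_hits)`, X ~ Binomial(n_regions, f). For
#' `n_regions <= 1e4` the tail is summed term by term from the exact
#' probability mass; above that a numerically stable upper-tail
#' computation is used.
#'
#' @param n_regions Number of test regions.
#' @param n_hits Number of regions hitting the annotation,
#'   `0 <= n_hits <= n_regions`.
#' @param f Background fraction in \[0, 1\].
#' @return List of class `enrichment_result`: `n_regions`, `n_hits`,
#'   `background_fraction`, `p_binomial` (1 when `n_hits` = 0).
#' @export
binomial_enrichment <- function(n_regions, n_hits, f) {
  stopifnot(n_hits >= 0, n_hits <= n_regions, f >= 0, f <= 1)
  p <- if (n_hits == 0) 1
  else if (n_regions <= 1e4) sum(dbinom(n_hits:n_regions, n_regions, f))
  else pbinom(n_hits - 1, n_regions, f, lower.tail = FALSE)
  structure(list(n_regions = n_regions, n_hits = n_hits,
                 background_fraction = f, p_binomial = min(p, 1)),
            class = "enrichment_result")
}

#' Read a SNP catalog TSV (id, chrom, pos)
#' @param path TSV path with header; `pos` is the 0-based base position.
#' @return Data.frame with columns `id`, `chrom`, `pos`.
#' @export
read_snp_table <- function(path) {
  read_table_schema(path, c(id = "character", chrom = "character",
                            pos = "integer"))
}

#' Full overlap report: LD expansion, Venn, enrichment
#'
#' The desk-scale version of the genome-wide analysis: expand the SNP
#' catalog with LD proxies, intersect with the TF and miRNA tracks, and
#' attach binomial enrichment p-values for each overlap class using the
#' track's genome coverage as the background fraction.
#'
#' @param snps SNP data.frame (`id`, `chrom`, `pos`).
#' @param ld LD table (or NULL to skip expansion).
#' @param tf_track,mir_track Interval data.frames.
#' @param genome_len Total background genome length in bp.
#' @param r2_min LD threshold (strict), default 0.8.
#' @return List with `snp_ids` (expanded set actually scored), `venn`
#'   (an `overlap_summary`), and `enrichment`: list of
#'   `enrichment_result` for `tf`, `mir`, `both`.
#' @export
overlap_report <- function(snps, ld, tf_track, mir_track, genome_len,
                           r2_min = 0.8) {
  ids <- expand_ld(snps$id, ld, r2_min)
  scored <- snps[snps$id %in% ids, , drop = FALSE]
  venn <- overlap_venn(scored, tf_track, mir_track)
  cover <- function(track) {
    if (nrow(track) == 0L) return(0)
    covered <- sum(vapply(unique(track$chrom), function(chr) {
      ti <- track$chrom == chr
      r <- IRanges::reduce(IRanges::IRanges(start = track$start[ti] + 1L,
                                            end = track$end[ti]))
      sum(IRanges::width(r))
    }, numeric(1)))
    min(covered / genome_len, 1)
  }
  f_tf <- cover(tf_track); f_mir <- cover(mir_track)
  enrichment <- list(
    tf = binomial_enrichment(venn$n_snps, venn$n_in_tf, f_tf),
    mir = binomial_enrichment(venn$n_snps, venn$n_in_mir, f_mir),
    both = binomial_enrichment(venn$n_snps, venn$n_in_both, f_tf * f_mir))
  list(snp_ids = scored$id, venn = venn, enrichment = enrichment)
}
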