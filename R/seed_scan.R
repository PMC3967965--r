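#' Reverse complement of an RNA string
#' @param seq RNA string.
#' @return Reverse complement, RNA alphabet.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_to_rna(seq)
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

.SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Classify a canonical seed-site type from its match flags
#'
#' Canonical site taxonomy from the four elementary observations: a
#' perfect Watson-Crick match to miRNA nt 2-8 (`match28`), to nt 2-7
#' (`match27`), an adenosine on the target opposite miRNA nt 1
#' (`a_at_t1`), and a match opposite nt 8 alone (`match_m8`).
#'
#' @param match28,match27,a_at_t1,match_m8 Logical flags.
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, or `NA`
#'   when no canonical site is formed.
#' @export
classify_site_type <- function(match28, match27, a_at_t1, match_m8) {
  if (match28 && !match27)
    stop("inconsistent flags: match28 implies match27", call. = FALSE)
  if (match28 && a_at_t1) return("8mer")
  if (match28) return("7mer-m8")
  if (match27 && a_at_t1 && !match_m8) return("7mer-A1")
  if (match27) return("6mer")
  NA_character_
}

#' Find canonical miRNA seed sites on a transcript
#'
#' Scans for exact Watson-Crick complementarity (no G:U wobble) between
#' the miRNA seed (guide nt 2-7/2-8) and the transcript. Each matched
#' locus is reported once with its single best site type under the
#' hierarchy 8mer > 7mer-m8 > 7mer-A1 > 6mer. The seed interval pairs
#' miRNA nt 2-8 (7 nt; 8mer and 7mer-m8) or nt 2-7 (6 nt; 7mer-A1 and
#' 6mer). `t1_pos` is the transcript position opposite guide nt 1 (NA
#' when the site abuts the transcript 3' end, in which case 8mer/7mer-A1
#' are unavailable).
#'
#' @param m A [mirna()].
#' @param t A [transcript()].
#' @param types Site types to report (default all four).
#' @return Data.frame with columns `mirna_id`, `transcript_id`,
#'   `site_type`, `start`, `end`, `t1_pos`, sorted by `start`; zero rows
#'   when nothing matches.
#' @export
find_seed_sites <- function(m, t, types = .SITE_TYPES) {
  stopifnot(inherits(m, "mirna"), inherits(t, "transcript"))
  types <- match.arg(types, .SITE_TYPES, several.ok = TRUE)
  n <- t$length
  core <- reverse_complement(substr(m$guide, 2L, 7L))  # pairs guide nt 2-7
  m8_target <- reverse_complement(substr(m$guide, 8L, 8L))
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      site_type = character(), start = integer(),
                      end = integer(), t1_pos = integer(),
                      stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  starts <- which(vapply(seq_len(n - 5L),
                         function(i) substr(t$seq, i, i + 5L) == core,
                         logical(1)))
  if (length(starts) == 0L) return(empty)
  rows <- lapply(starts, function(a) {
    match_m8 <- a > 1L && substr(t$seq, a - 1L, a - 1L) == m8_target
    t1 <- if (a + 6L <= n) a + 6L else NA_integer_
    a_at_t1 <- !is.na(t1) && substr(t$seq, t1, t1) == "A"
    type <- classify_site_type(match_m8, TRUE, a_at_t1, match_m8)
    if (!(type %in% types)) return(NULL)
    seven <- type %in% c("8mer", "7mer-m8")
    data.frame(mirna_id = m$id, transcript_id = t$id, site_type = type,
               start = if (seven) a - 1L else a, end = a + 5L,
               t1_pos = t1, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' How a variant changes a miRNA's seed sites
#'
#' Runs [find_seed_sites()] on both allele sequences, restricted to sites
#' whose seed interval contains the variant position, and classifies the
#' outcome: `disrupted_by_alt` (site on ref only), `created_by_alt` (site
#' on alt only), `unaffected` (site on both, or sites exist but none
#' touches the variant), `absent` (the transcript carries no site for
#' this miRNA on either allele).
#'
#' @param m A [mirna()].
#' @param t A [transcript()] carrying the reference allele.
#' @param v A [variant()] on `t`.
#' @param types Site types considered (default all four).
#' @return List of class `allelic_site_effect` with fields `variant`,
#'   `mirna_id`, `ref_match`, `alt_match`, `verdict`, `ref_sites`,
#'   `alt_sites`.
#' @export
allelic_site_effect <- function(m, t, v, types = .SITE_TYPES) {
  t_ref <- apply_allele(t, v, "ref")
  t_alt <- apply_allele(t, v, "alt")
  ref_all <- find_seed_sites(m, t_ref, types)
  alt_all <- find_seed_sites(m, t_alt, types)
  touches <- function(sites) sites[sites$start <= v$pos & sites$end >= v$pos, ,
                                   drop = FALSE]
  ref_sites <- touches(ref_all); alt_sites <- touches(alt_all)
  ref_match <- nrow(ref_sites) > 0L
  alt_match <- nrow(alt_sites) > 0L
  verdict <- if (ref_match && alt_match) "unaffected"
  else if (ref_match) "disrupted_by_alt"
  else if (alt_match) "created_by_alt"
  else if (nrow(ref_all) + nrow(alt_all) > 0L) "unaffected"
  else "absent"
  structure(list(variant = v, mirna_id = m$id, ref_match = ref_match,
                 alt_match = alt_match, verdict = verdict,
                 ref_sites = ref_sites, alt_sites = alt_sites),
            class = "allelic_site_effect")
}

#' @export
print.allelic_site_effect <- function(x, ...) {
  cat(sprintf("<allelic site effect %s x %s@%d%s>%s: ref_match=%s alt_match=%s -> %s\n",
              x$mirna_id, x$variant$transcript_id, x$variant$pos,
              paste0(x$variant$ref, ">", x$variant$alt), "",
              x$ref_match, x$alt_match, x$verdict))
  invisible(x)
}
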