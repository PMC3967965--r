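#' mirallele: allele-specific microRNA target site analysis
#'
#' Data model and algorithms for asking how a 3'-UTR SNP changes microRNA
#' regulation: seed-site scanning per allele, MFE secondary structure over
#' moving windows, duplex/accessibility energetics, annealing kinetics,
#' allelic-imbalance statistics and genome-track overlap enrichment.
#'
#' @useDynLib mirallele, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm optim rbinom residuals rlnorm rnorm runif
#'   dbinom pbinom qt sd t.test cor.test setNames
#' @importFrom utils read.delim write.table
#' @keywords internal
"_PACKAGE"

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U and strips whitespace. Any character other
#' than ACGTU (either case) or whitespace is an error naming the first
#' offending position (counted in the non-whitespace sequence).
#'
#' @param raw Character scalar.
#' @return Character scalar over the ACGU alphabet.
#' @examples
#' normalize_to_rna("acgt")   # "ACGU"
#' @export
normalize_to_rna <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[ \t\r\n]", "", raw)
  s <- toupper(s)
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0L) {
    stop(sprintf("invalid alphabet: character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  chartr("T", "U", s)
}

#' Construct a transcript
#'
#' A transcript is an identified RNA sequence; all positions are 1-based,
#' inclusive, counted from the 5' end.
#'
#' @param id Character scalar identifier.
#' @param seq Nucleotide string; normalized via [normalize_to_rna()].
#' @return An object of class `transcript` with fields `id`, `seq`, `length`.
#' @export
transcript <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_to_rna(seq)
  if (!nzchar(seq)) stop("transcript sequence is empty", call. = FALSE)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s: %d nt>\n", x$id, x$length))
  invisible(x)
}

#' Construct a variant record
#'
#' A single-nucleotide substitution on a transcript, e.g. the C>G change at
#' position 1058 of a 3'-UTR. Positions are 1-based on the transcript.
#'
#' @param transcript_id Transcript identifier the variant belongs to.
#' @param pos 1-based position.
#' @param ref,alt Single reference/alternate bases (RNA alphabet; T accepted).
#' @param rsid Variant identifier, stored verbatim.
#' @return An object of class `variant`.
#' @export
variant <- function(transcript_id, pos, ref, alt, rsid = NA_character_) {
  ref <- normalize_to_rna(ref); alt <- normalize_to_rna(alt)
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  pos <- as.integer(pos)
  stopifnot(length(pos) == 1L, !is.na(pos), pos >= 1L)
  if (ref == alt) stop("variant ref and alt alleles are identical", call. = FALSE)
  structure(list(transcript_id = as.character(transcript_id), pos = pos,
                 ref = ref, alt = alt, rsid = as.character(rsid)),
            class = "variant")
}

#' Construct a microRNA
#'
#' @param id Identifier.
#' @param guide Guide strand, 5'->3'; must be at least 8 nt so that seed
#'   positions 2-8 exist.
#' @param passenger Optional passenger strand.
#' @return An object of class `mirna`.
#' @export
mirna <- function(id, guide, passenger = NULL) {
  guide <- normalize_to_rna(guide)
  if (nchar(guide) < 8L)
    stop("miRNA guide must be at least 8 nt (seed positions 2-8)", call. = FALSE)
  if (!is.null(passenger)) passenger <- normalize_to_rna(passenger)
  structure(list(id = as.character(id), guide = guide, passenger = passenger),
            class = "mirna")
}

#' Check a variant against its transcript
#' @param t A `transcript`.
#' @param v A `variant`.
#' @return Invisibly TRUE; errors on mismatch.
#' @export
check_variant <- function(t, v) {
  stopifnot(inherits(t, "transcript"), inherits(v, "variant"))
  if (v$pos > t$length)
    stop(sprintf("variant position %d beyond transcript length %d",
                 v$pos, t$length), call. = FALSE)
  have <- substr(t$seq, v$pos, v$pos)
  if (have != v$ref)
    stop(sprintf(
      "reference check failed: transcript %s has %s at position %d, variant says %s",
      t$id, have, v$pos, v$ref), call. = FALSE)
  invisible(TRUE)
}

#' Apply one allele of a variant to a transcript
#'
#' `which = "ref"` returns the transcript unchanged (after the reference
#' check); `which = "alt"` substitutes the alternate base at the variant
#' position.
#'
#' @param t A `transcript`.
#' @param v A `variant` whose `ref` matches `t` at `v$pos`.
#' @param which `"ref"` or `"alt"`.
#' @return A `transcript` carrying the requested allele.
#' @export
apply_allele <- function(t, v, which = c("ref", "alt")) {
  which <- match.arg(which)
  check_variant(t, v)
  if (which == "ref") return(t)
  s <- t$seq
  substr(s, v$pos, v$pos) <- v$alt
  transcript(t$id, s)
}

#' Read transcripts from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet (DNA input is converted
#' T->U). Duplicate record ids and empty files are errors.
#'
#' @param path FASTA file path.
#' @return List of `transcript` objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mapply(function(id, s) transcript(id, s),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write transcripts to a FASTA file
#' @param transcripts List of `transcript` objects.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(transcripts, path) {
  seqs <- vapply(transcripts, function(t) t$seq, "")
  ids <- vapply(transcripts, function(t) t$id, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' BED convention: 0-based, half-open `[start, end)`. Strand, if present,
#' is ignored (tracks are treated as unstranded regions). Malformed lines
#' (non-numeric coordinates, start >= end) are errors naming the line.
#'
#' @param path BED file path (no header).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score` (`name`/`score` NA when absent). Zero rows for an empty file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d has fewer than 3 columns", path, i), call. = FALSE)
    start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("%s: line %d has non-integer coordinates", path, i), call. = FALSE)
    if (start >= end)
      stop(sprintf("%s: line %d has start >= end (%d >= %d)", path, i, start, end),
           call. = FALSE)
    out[[i]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4L) f[4] else NA_character_,
      score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write genomic intervals to a BED file
#' @param bed Data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_bed <- function(bed, path) {
  cols <- c("chrom", "start", "end")
  extra <- intersect(c("name", "score"), names(bed))
  keep <- bed[, c(cols, extra), drop = FALSE]
  if ("name" %in% extra && all(is.na(keep$name))) keep$name <- NULL
  if ("score" %in% names(keep) && all(is.na(keep$score))) keep$score <- NULL
  write.table(keep, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a headered TSV with schema validation
#'
#' @param path TSV path; first row is a header.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"numeric"`). Extra columns pass
#'   through untouched.
#' @return Data.frame with at least the schema columns, coerced to type.
#' @export
read_table_schema <- function(path, schema) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(path, ": missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in names(schema)) {
    coerce <- switch(schema[[col]],
                     character = as.character, integer = as.integer,
                     numeric = as.numeric,
                     stop("unknown schema type: ", schema[[col]]))
    val <- suppressWarnings(coerce(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: line %d: column '%s' is not %s", path, bad[1] + 1L,
                   col, schema[[col]]), call. = FALSE)
    df[[col]] <- val
  }
  df
}

#' Read a variants TSV (transcript_id, pos, ref, alt, rsid)
#' @param path TSV path with header.
#' @return List of `variant` objects.
#' @export
read_variants <- function(path) {
  df <- read_table_schema(path, c(transcript_id = "character", pos = "integer",
                                  ref = "character", alt = "character",
                                  rsid = "character"))
  lapply(seq_len(nrow(df)), function(i)
    variant(df$transcript_id[i], df$pos[i], df$ref[i], df$alt[i], df$rsid[i]))
}
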