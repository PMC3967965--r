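#' Moving-window scheme for SNP-centered structure ensembles
#'
#' The ensemble design slides each window size across the SNP so the
#' variant sits at every multiple of the step within the window. The
#' default grid (sizes 100/200/400/800 nt, steps 10/10/20/20 nt) yields
#' 90 windows per allele, 180 over both alleles.
#'
#' @param sizes Window sizes in nt.
#' @param steps Per-size step in nt (the default grid uses steps in the
#'   customary 10-25 nt range).
#' @param description Free-text label.
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(sizes = c(100L, 200L, 400L, 800L),
                          steps = c(10L, 10L, 20L, 20L),
                          description = "default moving-segment grid") {
  sizes <- as.integer(sizes); steps <- as.integer(steps)
  stopifnot(length(sizes) == length(steps), all(sizes > 0L), all(steps > 0L))
  structure(list(sizes = sizes, steps = steps, description = description),
            class = "window_scheme")
}

#' Enumerate SNP-containing windows
#'
#' For each size `s` with step `d`, windows place the SNP at internal
#' offsets `d, 2d, ..., <= s`, i.e. `floor(s/d)` windows per size. Each
#' window maps to transcript coordinates `[pos - offset + 1,
#' pos - offset + s]`; windows that would extend past the transcript are
#' errors, not clipped (unequal windows would break the paired allele
#' comparison).
#'
#' @param t A [transcript()].
#' @param v A [variant()] on `t`.
#' @param scheme A [window_scheme()].
#' @return Data.frame with columns `size`, `step`, `snp_offset`, `start`,
#'   `end` (1-based inclusive transcript interval).
#' @export
enumerate_windows <- function(t, v, scheme = window_scheme()) {
  check_variant(t, v)
  out <- list()
  for (w in seq_along(scheme$sizes)) {
    s <- scheme$sizes[w]; d <- scheme$steps[w]
    if (d > s) next  # step wider than the window: no offset fits
    offsets <- seq.int(d, s, by = d)
    for (off in offsets) {
      start <- v$pos - off + 1L
      end <- start + s - 1L
      if (start < 1L || end > t$length)
        stop(sprintf(
          "window size %d, snp_offset %d spans [%d,%d], outside transcript %s (1..%d)",
          s, off, start, end, t$id, t$length), call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(size = s, step = d,
                                            snp_offset = off,
                                            start = start, end = end)
    }
  }
  if (!length(out))
    return(data.frame(size = integer(), step = integer(),
                      snp_offset = integer(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

#' Fold the window ensemble for both alleles
#'
#' Folds every window of the scheme on the ref- and alt-allele sequences
#' over identical transcript coordinates, giving a paired per-window
#' comparison.
#'
#' @param t A [transcript()].
#' @param v A [variant()].
#' @param scheme A [window_scheme()].
#' @param model An [energy_model()].
#' @return List with `windows` (the [enumerate_windows()] table) and
#'   `structures`: named list `ref`/`alt`, each a list of
#'   `secondary_structure` parallel to the window table.
#' @export
fold_ensemble <- function(t, v, scheme = window_scheme(),
                          model = energy_model()) {
  windows <- enumerate_windows(t, v, scheme)
  alleles <- list(ref = apply_allele(t, v, "ref"),
                  alt = apply_allele(t, v, "alt"))
  structures <- lapply(alleles, function(ta) {
    lapply(seq_len(nrow(windows)), function(i) {
      mfe_fold(substr(ta$seq, windows$start[i], windows$end[i]), model)
    })
  })
  structure(list(windows = windows, structures = structures,
                 variant = v, transcript_id = t$id),
            class = "fold_ensemble")
}

#' Loop/stem summary of the SNP position across an ensemble
#'
#' Binary classification per window: the SNP base is `stem` when paired
#' and `loop` otherwise (hairpin, internal/bulge, multiloop and exterior
#' contexts all count as loop).
#'
#' @param ensemble A [fold_ensemble()] result.
#' @return Data.frame, one row per allele, with columns `allele` (base),
#'   `which` (ref/alt), `n_windows`, `n_loop`, `n_stem`, `fraction_loop`.
#' @export
snp_context_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "fold_ensemble"))
  v <- ensemble$variant
  windows <- ensemble$windows
  rows <- lapply(c("ref", "alt"), function(which) {
    structs <- ensemble$structures[[which]]
    paired <- vapply(seq_len(nrow(windows)), function(i) {
      structs[[i]]$partner[windows$snp_offset[i]] != 0L
    }, logical(1))
    data.frame(allele = if (which == "ref") v$ref else v$alt, which = which,
               n_windows = length(paired), n_loop = sum(!paired),
               n_stem = sum(paired),
               fraction_loop = mean(!paired), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of a site left unpaired by a structure
#'
#' @param s A `secondary_structure` over a window sequence.
#' @param site_start,site_end 1-based inclusive interval in window
#'   coordinates.
#' @return Fraction of site nucleotides unpaired, in \[0, 1\].
#' @export
site_accessibility <- function(s, site_start, site_end) {
  stopifnot(inherits(s, "secondary_structure"))
  n <- length(s$partner)
  if (site_start < 1L || site_end > n || site_start > site_end)
    stop("site interval outside window", call. = FALSE)
  idx <- site_start:site_end
  mean(s$partner[idx] == 0L)
}

#' Read a cleavage-probing table
#'
#' TSV columns: `allele`, `position` (1-based transcript nt), `reagent`
#' (`Pb` or `T1`), `strength` (`weak`/`strong`).
#'
#' @param path TSV path with header.
#' @return Data.frame of cleavage records.
#' @export
read_cleavage_table <- function(path) {
  df <- read_table_schema(path, c(allele = "character", position = "integer",
                                  reagent = "character",
                                  strength = "character"))
  bad <- !df$reagent %in% c("Pb", "T1")
  if (any(bad)) stop(path, ": reagent must be Pb or T1", call. = FALSE)
  bad <- !df$strength %in% c("weak", "strong")
  if (any(bad)) stop(path, ": strength must be weak or strong", call. = FALSE)
  df
}

#' Concordance of a predicted structure with cleavage probing
#'
#' Pb(2+) cleaves any unpaired residue, so a Pb record is concordant iff
#' the predicted structure leaves that position unpaired. RNase T1
#' cleaves only unpaired G residues: a T1 record is concordant iff the
#' position is predicted unpaired and the residue is G; a T1 record on a
#' non-G residue is flagged invalid and excluded from the denominator.
#'
#' @param s A `secondary_structure` over a window.
#' @param cleavages Data.frame as from [read_cleavage_table()] (already
#'   filtered to one allele).
#' @param window_offset Transcript position of window nt 1 minus 1; i.e.
#'   window position = transcript position - `window_offset`.
#' @return List with `n_concordant`, `n_total`, `fraction` and a
#'   `records` data.frame carrying per-record `verdict`
#'   (`concordant` / `discordant` / `invalid`).
#' @export
probing_concordance <- function(s, cleavages, window_offset = 0L) {
  stopifnot(inherits(s, "secondary_structure"))
  n <- length(s$partner)
  wpos <- cleavages$position - as.integer(window_offset)
  if (any(wpos < 1L | wpos > n))
    stop("cleavage position outside window", call. = FALSE)
  bases <- strsplit(s$seq, "")[[1]]
  verdict <- character(nrow(cleavages))
  for (i in seq_len(nrow(cleavages))) {
    p <- wpos[i]
    unpaired <- s$partner[p] == 0L
    if (cleavages$reagent[i] == "Pb") {
      verdict[i] <- if (unpaired) "concordant" else "discordant"
    } else { # T1
      if (bases[p] != "G") verdict[i] <- "invalid"
      else verdict[i] <- if (unpaired) "concordant" else "discordant"
    }
  }
  records <- cbind(cleavages, window_pos = wpos, verdict = verdict,
                   stringsAsFactors = FALSE)
  n_total <- sum(verdict != "invalid")
  n_conc <- sum(verdict == "concordant")
  list(n_concordant = n_conc, n_total = n_total,
       fraction = if (n_total > 0L) n_conc / n_total else NA_real_,
       records = records)
}

#' Per-window ensemble report table
#'
#' Flat table of the ensemble: allele, window geometry, MFE energy, SNP
#' context (binary loop/stem plus the detailed [pair_context()] label)
#' and, optionally, accessibility of a site interval.
#'
#' @param ensemble A [fold_ensemble()] result.
#' @param site_start,site_end Optional 1-based transcript interval whose
#'   accessibility is profiled per window (NA where the site is not fully
#'   inside a window).
#' @return Data.frame, one row per (allele, window).
#' @export
ensemble_report <- function(ensemble, site_start = NULL, site_end = NULL) {
  windows <- ensemble$windows
  v <- ensemble$variant
  rows <- lapply(c("ref", "alt"), function(which) {
    structs <- ensemble$structures[[which]]
    df <- windows
    df$which <- which
    df$allele <- if (which == "ref") v$ref else v$alt
    df$energy <- vapply(structs, function(s) s$energy, numeric(1))
    df$snp_detail <- vapply(seq_len(nrow(windows)), function(i)
      pair_context(structs[[i]], windows$snp_offset[i]), character(1))
    df$snp_context <- ifelse(df$snp_detail == "stem", "stem", "loop")
    if (!is.null(site_start)) {
      df$site_accessibility <- vapply(seq_len(nrow(windows)), function(i) {
        a <- site_start - windows$start[i] + 1L
        b <- site_end - windows$start[i] + 1L
        if (a < 1L || b > windows$size[i]) NA_real_
        else site_accessibility(structs[[i]], a, b)
      }, numeric(1))
    }
    df
  })
  do.call(rbind, rows)
}
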