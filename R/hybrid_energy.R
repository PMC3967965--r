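#' Hybridization energy of a miRNA guide with a target site
#'
#' Nearest-neighbor free energy of the antiparallel RNA:RNA hybrid formed
#' by the guide (5'->3') and the site (5'->3'): guide nt k is aligned
#' opposite site nt `L - k + 1`. Watson-Crick and G:U pairs contribute
#' stacking terms over consecutive paired positions; an internal mismatch
#' of m aligned positions is scored as a symmetric internal loop of 2m nt
#' (a single mismatch is a 1x1 internal loop); unpaired overhanging ends
#' are free; the duplex initiation penalty is added once. If no position
#' can pair at all the function returns 0 (no hybridization).
#'
#' @param m A [mirna()] (or plain guide string).
#' @param site Site sequence, 5'->3' (transcript strand).
#' @param model An [energy_model()].
#' @param region `"full"` hybridizes the whole guide against the site;
#'   `"seed"` restricts to guide nt 2-8 against the site 3' heptamer.
#' @return Energy in kcal/mol (duplex initiation included; more negative
#'   = more stable).
#' @export
duplex_energy <- function(m, site, model = energy_model(),
                          region = c("full", "seed")) {
  region <- match.arg(region)
  guide <- if (inherits(m, "mirna")) m$guide else normalize_to_rna(m)
  site <- normalize_to_rna(site)
  if (!nzchar(site)) stop("empty site sequence", call. = FALSE)
  if (region == "seed") {
    guide <- substr(guide, 2L, 8L)
    site <- substr(site, max(1L, nchar(site) - 6L), nchar(site))
  }
  Lg <- nchar(guide); Ls <- nchar(site)
  L <- min(Lg, Ls)
  g <- strsplit(guide, "")[[1]]
  s <- strsplit(site, "")[[1]]
  # aligned columns k = 1..L: guide[k] opposite site[Ls - k + 1]
  ptypes <- vapply(seq_len(L),
                   function(k) {
                     pt <- pair_type(g[k], s[Ls - k + 1L])
                     if (is.na(pt)) "" else pt
                   }, character(1))
  paired <- nzchar(ptypes)
  if (!any(paired)) return(0)
  e <- model$duplex_init
  idx <- which(paired)
  for (w in seq_len(length(idx) - 1L)) {
    k1 <- idx[w]; k2 <- idx[w + 1L]
    gap <- k2 - k1 - 1L
    if (gap == 0L) {
      e <- e + model$stack[ptypes[k1], ptypes[k2]]
    } else {
      # symmetric internal loop: gap unpaired nt on each strand
      e <- e + internal_penalty(model, 2L * gap)
    }
  }
  e
}

#' Energetic cost of opening a target site
#'
#' Free-energy penalty of forcing every nucleotide of the site interval
#' to be single-stranded in the window's MFE structure:
#' `energy(constrained fold) - energy(unconstrained fold)`. Non-negative
#' by constraint monotonicity; 0 when the MFE structure already leaves
#' the site unpaired.
#'
#' @param window_seq RNA sequence of the window (or a `transcript`).
#' @param site_start,site_end 1-based inclusive site interval in window
#'   coordinates.
#' @param model An [energy_model()].
#' @return `dG_open` in kcal/mol, >= 0.
#' @export
site_open_penalty <- function(window_seq, site_start, site_end,
                              model = energy_model()) {
  seq <- if (inherits(window_seq, "transcript")) window_seq$seq
         else normalize_to_rna(window_seq)
  n <- nchar(seq)
  if (site_start < 1L || site_end > n || site_start > site_end)
    stop("site interval outside window", call. = FALSE)
  unconstrained <- mfe_fold(seq, model)
  constrained <- mfe_fold(seq, model, constraints = site_start:site_end)
  dG <- constrained$energy - unconstrained$energy
  if (dG < -1e-9) stop("internal error: negative opening penalty", call. = FALSE)
  max(dG, 0)
}

#' Accessibility-corrected hybridization energy (ddG) per allele
#'
#' The binding score combines how well the miRNA pairs with the site
#' (`dG_duplex`) and how much structure must be melted to expose it
#' (`dG_open`): `ddG = dG_duplex + dG_open`, the opening cost entering as
#' a positive penalty. Lower (more negative) ddG means more favorable
#' net binding.
#'
#' @param window_seq Window sequence carrying one allele (string or
#'   `transcript`).
#' @param m A [mirna()].
#' @param site_start,site_end Site interval within the window.
#' @param model An [energy_model()].
#' @param allele Optional allele label carried through to the result.
#' @param region Duplex region passed to [duplex_energy()].
#' @return List of class `duplex_result`: `allele`, `dG_duplex`,
#'   `dG_open`, `ddG` (kcal/mol).
#' @export
site_ddG <- function(window_seq, m, site_start, site_end,
                     model = energy_model(), allele = NA_character_,
                     region = "full") {
  seq <- if (inherits(window_seq, "transcript")) window_seq$seq
         else normalize_to_rna(window_seq)
  site <- substr(seq, site_start, site_end)
  dG_duplex <- duplex_energy(m, site, model, region = region)
  dG_open <- site_open_penalty(seq, site_start, site_end, model)
  structure(list(allele = allele, dG_duplex = dG_duplex, dG_open = dG_open,
                 ddG = dG_duplex + dG_open),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("<duplex_result%s: dG_duplex=%.2f dG_open=%.2f ddG=%.2f kcal/mol>\n",
              if (is.na(x$allele)) "" else paste0(" allele ", x$allele),
              x$dG_duplex, x$dG_open, x$ddG))
  invisible(x)
}

#' Side-by-side allelic ddG comparison
#'
#' Applies [site_ddG()] to the ref- and alt-allele versions of a window
#' and returns both results plus their difference.
#'
#' @param t A [transcript()].
#' @param v A [variant()] on `t`.
#' @param m A [mirna()].
#' @param window_start,window_end Window interval on the transcript.
#' @param site_start,site_end Site interval on the transcript (inside the
#'   window).
#' @param model An [energy_model()].
#' @param region Duplex region passed to [duplex_energy()].
#' @return List with `ref`, `alt` (`duplex_result`s) and
#'   `ddG_alt_minus_ref`.
#' @export
allelic_ddG <- function(t, v, m, window_start, window_end,
                        site_start, site_end, model = energy_model(),
                        region = "full") {
  stopifnot(window_start <= site_start, site_end <= window_end)
  res <- lapply(c(ref = "ref", alt = "alt"), function(which) {
    ta <- apply_allele(t, v, which)
    site_ddG(substr(ta$seq, window_start, window_end), m,
             site_start - window_start + 1L, site_end - window_start + 1L,
             model, allele = if (which == "ref") v$ref else v$alt,
             region = region)
  })
  list(ref = res$ref, alt = res$alt,
       ddG_alt_minus_ref = res$alt$ddG - res$ref$ddG)
}
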