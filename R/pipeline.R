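#' Path of the packaged probing-cleavage fixture
#'
#' Per-allele Pb(2+) and RNase T1 cleavage positions around the
#' TCF21-style variant (transcript coordinates; C allele: strong Pb at
#' 1058-1063; G allele: weak Pb at 1045-1049, strong T1 at 1054, weak T1
#' at 1058 and 1070).
#'
#' @return File path of the TSV.
#' @export
cleavage_fixture_path <- function() {
  system.file("extdata", "tcf21_probing_cleavage.tsv",
              package = "mirallele", mustWork = TRUE)
}

# round every numeric leaf to 6 significant digits for diffable reports
.sig6 <- function(x) {
  if (is.list(x)) return(lapply(x, .sig6))
  if (is.numeric(x)) return(signif(x, 6))
  x
}

#' End-to-end replay on the packaged synthetic TCF21-like fixture
#'
#' Composes the whole pipeline on a seeded synthetic system shaped like
#' the TCF21 3'-UTR / miR-224 case: a 2000-nt transcript with the
#' GUGACUU heptamer planted at 1054-1060 and a C>G variant at 1058.
#' Produces the miRNA x allele seed-match truth table (including the
#' seed-mutant guide), the 180-window loop/stem ensemble summary,
#' allelic ddG for the displayed 941-1141 region, probing concordance
#' against the packaged cleavage table, annealing-rate recovery at the
#' reported C- and G-variant rate constants, allelic-imbalance cohort
#' statistics, an anticorrelated expression series, and a synthetic
#' genome-overlap report.
#'
#' @param seed Root seed for every stochastic component.
#' @param scheme Window scheme for the structure ensemble (default the
#'   180-window grid).
#' @param skip_ensemble If TRUE the (multi-minute) window ensemble is
#'   omitted.
#' @return Nested report list (all numerics at 6 significant digits).
#' @export
replay_tcf21 <- function(seed = 1L, scheme = window_scheme(),
                         skip_ensemble = FALSE) {
  syn <- synth_transcript_with_site(utr_len = 2000L,
                                    seed_heptamer = "GUGACUU",
                                    snp_offset_in_site = 5L, flank = 1053L,
                                    seed = seed)
  t <- syn$transcript; v <- syn$variant
  # the probing table has a T1 record at 1070: put a G there (background
  # position, outside the planted site)
  s <- t$seq; substr(s, 1070L, 1070L) <- "G"
  t <- transcript(t$id, s)

  mir224 <- mirna("miR-224", "CAAGUCACUAGUGGUUCCGUU")
  mir224_snp <- mirna("miR-224_SNP", "CAACUCACUAGUGGUUCCGUU")

  truth <- lapply(list(mir224, mir224_snp), function(m) {
    eff <- allelic_site_effect(m, t, v)
    list(mirna = m$id, ref_match = eff$ref_match, alt_match = eff$alt_match,
         verdict = eff$verdict)
  })
  names(truth) <- c(mir224$id, mir224_snp$id)

  ens_summary <- NULL
  if (!skip_ensemble) {
    ens <- fold_ensemble(t, v, scheme)
    ens_summary <- snp_context_summary(ens)
    ens_summary <- lapply(split(ens_summary, ens_summary$which), as.list)
  }

  win_start <- 941L; win_end <- 1141L
  ddg <- allelic_ddG(t, v, mir224, win_start, win_end,
                     syn$site_start, syn$site_end, region = "seed")

  cleav <- read_cleavage_table(cleavage_fixture_path())
  probing <- lapply(c(ref = "C", alt = "G"), function(al) {
    ta <- apply_allele(t, v, if (al == v$ref) "ref" else "alt")
    st <- mfe_fold(substr(ta$seq, win_start, win_end))
    pc <- probing_concordance(st, cleav[cleav$allele == al, , drop = FALSE],
                              window_offset = win_start - 1L)
    list(allele = al, n_concordant = pc$n_concordant, n_total = pc$n_total,
         fraction = pc$fraction)
  })

  kin <- lapply(c(C = 2.2e6, G = 1.4e6), function(k) {
    tc <- simulate_timecourse(k, A0 = 0.5e-9, B0 = 5e-9, noise_cv = 0,
                              seed = seed)
    est <- estimate_kobs(tc)
    list(k_true = k, k_obs = est$k_obs,
         rel_error = abs(est$k_obs - k) / k, converged = est$converged)
  })

  cohort <- synth_aei_cohort(22L, 2, 0.10, seed)
  aei <- aei_cohort_test(cohort)

  series <- synth_correlated_series(16L, -0.7, seed)
  corr <- pearson_correlation(series$x, series$y)

  tracks <- synth_tracks(seed = seed)
  ov <- overlap_report(tracks$snps, tracks$ld, tracks$tf, tracks$mir,
                       tracks$genome_len)
  overlap <- list(venn = unclass(ov$venn),
                  p_tf = ov$enrichment$tf$p_binomial,
                  p_mir = ov$enrichment$mir$p_binomial,
                  p_both = ov$enrichment$both$p_binomial)

  .sig6(list(
    seed = seed,
    variant = list(rsid = v$rsid, pos = v$pos, ref = v$ref, alt = v$alt),
    truth_table = truth,
    ensemble = ens_summary,
    ddG = list(ref = unclass(ddg$ref), alt = unclass(ddg$alt),
               alt_minus_ref = ddg$ddG_alt_minus_ref),
    probing = probing,
    kinetics = kin,
    aei = aei,
    expression_correlation = corr,
    overlap = overlap))
}

# --- minimal flag parser: c("--a", "1", "--b", "x") -> list(a="1", b="x")
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

.flag <- function(flags, name, default = NULL, required = FALSE) {
  if (!is.null(flags[[name]])) return(flags[[name]])
  if (required) stop("missing required flag --", name, call. = FALSE)
  default
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, used by the shipped
#' `inst/cli/mirallele` script. Subcommands: `scan` (seed sites and
#' allelic effects), `fold` (single-sequence MFE), `ddg` (allelic ddG),
#' `ensemble` (windowed ensemble summary), `probe` (probing
#' concordance), `kinetics-fit` (k_obs from a time-course TSV), `aei`
#' (cohort statistics), `overlap` (SNP x track Venn and enrichment),
#' `simulate` (write a synthetic fixture directory), `replay`
#' (end-to-end report). Results go to `--out` (JSON or TSV) or stdout.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit code, invisibly: 0 on success, 2 on a validation
#'   error, 64 on usage errors.
#' @export
pipeline_run <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mirallele <scan|fold|ddg|ensemble|probe|kinetics-fit|aei|overlap|simulate|replay> [--flags]")
  if (length(argv) == 0L) { message(usage); return(invisible(64L)) }
  sub <- argv[[1L]]
  known <- c("scan", "fold", "ddg", "ensemble", "probe", "kinetics-fit",
             "aei", "overlap", "simulate", "replay")
  if (!sub %in% known) { message(usage); return(invisible(64L)) }
  code <- tryCatch({
    flags <- .parse_flags(argv[-1L])
    .dispatch_subcommand(sub, flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

.emit_json <- function(x, flags) {
  out <- .flag(flags, "out")
  txt <- jsonlite::toJSON(.sig6(x), auto_unbox = TRUE, pretty = TRUE,
                          digits = NA)
  if (is.null(out)) cat(txt, "\n") else writeLines(txt, out)
}

.emit_tsv <- function(df, flags) {
  out <- .flag(flags, "out")
  if (is.null(out)) out <- stdout()
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
}

.dispatch_subcommand <- function(sub, flags) {
  switch(sub,
    "scan" = {
      m <- read_fasta(.flag(flags, "mirna", required = TRUE))[[1L]]
      m <- mirna(m$id, m$seq)
      utrs <- read_fasta(.flag(flags, "utr", required = TRUE))
      vfile <- .flag(flags, "variant")
      rows <- do.call(rbind, lapply(utrs, function(t) find_seed_sites(m, t)))
      .emit_tsv(rows, flags)
      if (!is.null(vfile)) {
        for (v in read_variants(vfile)) {
          t <- utrs[[which(vapply(utrs, function(u) u$id, "") ==
                             v$transcript_id)[1L]]]
          eff <- allelic_site_effect(m, t, v)
          message(sprintf("%s %s pos %d: %s", m$id, v$transcript_id, v$pos,
                          eff$verdict))
        }
      }
    },
    "fold" = {
      t <- read_fasta(.flag(flags, "utr", required = TRUE))[[1L]]
      st <- mfe_fold(t$seq)
      cat(t$seq, "\n", st$dotbracket, "\n",
          sprintf("%.2f kcal/mol", st$energy), "\n", sep = "")
    },
    "ddg" = {
      t <- read_fasta(.flag(flags, "utr", required = TRUE))[[1L]]
      m <- read_fasta(.flag(flags, "mirna", required = TRUE))[[1L]]
      m <- mirna(m$id, m$seq)
      v <- read_variants(.flag(flags, "variant", required = TRUE))[[1L]]
      a <- as.integer(.flag(flags, "site-start", required = TRUE))
      b <- as.integer(.flag(flags, "site-end", required = TRUE))
      ws <- as.integer(.flag(flags, "window-start", max(1L, a - 100L)))
      we <- as.integer(.flag(flags, "window-end", min(t$length, b + 100L)))
      res <- allelic_ddG(t, v, m, ws, we, a, b)
      .emit_tsv(data.frame(
        allele = c(res$ref$allele, res$alt$allele),
        dG_duplex = c(res$ref$dG_duplex, res$alt$dG_duplex),
        dG_open = c(res$ref$dG_open, res$alt$dG_open),
        ddG = c(res$ref$ddG, res$alt$ddG)), flags)
    },
    "ensemble" = {
      t <- read_fasta(.flag(flags, "utr", required = TRUE))[[1L]]
      v <- read_variants(.flag(flags, "variant", required = TRUE))[[1L]]
      ens <- fold_ensemble(t, v)
      .emit_tsv(snp_context_summary(ens), flags)
    },
    "probe" = {
      t <- read_fasta(.flag(flags, "utr", required = TRUE))[[1L]]
      cl <- read_cleavage_table(.flag(flags, "cleavage",
                                      cleavage_fixture_path()))
      al <- .flag(flags, "allele", required = TRUE)
      ws <- as.integer(.flag(flags, "window-start", 1L))
      we <- as.integer(.flag(flags, "window-end", t$length))
      st <- mfe_fold(substr(t$seq, ws, we))
      pc <- probing_concordance(st, cl[cl$allele == al, , drop = FALSE],
                                window_offset = ws - 1L)
      .emit_json(pc[c("n_concordant", "n_total", "fraction")], flags)
    },
    "kinetics-fit" = {
      a0 <- as.numeric(.flag(flags, "a0", required = TRUE)) * 1e-9 # nM
      b0 <- as.numeric(.flag(flags, "b0", required = TRUE)) * 1e-9
      tc <- read_timecourse(.flag(flags, "timecourse", required = TRUE),
                            a0, b0)
      est <- estimate_kobs(tc)
      .emit_json(unclass(est), flags)
    },
    "aei" = {
      samples <- read_aei_table(.flag(flags, "table", required = TRUE))
      .emit_json(aei_cohort_test(samples), flags)
    },
    "overlap" = {
      snps <- read_snp_table(.flag(flags, "snps", required = TRUE))
      ldf <- .flag(flags, "ld")
      ld <- if (is.null(ldf)) NULL else read_ld_table(ldf)
      tf <- read_bed(.flag(flags, "tf", required = TRUE))
      mir <- read_bed(.flag(flags, "mir", required = TRUE))
      gl <- as.numeric(.flag(flags, "genome-len", required = TRUE))
      rep <- overlap_report(snps, ld, tf, mir, gl)
      .emit_json(list(venn = unclass(rep$venn),
                      enrichment = lapply(rep$enrichment, unclass)), flags)
    },
    "simulate" = {
      dir <- .flag(flags, "dir", required = TRUE)
      seed <- as.integer(.flag(flags, "seed", 1L))
      write_fixture_dir(dir, seed = seed)
      message("fixture written to ", dir)
    },
    "replay" = {
      seed <- as.integer(.flag(flags, "seed", 1L))
      fast <- isTRUE(.flag(flags, "fast"))
      .emit_json(replay_tcf21(seed = seed, skip_ensemble = fast), flags)
    })
  invisible(NULL)
}
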