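# Independent oracles used across the suite.  Each deliberately takes the
# dumbest correct route (exhaustive enumeration, O(n*m) scans, term-by-term
# sums) so it shares no code path with the implementation it checks.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# every pseudoknot-free canonical structure (hairpin >= 3) of a sequence
enumerate_structures <- function(seq) {
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  res <- list()
  recurse <- function(pairs, next_i) {
    res[[length(res) + 1L]] <<- pairs
    if (next_i > n) return()
    used <- if (length(pairs)) unlist(pairs) else integer(0)
    for (i in next_i:n) {
      if (i %in% used) next
      if (i + 4L > n) break
      for (j in (i + 4L):n) {
        if (j %in% used) next
        if (!can_pair(bases[i], bases[j])) next
        ok <- TRUE
        for (p in pairs) {
          if ((i > p[1] && i < p[2]) != (j > p[1] && j < p[2])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) next
        recurse(c(pairs, list(c(i, j))), i + 1L)
      }
    }
  }
  recurse(list(), 1L)
  res
}

# brute-force MFE: minimum of energy_of_structure over every enumerated
# structure compatible with the forced-unpaired constraints
oracle_mfe <- function(seq, constraints = integer(0)) {
  best <- 0
  for (p in enumerate_structures(seq)) {
    if (length(p) && length(constraints) && any(unlist(p) %in% constraints))
      next
    m <- if (length(p)) do.call(rbind, p) else NULL
    e <- energy_of_structure(seq, m)
    if (e < best) best <- e
  }
  best
}

# brute-force seed-site scan: exact substring search of the
# reverse-complemented seed at every offset, then the canonical taxonomy
oracle_seed_sites <- function(m, t) {
  n <- t$length
  core <- reverse_complement(substr(m$guide, 2, 7))
  m8 <- reverse_complement(substr(m$guide, 8, 8))
  out <- list()
  for (a in seq_len(max(n - 5L, 0L))) {
    if (substr(t$seq, a, a + 5L) != core) next
    match_m8 <- a > 1L && substr(t$seq, a - 1L, a - 1L) == m8
    t1 <- if (a + 6L <= n) a + 6L else NA_integer_
    a_at_t1 <- !is.na(t1) && substr(t$seq, t1, t1) == "A"
    type <- if (match_m8 && a_at_t1) "8mer"
    else if (match_m8) "7mer-m8"
    else if (a_at_t1) "7mer-A1"
    else "6mer"
    seven <- type %in% c("8mer", "7mer-m8")
    out[[length(out) + 1L]] <- data.frame(
      site_type = type, start = if (seven) a - 1L else a, end = a + 5L,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# O(n*m) SNP-in-track scan
oracle_snps_in_track <- function(snps, track) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(track$chrom == snps$chrom[i] &
          track$start <= snps$pos[i] & snps$pos[i] < track$end)
  }, logical(1))
}

# numerical integration of dx/dt = k (A0 - x)(B0 - x) via deSolve
oracle_ode_fraction <- function(k, A0, B0, times) {
  rhs <- function(t, state, parms) {
    list(parms$k * (parms$A0 - state[1]) * (parms$B0 - state[1]))
  }
  out <- deSolve::ode(y = c(x = 0), times = c(0, times), func = rhs,
                      parms = list(k = k, A0 = A0, B0 = B0),
                      rtol = 1e-10, atol = 1e-16)
  unname(out[-1, "x"] / A0)
}
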