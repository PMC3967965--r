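#' Nearest-neighbor energy model
#'
#' Loads the versioned nearest-neighbor parameter set shipped with the
#' package: Watson-Crick and G:U stacking free energies (kcal/mol at 37C),
#' tabulated hairpin/bulge/internal loop penalties with logarithmic
#' extrapolation beyond 30 nt, affine multiloop constants and the duplex
#' initiation penalty. The same table drives the reference scorer
#' [energy_of_structure()], the folding engine [mfe_fold()] and
#' [duplex_energy()], so all energies in the package are mutually
#' consistent.
#'
#' @param version Parameter set version; currently only `"v1"`.
#' @return An object of class `energy_model`: list with `stack` (6x6 matrix
#'   indexed by pair type AU/UA/CG/GC/GU/UG), `hairpin`, `bulge`,
#'   `internal` (length-30 penalty vectors, kcal/mol), `ml_a`, `ml_b`,
#'   `ml_c` (multiloop offset, per-branch, per-unpaired), `duplex_init`,
#'   `lxc` (log-extrapolation coefficient) and `max_loop`.
#' @export
energy_model <- function(version = "v1") {
  cache_key <- paste0("model_", version)
  if (!is.null(.mirallele_cache[[cache_key]]))
    return(.mirallele_cache[[cache_key]])
  path <- system.file("extdata", sprintf("nn_params_%s.tsv", version),
                      package = "mirallele", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  ptypes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stk <- matrix(NA_real_, 6, 6, dimnames = list(ptypes, ptypes))
  srows <- df[df$category == "stack", ]
  for (i in seq_len(nrow(srows))) {
    k <- strsplit(srows$key[i], ".", fixed = TRUE)[[1]]
    stk[k[1], k[2]] <- srows$value[i]
  }
  stopifnot(!anyNA(stk))
  tab <- function(cat, n) {
    rows <- df[df$category == cat, ]
    v <- rep(NA_real_, n)
    v[as.integer(rows$key)] <- rows$value
    v
  }
  getval <- function(cat, key) df$value[df$category == cat & df$key == key]
  m <- structure(list(
    version = version,
    stack = stk,
    hairpin = tab("hairpin", 30L),
    bulge = tab("bulge", 30L),
    internal = tab("internal", 30L),
    ml_a = getval("multiloop", "a"),
    ml_b = getval("multiloop", "b"),
    ml_c = getval("multiloop", "c"),
    duplex_init = getval("misc", "duplex_init"),
    lxc = getval("misc", "lxc"),
    max_loop = as.integer(getval("misc", "max_loop"))
  ), class = "energy_model")
  .mirallele_cache[[cache_key]] <- m
  m
}

.mirallele_cache <- new.env(parent = emptyenv())

# pair-type index used throughout: AU=1 UA=2 CG=3 GC=4 GU=5 UG=6; 0 = no pair
.PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Pair type of two bases
#' @param a,b Single bases (ACGU).
#' @return One of `"AU","UA","CG","GC","GU","UG"` or `NA` if not pairable
#'   (Watson-Crick plus G:U wobble).
#' @export
pair_type <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% .PAIR_TYPES) key else NA_character_
}

#' Can two bases pair (Watson-Crick or G:U)?
#' @param a,b Single bases.
#' @return Logical.
#' @export
can_pair <- function(a, b) !is.na(pair_type(a, b))

# loop penalties with log extrapolation beyond the tabulated 30 nt
.loop_penalty <- function(table30, size, lxc) {
  if (size <= 30L) table30[size] else table30[30L] + lxc * log(size / 30)
}

hairpin_penalty <- function(model, size) {
  if (size < 3L) stop("hairpin loop smaller than 3 nt", call. = FALSE)
  .loop_penalty(model$hairpin, size, model$lxc)
}

bulge_penalty <- function(model, size) .loop_penalty(model$bulge, size, model$lxc)

internal_penalty <- function(model, size) {
  if (size < 2L) stop("internal loop smaller than 2 nt", call. = FALSE)
  .loop_penalty(model$internal, size, model$lxc)
}
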