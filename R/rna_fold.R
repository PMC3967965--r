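#' Secondary structure object
#'
#' A pseudoknot-free secondary structure: a set of base pairs on a
#' sequence, its dot-bracket string, and its free energy under the shipped
#' nearest-neighbor model. Invariants enforced on construction: pairs are
#' non-crossing, each position is in at most one pair, every pair is
#' canonical (Watson-Crick or G:U), and each hairpin loop is at least 3 nt
#' (j - i >= 4).
#'
#' @param seq RNA string (normalized via [normalize_to_rna()]).
#' @param pairs Two-column matrix (or empty) of 1-based pair positions,
#'   i < j per row.
#' @param model An [energy_model()]; used to score `energy`.
#' @return An object of class `secondary_structure` with fields `seq`,
#'   `partner` (integer vector, 0 = unpaired), `pairs`, `dotbracket`,
#'   `energy`.
#' @export
secondary_structure <- function(seq, pairs, model = energy_model()) {
  seq <- normalize_to_rna(seq)
  n <- nchar(seq)
  partner <- .pairs_to_partner(pairs, n, seq)
  energy <- .score_partner(seq, partner, model)
  structure(list(seq = seq, partner = partner,
                 pairs = .partner_to_pairs(partner),
                 dotbracket = partner_to_dotbracket(partner),
                 energy = energy),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "  (", sprintf("%.2f", x$energy),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

# validate a pair list and return a partner vector; errors carry the reason
.pairs_to_partner <- function(pairs, n, seq) {
  partner <- integer(n)
  if (is.null(pairs) || length(pairs) == 0L) return(partner)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  bases <- strsplit(seq, "")[[1]]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i >= j) stop("invalid structure: pair has i >= j", call. = FALSE)
    if (i < 1L || j > n) stop("invalid structure: pair out of bounds", call. = FALSE)
    if (j - i < 4L)
      stop("invalid structure: hairpin loop smaller than 3 nt", call. = FALSE)
    if (partner[i] != 0L || partner[j] != 0L)
      stop("invalid structure: position in more than one pair", call. = FALSE)
    if (!can_pair(bases[i], bases[j]))
      stop(sprintf("invalid structure: non-canonical pair %s:%s at (%d,%d)",
                   bases[i], bases[j], i, j), call. = FALSE)
    partner[i] <- j; partner[j] <- i
  }
  # crossing check: (i,j) and (k,l) with i<k<j<l
  pr <- .partner_to_pairs(partner)
  if (nrow(pr) > 1L) {
    for (a in seq_len(nrow(pr) - 1L)) for (b in (a + 1L):nrow(pr)) {
      i <- pr[a, 1]; j <- pr[a, 2]; k <- pr[b, 1]; l <- pr[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
        stop("invalid structure: crossing pairs (pseudoknot)", call. = FALSE)
    }
  }
  partner
}

.partner_to_pairs <- function(partner) {
  i <- which(partner > seq_along(partner))
  cbind(i = i, j = partner[i])
}

#' Convert a partner vector to dot-bracket notation
#' @param partner Integer vector, `partner[i]` = paired position or 0.
#' @return Dot-bracket string.
#' @export
partner_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  db[partner > seq_along(partner)] <- "("
  db[partner != 0L & partner < seq_along(partner)] <- ")"
  paste(db, collapse = "")
}

#' Parse dot-bracket notation to a partner vector
#' @param db Dot-bracket string over `().`.
#' @return Integer partner vector (0 = unpaired).
#' @export
dotbracket_to_partner <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("dot-bracket string may contain only '(', ')', '.'", call. = FALSE)
  partner <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- open[length(open)]; open <- open[-length(open)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
  partner
}

# loop decomposition scorer on a validated partner vector
.score_partner <- function(seq, partner, model) {
  bases <- strsplit(seq, "")[[1]]
  pr <- .partner_to_pairs(partner)
  if (nrow(pr) == 0L) return(0)
  total <- 0
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    # direct children pairs and unpaired count inside loop closed by (i,j)
    children <- matrix(integer(0), ncol = 2)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children <- rbind(children, c(k, partner[k]))
        k <- partner[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nb <- nrow(children)
    if (nb == 0L) {
      total <- total + hairpin_penalty(model, j - i - 1L)
    } else if (nb == 1L) {
      k <- children[1, 1]; l <- children[1, 2]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 == 0L && s2 == 0L) {
        total <- total +
          model$stack[pair_type(bases[i], bases[j]),
                      pair_type(bases[k], bases[l])]
      } else if (s1 == 0L || s2 == 0L) {
        total <- total + bulge_penalty(model, s1 + s2)
      } else {
        total <- total + internal_penalty(model, s1 + s2)
      }
    } else {
      total <- total + model$ml_a + model$ml_b * (nb + 1L) +
        model$ml_c * unpaired
    }
  }
  total # exterior unpaired bases are free
}

#' Free energy of a given structure
#'
#' Loop-decomposition score of an explicit structure under the
#' nearest-neighbor model: stacking terms for adjacent pairs, hairpin /
#' bulge / internal loop length penalties, an affine multiloop term, and
#' free exterior bases. The all-unpaired structure is the zero reference.
#' This scorer is deliberately independent of the folding engine; the two
#' are held together by tests.
#'
#' @param seq RNA string.
#' @param pairs Two-column matrix of 1-based pairs (or NULL/empty).
#' @param model An [energy_model()].
#' @return Energy in kcal/mol.
#' @export
energy_of_structure <- function(seq, pairs, model = energy_model()) {
  seq <- normalize_to_rna(seq)
  partner <- .pairs_to_partner(pairs, nchar(seq), seq)
  .score_partner(seq, partner, model)
}

.BASE_CODES <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' Predict the minimum-free-energy structure
#'
#' Dynamic-programming MFE fold over all pseudoknot-free structures
#' (optionally with positions forced unpaired), under the same
#' nearest-neighbor model as [energy_of_structure()]. Interior loops are
#' capped at `model$max_loop` unpaired nt total, lonely pairs are allowed,
#' and there are no dangling-end terms, so the DP optimum coincides with
#' the exhaustive-enumeration optimum at small sizes. Equal-energy ties
#' break deterministically (smallest 5' pairing first).
#'
#' Sequences shorter than 5 nt cannot form any pair and return the
#' all-unpaired structure at 0 kcal/mol.
#'
#' @param seq RNA string (<= 2000 nt).
#' @param model An [energy_model()].
#' @param constraints Integer vector of 1-based positions forced to stay
#'   unpaired (default none).
#' @return A `secondary_structure`; its `energy` field re-scores
#'   identically via [energy_of_structure()].
#' @export
mfe_fold <- function(seq, model = energy_model(), constraints = integer(0)) {
  seq <- normalize_to_rna(seq)
  n <- nchar(seq)
  if (n > 2000L) stop("sequence longer than the 2000-nt practical bound", call. = FALSE)
  constraints <- as.integer(constraints)
  if (length(constraints) && (min(constraints) < 1L || max(constraints) > n))
    stop("constraint positions out of bounds", call. = FALSE)
  forced <- rep(FALSE, n)
  forced[constraints] <- TRUE
  codes <- unname(.BASE_CODES[strsplit(seq, "")[[1]]])
  res <- .c_mfe_fold(codes, forced, model$stack, model$hairpin, model$bulge,
                     model$internal, model$ml_a, model$ml_b, model$ml_c,
                     model$lxc, model$max_loop)
  partner <- res$partner
  out <- structure(list(seq = seq, partner = partner,
                        pairs = .partner_to_pairs(partner),
                        dotbracket = partner_to_dotbracket(partner),
                        energy = res$energy),
                   class = "secondary_structure")
  # scorer/DP consistency is an invariant, not an assumption
  rescore <- .score_partner(seq, partner, model)
  if (abs(rescore - out$energy) > 1e-6)
    stop("internal error: DP energy and scorer disagree", call. = FALSE)
  out
}

#' Structural context of a position
#'
#' Classifies a position of a structure as `stem` (paired) or, if
#' unpaired, by the loop that contains it: `hairpin_loop`,
#' `internal_or_bulge`, `multiloop`, or `exterior` (not enclosed by any
#' pair).
#'
#' @param s A `secondary_structure`.
#' @param pos 1-based position.
#' @return Character scalar context label.
#' @export
pair_context <- function(s, pos) {
  stopifnot(inherits(s, "secondary_structure"))
  n <- length(s$partner)
  pos <- as.integer(pos)
  if (pos < 1L || pos > n) stop("position out of bounds", call. = FALSE)
  if (s$partner[pos] != 0L) return("stem")
  # innermost enclosing pair
  pr <- s$pairs
  enc <- pr[pr[, 1] < pos & pr[, 2] > pos, , drop = FALSE]
  if (nrow(enc) == 0L) return("exterior")
  i <- enc[which.max(enc[, 1]), 1]
  j <- s$partner[i]
  # count direct children of (i,j)
  nb <- 0L
  k <- i + 1L
  while (k < j) {
    if (s$partner[k] > k) { nb <- nb + 1L; k <- s$partner[k] + 1L } else k <- k + 1L
  }
  if (nb == 0L) "hairpin_loop" else if (nb == 1L) "internal_or_bulge" else "multiloop"
}
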