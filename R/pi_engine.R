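#' @importFrom stats sd aggregate prcomp rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# -- internal: ionizable-group counting ---------------------------------------

# Count ionizable group instances per sequence: seven side chains plus one
# N-terminal and one C-terminal group per chain (unless termini are excluded).
# Returns an n x 9 matrix with columns in PKA_GROUPS order.
ionizable_counts <- function(sequences, include_termini = TRUE) {
  set <- Biostrings::AAStringSet(sequences)
  side <- Biostrings::letterFrequency(set, letters = c("D", "E", "C", "Y", "H", "K", "R"))
  term <- if (include_termini) 1 else 0
  counts <- cbind(Nterm = rep(term, length(set)),
                  Cterm = rep(term, length(set)),
                  side)
  counts[, PKA_GROUPS, drop = FALSE]
}

# Net charge for a counts matrix at a vector of pH values: counts %*% F where
# F[g, p] = sign_g / (1 + 10^(sign_g * (pH_p - pKa_g))), the
# Henderson-Hasselbalch fractional ionization with the group's sign folded in.
charge_from_counts <- function(counts, pH, pka) {
  s <- pka$sign[PKA_GROUPS]
  k <- pka$pka[PKA_GROUPS]
  f <- vapply(seq_along(pH), function(p) {
    s / (1 + 10^(s * (pH[p] - k)))
  }, numeric(length(PKA_GROUPS)))
  counts %*% f
}

# -- exported operations ------------------------------------------------------

#' Net charge of a protein as a function of pH
#'
#' Sums, over every ionizable group instance in the chain, the signed
#' Henderson-Hasselbalch fractional ionization: for a positively charging
#' group \eqn{+1/(1+10^{pH-pKa})}, for a negatively charging group
#' \eqn{-1/(1+10^{pKa-pH})}. Exactly one N-terminal and one C-terminal group
#' are included per chain. Ambiguity codes (X, B, Z, J, U, O) contribute zero
#' charge. The function is strictly decreasing in pH whenever at least one
#' ionizable group is present, which is what makes the bisection pI solver
#' in [isoelectric_point()] converge.
#'
#' @param sequence a single amino-acid string (uppercase one-letter codes).
#' @param pH numeric vector of pH values in \[0, 14\].
#' @param pka a [pka_set()] name or object; default \code{"emboss"}.
#' @param include_termini include the two chain-terminal groups (default
#'   TRUE). Side-chain-only mode is occasionally useful for length-invariance
#'   arguments.
#' @return numeric vector of net charges (elementary charge units), one per pH.
#' @examples
#' net_charge("MKKDE", 7.0)
#' net_charge("K", c(2, 7, 12))
#' @export
net_charge <- function(sequence, pH, pka = "emboss", include_termini = TRUE) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stopf("`sequence` must be a single string; use protein_pi() for batches")
  }
  if (any(pH < 0 | pH > 14)) stopf("pH must lie in [0, 14]")
  pka <- pka_set(pka)
  counts <- ionizable_counts(sequence, include_termini)
  drop(charge_from_counts(counts, pH, pka))
}

# Vectorized bisection on [0, 14] exploiting strict monotonicity of the
# charge curve. `counts` is an n x 9 matrix; returns n pI values.
pi_from_counts <- function(counts, pka, tol = 1e-3) {
  n <- nrow(counts)
  lo <- rep(0, n)
  hi <- rep(14, n)
  none <- rowSums(counts) == 0
  c_lo <- drop(charge_from_counts(counts, 0, pka))
  c_hi <- drop(charge_from_counts(counts, 14, pka))
  # clamp to the boundary when the charge never crosses zero inside [0, 14]
  done_lo <- c_lo <= 0
  done_hi <- c_hi >= 0
  iters <- ceiling(log2(14 / tol)) + 1L
  s <- pka$sign[PKA_GROUPS]
  k <- pka$pka[PKA_GROUPS]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    # midpoints differ per protein, so evaluate group-by-group
    cm <- numeric(n)
    for (g in seq_along(PKA_GROUPS)) {
      cm <- cm + counts[, g] * (s[g] / (1 + 10^(s[g] * (mid - k[g]))))
    }
    pos <- cm > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  out <- (lo + hi) / 2
  out[done_lo] <- 0
  out[done_hi] <- 14
  out[none] <- NA_real_
  out
}

#' Isoelectric point of a protein
#'
#' Finds the pH at which [net_charge()] is zero by bisection on \[0, 14\],
#' to within \code{tol} (default 0.001 pH units). The charge curve is
#' strictly decreasing in pH, so the zero is unique. A sequence with no
#' ionizable side chains still carries its two terminal groups, so the pI is
#' always defined in the default mode and equals the midpoint of the two
#' terminal pKas (6.10 under the EMBOSS set). In side-chain-only mode a
#' sequence with no ionizable groups returns NA with a warning.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units (> 0).
#' @return the pI in pH units.
#' @examples
#' isoelectric_point("GGG")          # midpoint of the terminal pKas: 6.10
#' isoelectric_point("DDEEKKRR")
#' @export
isoelectric_point <- function(sequence, pka = "emboss", tol = 1e-3,
                              include_termini = TRUE) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stopf("`sequence` must be a single string; use protein_pi() for batches")
  }
  if (!is.numeric(tol) || tol <= 0) stopf("`tol` must be > 0")
  pka <- pka_set(pka)
  counts <- ionizable_counts(sequence, include_termini)
  if (sum(counts) == 0) {
    warning("sequence has no ionizable groups; pI undefined", call. = FALSE)
    return(NA_real_)
  }
  pi_from_counts(counts, pka, tol)
}

#' Per-protein pI and charge summary for a proteome
#'
#' Batch version of [isoelectric_point()] / [net_charge()]: one row per
#' protein with its length (standard + ambiguity residues), pI, net charge
#' at pH 7, and the counts of acidic (D+E) and basic (K+R+H) residues.
#'
#' @param x a proteome data frame from [read_proteome()] (columns
#'   \code{protein_id}, \code{sequence}) or a character vector of sequences
#'   (names used as ids when present).
#' @inheritParams isoelectric_point
#' @return a data frame with columns \code{protein_id}, \code{length},
#'   \code{pI}, \code{net_charge_at_7}, \code{acidic_count},
#'   \code{basic_count}.
#' @export
protein_pi <- function(x, pka = "emboss", tol = 1e-3, include_termini = TRUE) {
  seqs <- as_sequences(x)
  pka <- pka_set(pka)
  counts <- ionizable_counts(seqs, include_termini)
  pis <- pi_from_counts(counts, pka, tol)
  q7 <- drop(charge_from_counts(counts, 7, pka))
  data.frame(
    protein_id = names(seqs),
    length = nchar(seqs),
    pI = pis,
    net_charge_at_7 = q7,
    acidic_count = counts[, "D"] + counts[, "E"],
    basic_count = counts[, "K"] + counts[, "R"] + counts[, "H"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Coerce a proteome data frame or (optionally named) character vector to a
# named character vector of sequences.
as_sequences <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("protein_id", "sequence") %in% names(x))) {
      stopf("proteome data frame needs columns protein_id and sequence")
    }
    seqs <- x$sequence
    names(seqs) <- x$protein_id
  } else if (is.character(x)) {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stopf("expected a proteome data frame or character vector of sequences")
  }
  if (length(seqs) == 0L) stopf("no sequences supplied")
  seqs
}

#' Pooled amino-acid composition of a proteome (Mole%)
#'
#' Counts the 20 standard residues pooled over all records and expresses each
#' as a percentage of the standard-residue total (Mole%). Ambiguity codes are
#' excluded from both numerator and denominator, so the percentages always
#' sum to 100.
#'
#' @param x a proteome data frame or character vector of sequences.
#' @return an object of class \code{aa_composition}: list with
#'   \code{mole_percent} (named over the 20 standard residues) and
#'   \code{n_residues} (standard-residue count).
#' @examples
#' aa_composition(c("DK"))$mole_percent[c("D", "K")]
#' @export
aa_composition <- function(x) {
  seqs <- as_sequences(x)
  set <- Biostrings::AAStringSet(seqs)
  counts <- colSums(Biostrings::letterFrequency(set, letters = AA_STANDARD))
  total <- sum(counts)
  if (total == 0) stopf("proteome contains no standard residues")
  structure(list(mole_percent = 100 * counts / total, n_residues = total),
            class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat("Amino-acid composition over", x$n_residues, "residues (Mole%):\n")
  print(round(x$mole_percent, 2))
  invisible(x)
}

#' Acidic, basic and total charged Mole% of a composition
#'
#' Acidic = D + E; basic = K + H + R; charged = acidic + basic. These are the
#' summary quantities in which marine proteomes show an acidic excess and
#' freshwater proteomes a (more moderate) basic excess.
#'
#' @param comp an [aa_composition()] object.
#' @return named numeric vector \code{c(acidic, basic, charged)} in Mole%.
#' @export
charged_fractions <- function(comp) {
  if (!inherits(comp, "aa_composition")) {
    stopf("`comp` must be an aa_composition object")
  }
  m <- comp$mole_percent
  acidic <- unname(m[["D"]] + m[["E"]])
  basic <- unname(m[["K"]] + m[["H"]] + m[["R"]])
  c(acidic = acidic, basic = basic, charged = acidic + basic)
}
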