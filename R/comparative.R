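# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11 / extend 1),
# used to convert raw Smith-Waterman scores into a BLAST-like e-value proxy
# with database size = subject proteome residue count.
KA_LAMBDA <- 0.267
KA_K <- 0.041

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# unique 5-mers of each sequence (used by the shared-kmer prefilter)
.kmers <- function(s, k = 5L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
}

#' All-vs-all best local alignment hits between two proteomes
#'
#' For each query protein, candidate subjects are preselected by a k-mer
#' prefilter (at least 2 shared exact 5-mers) and aligned with affine-gap
#' local (Smith-Waterman) alignment under BLOSUM62, gap open 11 / extend 1.
#' Hits below \code{min_identity} or \code{min_coverage} are discarded and
#' only the best-scoring passing hit per query is retained (score ties break
#' to the lexicographically smaller subject id), which is exactly what the
#' reciprocal-best-hit machinery downstream needs. Percent identity is
#' computed over the aligned region (including gap positions); coverage is
#' the alignable fraction of the query. The e-value proxy applies the
#' Karlin-Altschul formula to the raw score with the subject proteome's
#' residue count as database size.
#'
#' @param proteome_a,proteome_b proteome data frames (query and subject).
#' @param min_identity minimum percent identity (default 30).
#' @param min_coverage minimum alignable fraction of the query (default 0.5).
#' @return data frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignable_fraction_of_query},
#'   \code{score}, \code{e_value_proxy}; zero rows when nothing passes.
#' @export
all_vs_all_hits <- function(proteome_a, proteome_b, min_identity = 30,
                            min_coverage = 0.5) {
  qseqs <- as_sequences(proteome_a)
  sseqs <- as_sequences(proteome_b)
  if (!length(qseqs) || !length(sseqs)) stopf("both proteomes must be non-empty")
  db_residues <- sum(nchar(sseqs))
  # kmer index: 5-mer -> subject indices
  skmers <- lapply(sseqs, .kmers)
  idx <- split(rep(seq_along(sseqs), lengths(skmers)), unlist(skmers))
  sset <- Biostrings::AAStringSet(sseqs)
  mat <- .blosum62()
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignable_fraction_of_query = numeric(),
                      score = numeric(), e_value_proxy = numeric(),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_along(qseqs), function(i) {
    qk <- .kmers(qseqs[[i]])
    hits <- unlist(idx[qk], use.names = FALSE)
    if (is.null(hits) || !length(hits)) return(NULL)
    shared <- tabulate(hits, nbins = length(sseqs))
    cand <- which(shared >= 2L)
    if (!length(cand)) return(NULL)
    aln <- Biostrings::pairwiseAlignment(
      sset[cand], Biostrings::AAString(qseqs[[i]]), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    pid <- Biostrings::pid(aln, type = "PID1")
    qlen <- nchar(qseqs[[i]])
    cov <- (BiocGenerics::end(Biostrings::subject(aln)) -
              BiocGenerics::start(Biostrings::subject(aln)) + 1) / qlen
    keep <- pid >= min_identity & cov >= min_coverage & sc > 0
    if (!any(keep)) return(NULL)
    sub_ids <- names(sseqs)[cand][keep]
    ord <- order(-sc[keep], sub_ids)[1]
    bit <- (KA_LAMBDA * sc[keep][ord] - log(KA_K)) / log(2)
    data.frame(query_id = names(qseqs)[i], subject_id = sub_ids[ord],
               percent_identity = pid[keep][ord],
               alignable_fraction_of_query = cov[keep][ord],
               score = sc[keep][ord],
               e_value_proxy = qlen * db_residues * 2^(-bit),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two directional hit tables
#'
#' @param hits_ab,hits_ba best-hit tables from [all_vs_all_hits()] run in the
#'   two directions.
#' @return data frame with columns \code{id_a}, \code{id_b},
#'   \code{identity_ab}, \code{identity_ba} (one row per RBH pair).
#' @export
rbh_pairs <- function(hits_ab, hits_ba) {
  if (!nrow(hits_ab) || !nrow(hits_ba)) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity_ab = numeric(), identity_ba = numeric(),
                      stringsAsFactors = FALSE))
  }
  back <- hits_ba$subject_id[match(hits_ab$subject_id, hits_ba$query_id)]
  keep <- !is.na(back) & back == hits_ab$query_id
  ab <- hits_ab[keep, , drop = FALSE]
  ba_idx <- match(ab$subject_id, hits_ba$query_id)
  data.frame(id_a = ab$query_id, id_b = ab$subject_id,
             identity_ab = ab$percent_identity,
             identity_ba = hits_ba$percent_identity[ba_idx],
             stringsAsFactors = FALSE)
}

#' Average amino-acid identity (AAI) over reciprocal best hits
#'
#' AAI is the unweighted mean percent identity over reciprocal-best-hit
#' ortholog pairs; each pair contributes the average of its two directional
#' identities, which makes the result symmetric in argument order.
#'
#' @inheritParams rbh_pairs
#' @return list with \code{aai} (percent; NA with a warning when there are
#'   no RBH pairs) and \code{n_rbh_pairs}.
#' @export
compute_aai <- function(hits_ab, hits_ba) {
  rbh <- rbh_pairs(hits_ab, hits_ba)
  if (!nrow(rbh)) {
    warning("no reciprocal best hits; AAI undefined", call. = FALSE)
    return(list(aai = NA_real_, n_rbh_pairs = 0L))
  }
  list(aai = mean((rbh$identity_ab + rbh$identity_ba) / 2),
       n_rbh_pairs = nrow(rbh))
}

#' Percentage of conserved proteins (POCP)
#'
#' \eqn{POCP = 100 (C_a + C_b) / (n_a + n_b)} where \eqn{C_x} counts the
#' proteins of proteome x with at least one hit in the other proteome
#' passing the conserved-protein thresholds: e-value < 1e-5, identity > 40
#' percent, alignable region > 50 percent of the query.
#'
#' @inheritParams rbh_pairs
#' @param n_a,n_b total protein counts of the two proteomes.
#' @return POCP in percent.
#' @export
compute_pocp <- function(hits_ab, hits_ba, n_a, n_b) {
  if (n_a + n_b == 0) stopf("both proteomes are empty")
  conserved <- function(h) {
    if (!nrow(h)) return(0L)
    sum(h$e_value_proxy < 1e-5 & h$percent_identity > 40 &
          h$alignable_fraction_of_query > 0.5)
  }
  100 * (conserved(hits_ab) + conserved(hits_ba)) / (n_a + n_b)
}

#' Core / flexible partition of a proteome pair
#'
#' For a two-genome comparison the core genome is the set of proteins in a
#' reciprocal-best-hit pair and the flexible genome is everything else; the
#' two sets partition each proteome.
#'
#' @param rbh data frame from [rbh_pairs()].
#' @param ids_a,ids_b full protein id vectors of the two proteomes.
#' @return list with \code{core_a}, \code{flexible_a}, \code{core_b},
#'   \code{flexible_b}.
#' @export
core_flexible_partition <- function(rbh, ids_a, ids_b) {
  list(core_a = intersect(ids_a, rbh$id_a),
       flexible_a = setdiff(ids_a, rbh$id_a),
       core_b = intersect(ids_b, rbh$id_b),
       flexible_b = setdiff(ids_b, rbh$id_b))
}

#' Full pairwise comparison of two proteomes
#'
#' The engine behind marine-freshwater neighbor-pair comparisons: runs
#' [all_vs_all_hits()] in both directions, derives AAI, POCP and the
#' core/flexible partition, computes whole, per-localization-category and
#' per-partition pI spectra for both proteomes, per-category mean pIs, and
#' the per-residue Mole% composition difference (A - B). The result records
#' which proteome has the higher acid fraction (the expected "marine"
#' direction when A is the salt-adapted genome).
#'
#' @param proteome_a,proteome_b proteome data frames.
#' @param loc_a,loc_b localization call data frames (from
#'   [localize_proteome()] or [import_localization()]); NULL runs the
#'   heuristic.
#' @param pka,bin_width,range spectrum parameters, see [proteome_profile()].
#' @param min_identity,min_coverage alignment thresholds, see
#'   [all_vs_all_hits()].
#' @return object of class \code{pair_comparison}: list with \code{aai},
#'   \code{n_rbh_pairs}, \code{pocp}, \code{partition}, \code{spectra}
#'   (nested: per genome, whole / secreted / transmembrane / cytoplasmic /
#'   core / flexible), \code{mean_pi} (matrix genome x category),
#'   \code{acid_fraction} (per genome), \code{composition_delta} (named
#'   20-vector, Mole% A - B), \code{higher_acid} ("a" or "b").
#' @export
compare_pair <- function(proteome_a, proteome_b, loc_a = NULL, loc_b = NULL,
                         pka = "emboss", bin_width = 0.25, range = c(2, 14),
                         min_identity = 30, min_coverage = 0.5) {
  if (is.null(loc_a)) loc_a <- localize_proteome(proteome_a)
  if (is.null(loc_b)) loc_b <- localize_proteome(proteome_b)
  hits_ab <- all_vs_all_hits(proteome_a, proteome_b,
                             min_identity = min_identity,
                             min_coverage = min_coverage)
  hits_ba <- all_vs_all_hits(proteome_b, proteome_a,
                             min_identity = min_identity,
                             min_coverage = min_coverage)
  rbh <- rbh_pairs(hits_ab, hits_ba)
  aai <- compute_aai(hits_ab, hits_ba)
  pocp <- compute_pocp(hits_ab, hits_ba, nrow(proteome_a), nrow(proteome_b))
  part <- core_flexible_partition(rbh, proteome_a$protein_id,
                                  proteome_b$protein_id)
  side <- function(proteome, loc, core_ids, label) {
    tab <- protein_pi(proteome, pka = pka)
    cat_of <- loc$category[match(tab$protein_id, loc$protein_id)]
    subsets <- list(
      whole = rep(TRUE, nrow(tab)),
      secreted = !is.na(cat_of) & cat_of == "secreted",
      transmembrane = !is.na(cat_of) & cat_of == "transmembrane",
      cytoplasmic = !is.na(cat_of) & cat_of == "cytoplasmic",
      core = tab$protein_id %in% core_ids,
      flexible = !tab$protein_id %in% core_ids
    )
    specs <- lapply(names(subsets), function(nm) {
      bin_spectrum(tab$pI[subsets[[nm]]], bin_width = bin_width,
                   range = range, label = paste(label, nm, sep = ":"))
    })
    names(specs) <- names(subsets)
    means <- vapply(subsets, function(s) {
      if (any(s)) mean(tab$pI[s], na.rm = TRUE) else NA_real_
    }, numeric(1))
    list(spectra = specs, mean_pi = means,
         acid_fraction = unname(acid_neutral_basic(specs$whole)["acid_fraction"]),
         composition = aa_composition(proteome))
  }
  a <- side(proteome_a, loc_a, part$core_a, "a")
  b <- side(proteome_b, loc_b, part$core_b, "b")
  comp_delta <- a$composition$mole_percent - b$composition$mole_percent
  structure(list(
    aai = aai$aai, n_rbh_pairs = aai$n_rbh_pairs, pocp = pocp,
    partition = part,
    spectra = list(a = a$spectra, b = b$spectra),
    mean_pi = rbind(a = a$mean_pi, b = b$mean_pi),
    acid_fraction = c(a = a$acid_fraction, b = b$acid_fraction),
    composition_delta = comp_delta,
    higher_acid = if (a$acid_fraction >= b$acid_fraction) "a" else "b"
  ), class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("Pair comparison: AAI %.1f%% over %d RBH pairs, POCP %.1f%%\n",
              x$aai, x$n_rbh_pairs, x$pocp))
  cat(sprintf("  core a/b: %d/%d, flexible a/b: %d/%d\n",
              length(x$partition$core_a), length(x$partition$core_b),
              length(x$partition$flexible_a), length(x$partition$flexible_b)))
  cat(sprintf("  acid fraction a %.3f vs b %.3f (higher: %s)\n",
              x$acid_fraction[["a"]], x$acid_fraction[["b"]], x$higher_acid))
  invisible(x)
}
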