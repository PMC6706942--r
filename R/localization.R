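# Kyte-Doolittle hydropathy, the single scale used by the heuristic.
# Ambiguity codes get 0 (neutral) so rare codes cannot flip a call.
KYTE_DOOLITTLE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5,
  X = 0, B = 0, Z = 0, J = 0, U = 0, O = 0
)

# centered moving average of x with odd window w; NA outside valid centers
.win_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# localization call for one hydropathy vector; returns list(sp, n_tm, short)
.call_one <- function(h, window, tm_threshold, sp_max_pos) {
  n <- length(h)
  if (n < window) {
    return(list(sp = FALSE, n_tm = 0L, short = TRUE))
  }
  # signal peptide: >=1 K/R in the first 5 residues (checked by caller via
  # attr) is combined here with the hydrophobic h-region test: some 8-residue
  # stretch with mean hydropathy >= tm_threshold ending by sp_max_pos
  sp_region_end <- min(sp_max_pos, n)
  has_hregion <- FALSE
  if (sp_region_end >= 8) {
    trailing <- as.numeric(stats::filter(h[seq_len(sp_region_end)],
                                         rep(1 / 8, 8), sides = 1))
    has_hregion <- any(trailing >= tm_threshold, na.rm = TRUE)
  }
  list(sp = has_hregion, n_tm = NA_integer_, short = FALSE)
}

# count TM segments on h[from..n]: maximal runs of >= `window` consecutive
# window centers whose centered mean hydropathy >= threshold
.count_tm <- function(h, window, tm_threshold, from = 1L) {
  h <- h[seq(from, length(h))]
  if (length(h) < window) return(0L)
  wm <- .win_mean(h, window)
  hot <- !is.na(wm) & wm >= tm_threshold
  r <- rle(hot)
  sum(r$values & r$lengths >= window)
}

#' Heuristic protein localization from hydropathy
#'
#' A deterministic, download-free stand-in for signal-peptide and
#' transmembrane predictors. A transmembrane (TM) segment is called where the
#' centered Kyte-Doolittle window mean (window 19) stays at or above
#' \code{tm_threshold} (default 1.6) over at least \code{window} consecutive
#' window centers. A signal peptide is called when the first 5 residues
#' contain at least one K/R (the charged N-region) and the first
#' \code{sp_max_pos} residues (default 35) contain a hydrophobic stretch of
#' at least 8 residues with mean hydropathy at or above \code{tm_threshold}.
#' Categories follow the precedence rule: TM segments (searched after the
#' first \code{sp_max_pos} residues when a signal peptide is called) make a
#' protein \code{transmembrane}; otherwise a signal peptide makes it
#' \code{secreted}; otherwise it is \code{cytoplasmic}. Sequences shorter
#' than the window are called \code{cytoplasmic} and flagged.
#'
#' This heuristic is intentionally simple; imported predictions (see
#' [import_localization()]) are the fidelity route when annotations exist.
#'
#' @param x a proteome data frame or character vector of sequences.
#' @param window TM sliding-window width in residues (default 19).
#' @param tm_threshold mean Kyte-Doolittle hydropathy threshold (default 1.6).
#' @param sp_max_pos last residue considered part of a signal peptide
#'   (default 35).
#' @return data frame with columns \code{protein_id}, \code{category},
#'   \code{n_tm_segments}, \code{has_signal_peptide}, \code{evidence}
#'   (always \code{"heuristic"}), \code{short_sequence}.
#' @export
heuristic_localization <- function(x, window = 19L, tm_threshold = 1.6,
                                   sp_max_pos = 35L) {
  seqs <- as_sequences(x)
  out <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    h <- unname(KYTE_DOOLITTLE[chars])
    h[is.na(h)] <- 0
    n <- length(h)
    if (n < window) {
      return(data.frame(protein_id = names(seqs)[i],
                        category = "cytoplasmic", n_tm_segments = 0L,
                        has_signal_peptide = FALSE, evidence = "heuristic",
                        short_sequence = TRUE, stringsAsFactors = FALSE))
    }
    n_region <- any(chars[seq_len(min(5, n))] %in% c("K", "R"))
    hcall <- .call_one(h, window, tm_threshold, sp_max_pos)
    n_tm_all <- .count_tm(h, window, tm_threshold, from = 1L)
    n_tm_masked <- .count_tm(h, window, tm_threshold,
                             from = min(sp_max_pos + 1L, n))
    # a signal peptide needs a short early hydrophobic stretch that is NOT
    # itself a full TM segment: if masking the SP region removes a TM call,
    # the stretch was a membrane anchor, not a signal peptide
    sp <- n_region && hcall$sp && n_tm_all == n_tm_masked
    n_tm <- if (sp) n_tm_masked else n_tm_all
    category <- if (n_tm >= 1L) "transmembrane" else if (sp) "secreted" else "cytoplasmic"
    data.frame(protein_id = names(seqs)[i], category = category,
               n_tm_segments = n_tm, has_signal_peptide = sp,
               evidence = "heuristic", short_sequence = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Import external localization predictions
#'
#' Reads a TSV with columns \code{protein_id}, \code{has_signal_peptide}
#' (logical or 0/1), \code{n_tm_segments} (count of predicted TM segments
#' outside the signal peptide), as exported from signal-peptide/TM
#' predictors, and derives the category by the same precedence rule as
#' [heuristic_localization()]: TM segments dominate, then signal peptide,
#' else cytoplasmic.
#'
#' @param path path to the TSV.
#' @return data frame with columns \code{protein_id}, \code{category},
#'   \code{n_tm_segments}, \code{has_signal_peptide}, \code{evidence}
#'   (always \code{"imported"}).
#' @export
import_localization <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("protein_id", "has_signal_peptide", "n_tm_segments")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stopf("localization table missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  sp <- as.logical(tab$has_signal_peptide)
  ntm <- as.integer(tab$n_tm_segments)
  if (any(is.na(sp)) || any(is.na(ntm)) || any(ntm < 0)) {
    stopf("has_signal_peptide must be logical/0-1 and n_tm_segments a count")
  }
  category <- ifelse(ntm >= 1L, "transmembrane",
                     ifelse(sp, "secreted", "cytoplasmic"))
  data.frame(protein_id = tab$protein_id, category = category,
             n_tm_segments = ntm, has_signal_peptide = sp,
             evidence = "imported", stringsAsFactors = FALSE)
}

#' Localize every protein of a proteome
#'
#' Combines imported predictions (which take precedence) with the heuristic
#' fallback so that every protein receives exactly one category; the three
#' categories partition the proteome. Annotation rows whose
#' \code{protein_id} does not occur in the proteome are dropped with a
#' warning.
#'
#' @param proteome a proteome data frame from [read_proteome()].
#' @param annotations optional: a path to a localization TSV or a data frame
#'   from [import_localization()].
#' @param ... passed to [heuristic_localization()].
#' @return data frame with one row per protein: \code{protein_id},
#'   \code{category}, \code{n_tm_segments}, \code{has_signal_peptide},
#'   \code{evidence}.
#' @export
localize_proteome <- function(proteome, annotations = NULL, ...) {
  seqs <- as_sequences(proteome)
  imported <- NULL
  if (!is.null(annotations)) {
    imported <- if (is.character(annotations)) {
      import_localization(annotations)
    } else {
      annotations
    }
    unknown <- setdiff(imported$protein_id, names(seqs))
    if (length(unknown)) {
      warning(sprintf("%d annotation row(s) match no protein and were dropped",
                      length(unknown)), call. = FALSE)
      imported <- imported[!imported$protein_id %in% unknown, , drop = FALSE]
    }
  }
  need_heuristic <- setdiff(names(seqs), imported$protein_id %||% character())
  calls <- list()
  if (!is.null(imported) && nrow(imported)) {
    calls[[1]] <- imported[c("protein_id", "category", "n_tm_segments",
                             "has_signal_peptide", "evidence")]
  }
  if (length(need_heuristic)) {
    h <- heuristic_localization(seqs[need_heuristic], ...)
    calls[[length(calls) + 1L]] <- h[c("protein_id", "category",
                                       "n_tm_segments", "has_signal_peptide",
                                       "evidence")]
  }
  out <- do.call(rbind, calls)
  out <- out[match(names(seqs), out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
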