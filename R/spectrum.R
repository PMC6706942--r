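#' Bin a list of isoelectric points into a relative-frequency spectrum
#'
#' Builds the binned pI histogram ("pI spectrum") of a proteome. Bins are
#' half-open \code{[lo, hi)} with the last bin closed; the default is width
#' 0.25 over \[2, 14\], which resolves the canonical acidic/neutral/basic
#' proteome peaks (near 4.5, 6.8 and 9.8) and nests exactly inside the
#' aggregate ranges used by [acid_neutral_basic()]. pI values falling outside
#' the range (possible for extremely acidic proteins) are counted in the
#' nearest boundary bin so that frequencies always sum to 1.
#'
#' @param pis numeric vector of pI values (NA dropped).
#' @param bin_width bin width in pH units (> 0; default 0.25).
#' @param range length-2 numeric, default \code{c(2, 14)}; must be an integer
#'   number of bins wide.
#' @param label a name carried on the spectrum (proteome id, category, ...).
#' @return an object of class \code{pi_spectrum}: list with
#'   \code{bin_edges}, \code{rel_freq}, \code{counts}, \code{n_proteins},
#'   \code{label}.
#' @export
bin_spectrum <- function(pis, bin_width = 0.25, range = c(2, 14), label = "") {
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("`bin_width` must be > 0")
  lo <- range[1]; hi <- range[2]
  nb <- (hi - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-8) {
    stopf("range width must be an integer multiple of bin_width")
  }
  nb <- as.integer(round(nb))
  edges <- lo + bin_width * (0:nb)
  pis <- pis[!is.na(pis)]
  n <- length(pis)
  counts <- integer(nb)
  if (n > 0) {
    idx <- floor((pis - lo) / bin_width) + 1
    idx[idx < 1] <- 1L            # clamp out-of-range values to edge bins
    idx[idx > nb] <- nb
    counts <- tabulate(as.integer(idx), nbins = nb)
  }
  rel <- if (n > 0) counts / n else rep(0, nb)
  structure(list(bin_edges = edges, rel_freq = rel, counts = counts,
                 n_proteins = n, label = label),
            class = "pi_spectrum")
}

#' @export
print.pi_spectrum <- function(x, ...) {
  cat(sprintf("pI spectrum '%s': %d proteins, %d bins on [%g, %g]\n",
              x$label, x$n_proteins, length(x$rel_freq),
              min(x$bin_edges), max(x$bin_edges)))
  if (x$n_proteins > 0) {
    agg <- acid_neutral_basic(x)
    cat(sprintf("  acid %.3f / neutral %.3f / basic %.3f\n",
                agg[["acid_fraction"]], agg[["neutral_fraction"]],
                agg[["basic_fraction"]]))
  }
  invisible(x)
}

bin_centers <- function(spec) {
  e <- spec$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Acid, neutral and basic fractions of a pI spectrum
#'
#' Sums relative frequencies over the three conventional pI windows:
#' acid 3.25-6.25, neutral 6.75-7.25, basic 7.75-13.75 (inclusive on bin
#' centers). The ranges deliberately leave gaps, so the three fractions sum
#' to at most 1. The default bin layout nests inside the ranges; an
#' incompatible layout (a range boundary cutting through a bin) is a
#' configuration error.
#'
#' @param spec a \code{pi_spectrum}.
#' @param ranges named list of length-2 numeric ranges; defaults to the
#'   conventional windows above.
#' @return named numeric vector \code{c(acid_fraction, neutral_fraction,
#'   basic_fraction)}.
#' @export
acid_neutral_basic <- function(spec,
                               ranges = list(acid = c(3.25, 6.25),
                                             neutral = c(6.75, 7.25),
                                             basic = c(7.75, 13.75))) {
  stopifnot(inherits(spec, "pi_spectrum"))
  centers <- bin_centers(spec)
  w <- diff(spec$bin_edges[1:2])
  out <- vapply(ranges, function(r) {
    # range boundaries must coincide with a bin edge or bin center
    for (b in r) {
      off <- (b - spec$bin_edges[1]) / w
      frac <- off - floor(off)
      if (!(frac < 1e-6 || frac > 1 - 1e-6 || abs(frac - 0.5) < 1e-6)) {
        stopf("aggregate range boundary %g does not align with the bin layout", b)
      }
    }
    sum(spec$rel_freq[centers >= r[1] - 1e-9 & centers <= r[2] + 1e-9])
  }, numeric(1))
  names(out) <- paste0(names(ranges), "_fraction")
  out
}

#' Per-group mean and standard deviation of spectrum aggregates
#'
#' Computes [acid_neutral_basic()] for each spectrum and summarizes each
#' component per group (habitat) with the mean and the unbiased (n-1)
#' standard deviation; single-member groups report SD as NA.
#'
#' @param specs list of \code{pi_spectrum} objects.
#' @param groups character vector of group labels, one per spectrum.
#' @return data frame with columns \code{group}, \code{component},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
group_aggregate_stats <- function(specs, groups) {
  if (length(specs) != length(groups)) {
    stopf("`specs` and `groups` must have the same length")
  }
  if (any(is.na(groups) | !nzchar(groups))) {
    stopf("every spectrum needs a non-missing group label")
  }
  aggs <- t(vapply(specs, acid_neutral_basic, numeric(3)))
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    m <- aggs[groups == g, , drop = FALSE]
    data.frame(group = g, component = colnames(aggs),
               mean = colMeans(m),
               sd = if (nrow(m) > 1) apply(m, 2, sd) else NA_real_,
               n = nrow(m), row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Peak positions of a pI spectrum
#'
#' Smooths the spectrum with a 3-bin moving average, finds local maxima
#' (within a plateau of equal smoothed values the peak bin is the one with
#' the largest raw mass, ties to the lowest pH), ranks them by smoothed
#' height, and greedily suppresses any maximum closer than
#' \code{min_separation} to an already-accepted higher one. Whole-proteome
#' spectra typically show up to three peaks (acidic, neutral, basic).
#'
#' @param spec a \code{pi_spectrum}.
#' @param min_separation minimum pH distance between reported peaks
#'   (default 1.0).
#' @param min_height noise floor: local maxima whose smoothed height is
#'   below this fraction of the tallest one are not peaks (default 0.1).
#' @param max_peaks optional cap on the number of reported peaks.
#' @return numeric vector of bin centers, ordered by decreasing peak height.
#' @export
peak_positions <- function(spec, min_separation = 1.0, min_height = 0.1,
                           max_peaks = Inf) {
  stopifnot(inherits(spec, "pi_spectrum"))
  y <- spec$rel_freq
  nb <- length(y)
  if (spec$n_proteins == 0 || nb == 0) return(numeric(0))
  # moving average, window 3; edges average over the available bins
  ypad <- c(y[1], y, y[nb])
  sm <- (ypad[1:nb] + ypad[2:(nb + 1)] + ypad[3:(nb + 2)]) / 3
  centers <- bin_centers(spec)
  # local maxima over runs of equal smoothed values: a run is a maximum when
  # it exceeds both neighboring runs; within a run the peak bin is the one
  # with the largest raw mass (ties resolved to the lowest-pH bin)
  r <- rle(sm)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  nr <- length(r$values)
  left <- c(-Inf, r$values[-nr])
  right <- c(r$values[-1], -Inf)
  max_runs <- which(r$values > left & r$values > right)
  cand <- vapply(max_runs, function(k) {
    bins <- run_start[k]:run_end[k]
    bins[which.max(y[bins])]
  }, integer(1))
  cand <- cand[sm[cand] >= min_height * max(sm) & sm[cand] > 0]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(-sm[cand], centers[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(centers[i] - centers[kept]) >= min_separation)) {
      kept <- c(kept, i)
    }
    if (length(kept) >= max_peaks) break
  }
  centers[kept]
}

#' Full pI profile of a proteome
#'
#' Convenience wrapper: computes per-protein pIs with [protein_pi()], bins
#' them with [bin_spectrum()], and returns the spectrum together with the
#' aggregate fractions and peak positions. When localization calls are
#' supplied, per-category spectra (secreted / transmembrane / cytoplasmic)
#' are attached alongside the whole-proteome spectrum.
#'
#' @param proteome a proteome data frame.
#' @param localization optional data frame from [localize_proteome()].
#' @param pka,tol passed to [protein_pi()].
#' @param bin_width,range passed to [bin_spectrum()].
#' @param label spectrum label; defaults to the proteome id when present.
#' @return list with elements \code{pi_table}, \code{spectrum} (whole
#'   proteome), \code{aggregates}, \code{peaks}, and \code{by_category}
#'   (NULL or a named list of spectra).
#' @export
proteome_profile <- function(proteome, localization = NULL, pka = "emboss",
                             tol = 1e-3, bin_width = 0.25, range = c(2, 14),
                             label = NULL) {
  if (is.null(label)) {
    label <- if (is.data.frame(proteome) && "proteome_id" %in% names(proteome) &&
                 nrow(proteome)) proteome$proteome_id[1] else ""
  }
  tab <- protein_pi(proteome, pka = pka, tol = tol)
  spec <- bin_spectrum(tab$pI, bin_width = bin_width, range = range,
                       label = label)
  by_cat <- NULL
  if (!is.null(localization)) {
    loc <- localization[match(tab$protein_id, localization$protein_id),
                        "category"]
    by_cat <- lapply(LOCALIZATION_LEVELS, function(cat) {
      bin_spectrum(tab$pI[!is.na(loc) & loc == cat], bin_width = bin_width,
                   range = range, label = paste(label, cat, sep = ":"))
    })
    names(by_cat) <- LOCALIZATION_LEVELS
  }
  list(pi_table = tab, spectrum = spec,
       aggregates = acid_neutral_basic(spec),
       peaks = peak_positions(spec), by_category = by_cat)
}
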