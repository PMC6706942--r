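# FNV-1a hash of a string; used to stamp a config fingerprint into run
# manifests without adding a dependency.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.load_proteomes <- function(proteomes) {
  if (is.character(proteomes)) {
    ids <- names(proteomes)
    if (is.null(ids)) {
      ids <- sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(proteomes))
    }
    proteomes <- Map(read_proteome, proteomes, ids)
    names(proteomes) <- ids
  }
  if (!is.list(proteomes) || is.null(names(proteomes))) {
    stopf("`proteomes` must be a named list of proteome data frames or a named vector of FASTA paths")
  }
  proteomes
}

#' Run the cohort analysis: spectra, distances, PERMANOVA, PCA
#'
#' End-to-end workflow for a panel of habitat-annotated proteomes: computes
#' each proteome's pI spectrum, builds the Bray-Curtis distance matrix
#' between the relative-frequency profiles, runs a one-way PERMANOVA for
#' each requested factor (habitat and/or taxon), a PCA of the profiles, and
#' the per-habitat mean/SD table of the acid/neutral/basic aggregates. With
#' fewer than 3 proteomes the statistics are skipped with an explicit notice
#' and only the spectra are produced. All outputs are deterministic given
#' the inputs and \code{seed}.
#'
#' @param proteomes named list of proteome data frames, or a named character
#'   vector of FASTA paths.
#' @param metadata metadata data frame (or TSV path) with columns
#'   \code{proteome_id}, \code{habitat}, \code{taxon}.
#' @param factors factors to test, subset of \code{c("habitat", "taxon")}.
#' @param pka,bin_width,range spectrum parameters.
#' @param n_permutations,seed PERMANOVA settings.
#' @param out_dir optional output directory; when given, writes per-proteome
#'   spectrum TSVs, the distance matrix, PERMANOVA JSON, PCA scores TSV,
#'   aggregate-stats TSV and a run manifest JSON.
#' @return list with \code{spectra}, \code{profiles} (matrix),
#'   \code{distance}, \code{permanova} (named by factor), \code{pca},
#'   \code{aggregate_stats}, \code{manifest}.
#' @export
run_cohort_analysis <- function(proteomes, metadata,
                                factors = c("habitat", "taxon"),
                                pka = "emboss", bin_width = 0.25,
                                range = c(2, 14), n_permutations = 999,
                                seed = 1, out_dir = NULL) {
  proteomes <- .load_proteomes(proteomes)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  missing_meta <- setdiff(names(proteomes), metadata$proteome_id)
  if (length(missing_meta)) {
    stopf("proteome(s) missing from metadata: %s",
          paste(missing_meta, collapse = ", "))
  }
  metadata <- metadata[match(names(proteomes), metadata$proteome_id), ]
  spectra <- lapply(names(proteomes), function(pid) {
    tab <- protein_pi(proteomes[[pid]], pka = pka)
    bin_spectrum(tab$pI, bin_width = bin_width, range = range, label = pid)
  })
  names(spectra) <- names(proteomes)
  profiles <- as_profile_matrix(spectra)
  n <- length(spectra)
  perm <- list(); pca <- NULL; dmat <- NULL; aggstats <- NULL
  if (n < 3) {
    message("fewer than 3 proteomes: distance/PERMANOVA/PCA skipped")
  } else {
    dmat <- bray_curtis_matrix(profiles)
    for (f in factors) {
      g <- metadata[[f]]
      if (length(unique(g[!is.na(g)])) < 2) {
        message(sprintf("factor '%s' has < 2 levels: skipped", f))
        next
      }
      perm[[f]] <- permanova(dmat, g, n_permutations = n_permutations,
                             seed = seed)
    }
    pca <- pca_profiles(profiles, n_components = 2)
    if (all(!is.na(metadata$habitat))) {
      aggstats <- group_aggregate_stats(spectra, metadata$habitat)
    }
  }
  config <- list(pka = pka_set(pka)$name, bin_width = bin_width,
                 range = range, factors = factors,
                 n_permutations = n_permutations, seed = seed)
  manifest <- list(
    tool = "piscape",
    version = as.character(utils::packageVersion("piscape")),
    seed = seed,
    config_hash = .fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    config = config, n_proteomes = n)
  result <- list(spectra = spectra, profiles = profiles, distance = dmat,
                 permanova = perm, pca = pca, aggregate_stats = aggstats,
                 manifest = manifest)
  if (!is.null(out_dir)) .write_cohort_bundle(result, out_dir)
  result
}

.provenance_header <- function(manifest) {
  sprintf("# %s %s | seed %s | config %s", manifest$tool, manifest$version,
          manifest$seed, manifest$config_hash)
}

.write_tsv <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(manifest), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_cohort_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- result$manifest
  for (pid in names(result$spectra)) {
    s <- result$spectra[[pid]]
    df <- data.frame(bin_lo = s$bin_edges[-length(s$bin_edges)],
                     bin_hi = s$bin_edges[-1], rel_freq = s$rel_freq,
                     count = s$counts)
    .write_tsv(df, file.path(out_dir, paste0("spectrum_", pid, ".tsv")), man)
  }
  if (!is.null(result$distance)) {
    d <- as.data.frame(result$distance)
    d <- cbind(proteome_id = rownames(result$distance), d)
    .write_tsv(d, file.path(out_dir, "bray_curtis.tsv"), man)
  }
  if (length(result$permanova)) {
    perm <- lapply(result$permanova, function(p) {
      list(pseudo_F = p$pseudo_F, r_squared = p$r_squared,
           p_value = p$p_value, n_permutations = p$n_permutations,
           seed = p$seed)
    })
    jsonlite::write_json(perm, file.path(out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$pca)) {
    sc <- as.data.frame(result$pca$scores)
    sc <- cbind(proteome_id = rownames(result$pca$scores), sc)
    .write_tsv(sc, file.path(out_dir, "pca_scores.tsv"), man)
  }
  if (!is.null(result$aggregate_stats)) {
    .write_tsv(result$aggregate_stats,
               file.path(out_dir, "aggregate_stats.tsv"), man)
  }
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run a pairwise marine/freshwater genome comparison
#'
#' Thin orchestration over [compare_pair()]: resolves the localization mode,
#' runs the comparison, optionally attaches externally supplied nucleotide
#' identity values (ANI, 16S identity - quantities this package does not
#' compute) verbatim to the report, and writes a JSON + TSV bundle when an
#' output directory is given.
#'
#' @param proteome_a,proteome_b proteome data frames or FASTA paths.
#' @param localization_mode \code{"heuristic"} (default), \code{"imported"}
#'   (annotation tables required; no silent fallback) or \code{"merged"}
#'   (imported calls take precedence, heuristic fills the gaps).
#' @param annotations_a,annotations_b localization TSV paths or data frames
#'   (required for \code{"imported"}/\code{"merged"}).
#' @param external_metadata optional named list (e.g.
#'   \code{list(ani = 66.5, s16_identity = 91.2)}) passed through verbatim.
#' @param out_dir optional output directory.
#' @param ... passed to [compare_pair()].
#' @return the \code{pair_comparison} object with an \code{external}
#'   element.
#' @export
run_pair_analysis <- function(proteome_a, proteome_b,
                              localization_mode = c("heuristic", "imported",
                                                    "merged"),
                              annotations_a = NULL, annotations_b = NULL,
                              external_metadata = NULL, out_dir = NULL, ...) {
  localization_mode <- match.arg(localization_mode)
  if (is.character(proteome_a)) proteome_a <- read_proteome(proteome_a, "a")
  if (is.character(proteome_b)) proteome_b <- read_proteome(proteome_b, "b")
  resolve <- function(proteome, annotations, who) {
    if (localization_mode == "heuristic") {
      return(localize_proteome(proteome))
    }
    if (is.null(annotations)) {
      stopf("localization_mode '%s' requires annotations for proteome %s",
            localization_mode, who)
    }
    if (localization_mode == "imported") {
      imp <- if (is.character(annotations)) import_localization(annotations) else annotations
      missing <- setdiff(proteome$protein_id, imp$protein_id)
      if (length(missing)) {
        stopf("imported mode: %d protein(s) of proteome %s lack annotations",
              length(missing), who)
      }
      return(imp)
    }
    localize_proteome(proteome, annotations)
  }
  loc_a <- resolve(proteome_a, annotations_a, "a")
  loc_b <- resolve(proteome_b, annotations_b, "b")
  cmp <- compare_pair(proteome_a, proteome_b, loc_a, loc_b, ...)
  cmp$external <- external_metadata
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      aai = cmp$aai, n_rbh_pairs = cmp$n_rbh_pairs, pocp = cmp$pocp,
      n_core_a = length(cmp$partition$core_a),
      n_core_b = length(cmp$partition$core_b),
      n_flexible_a = length(cmp$partition$flexible_a),
      n_flexible_b = length(cmp$partition$flexible_b),
      acid_fraction = as.list(cmp$acid_fraction),
      higher_acid = cmp$higher_acid,
      mean_pi = list(a = as.list(cmp$mean_pi["a", ]),
                     b = as.list(cmp$mean_pi["b", ])),
      composition_delta = as.list(cmp$composition_delta),
      external = external_metadata)
    jsonlite::write_json(report, file.path(out_dir, "pair_report.json"),
                         auto_unbox = TRUE, digits = NA)
    man <- list(tool = "piscape",
                version = as.character(utils::packageVersion("piscape")),
                seed = NA, config_hash = .fnv1a("pair"))
    for (g in c("a", "b")) {
      for (nm in names(cmp$spectra[[g]])) {
        s <- cmp$spectra[[g]][[nm]]
        df <- data.frame(bin_lo = s$bin_edges[-length(s$bin_edges)],
                         bin_hi = s$bin_edges[-1], rel_freq = s$rel_freq)
        .write_tsv(df, file.path(out_dir,
                                 sprintf("spectrum_%s_%s.tsv", g, nm)), man)
      }
    }
  }
  cmp
}
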