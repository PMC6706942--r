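# Baseline residue frequencies (Mole%) typical of prokaryotic proteomes;
# normalized to sum exactly to 1 when used as sampling probabilities. The
# neutral polar pool {N,Q,S,T} holds ~19%, which is the reservoir the
# acid/basic shifts draw from.
BASELINE_COMPOSITION <- c(
  A = 8.8, C = 1.0, D = 5.4, E = 6.2, F = 3.9, G = 7.4, H = 2.1, I = 6.0,
  K = 5.2, L = 10.2, M = 2.3, N = 3.9, P = 4.4, Q = 3.8, R = 5.6, S = 6.0,
  T = 5.4, V = 7.0, W = 1.2, Y = 3.1
)

ACID_RESIDUES <- c("D", "E")
BASIC_RESIDUES <- c("K", "R", "H")
POLAR_POOL <- c("N", "Q", "S", "T")
TM_ALPHABET <- c("L", "I", "V", "F")

#' Shift a residue composition toward acidic or basic usage
#'
#' Moves \code{acid_delta} Mole% onto \{D, E\} and \code{basic_delta} Mole%
#' onto \{K, R, H\} (each distributed proportionally to the baseline weights
#' of the receiving residues), taking the mass proportionally from the
#' neutral polar pool \{N, Q, S, T\}. Drawing from the polar pool keeps
#' overall hydrophobicity approximately unchanged, so the shift alters
#' charge - the effect under study - without disturbing the localization
#' heuristics. Negative deltas move mass the other way.
#'
#' @param base named Mole% vector over the 20 standard residues (default
#'   [BASELINE_COMPOSITION]).
#' @param acid_delta,basic_delta Mole% to move (can be negative).
#' @return a probability vector (sums to 1) over the 20 residues.
#' @export
shift_composition <- function(base = BASELINE_COMPOSITION, acid_delta = 0,
                              basic_delta = 0) {
  if (!all(AA_STANDARD %in% names(base))) {
    stopf("`base` must name all 20 standard residues")
  }
  comp <- base[AA_STANDARD] / sum(base[AA_STANDARD]) * 100
  move <- function(comp, onto, delta) {
    comp[onto] <- comp[onto] + delta * comp[onto] / sum(comp[onto])
    comp[POLAR_POOL] <- comp[POLAR_POOL] - delta * comp[POLAR_POOL] / sum(comp[POLAR_POOL])
    comp
  }
  comp <- move(comp, ACID_RESIDUES, acid_delta)
  comp <- move(comp, BASIC_RESIDUES, basic_delta)
  if (any(comp < 0)) {
    stopf("composition shift drives residue(s) negative: %s",
          paste(names(comp)[comp < 0], collapse = ", "))
  }
  comp / sum(comp)
}

#' Specification for a synthetic proteome
#'
#' Bundles the parameters of the generator: protein count, a log-normal
#' length law (median 250 residues, sigma 0.45, minimum 30 - plausible
#' prokaryotic protein lengths), the baseline composition and the
#' acidic/basic shifts applied to it, the fractions of proteins carrying
#' planted signal peptides or transmembrane helices, the per-site
#' substitution probability used when deriving a partner proteome, and the
#' seed that fully determines the output.
#'
#' @param n_proteins number of proteins.
#' @param acid_shift_delta,basic_shift_delta Mole% shifts, see
#'   [shift_composition()].
#' @param frac_secreted,frac_tm fractions with planted signal peptides /
#'   TM segments (deterministic allocation: \code{round(frac * n)} proteins);
#'   their sum must be at most 1.
#' @param length_median,length_sigma log-normal length law parameters.
#' @param mutation_rate per-site substitution probability for derived pairs.
#' @param baseline baseline Mole% composition.
#' @param seed integer seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_proteins = 300, acid_shift_delta = 0,
                           basic_shift_delta = 0, frac_secreted = 0,
                           frac_tm = 0, length_median = 250,
                           length_sigma = 0.45, mutation_rate = 0.2,
                           baseline = BASELINE_COMPOSITION, seed = 1) {
  if (frac_secreted + frac_tm > 1 + 1e-12) {
    stopf("frac_secreted + frac_tm must be at most 1")
  }
  if (n_proteins < 1) stopf("n_proteins must be at least 1")
  comp <- shift_composition(baseline, acid_shift_delta, basic_shift_delta)
  structure(list(n_proteins = as.integer(n_proteins),
                 acid_shift_delta = acid_shift_delta,
                 basic_shift_delta = basic_shift_delta,
                 frac_secreted = frac_secreted, frac_tm = frac_tm,
                 length_median = length_median, length_sigma = length_sigma,
                 mutation_rate = mutation_rate, baseline = baseline,
                 composition = comp, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# -- internal sequence builders (run inside an active with_seed stream) ------

.rand_residues <- function(n, comp) {
  if (n <= 0) return(character(0))
  sample(AA_STANDARD, n, replace = TRUE, prob = comp)
}

# signal peptide: Met + charged N-region (K/R) + short polar linker + 10-mer
# hydrophobic core; 15 residues, well inside the 35-residue search window
.make_signal_peptide <- function() {
  c("M", sample(c("K", "R"), 2, replace = TRUE),
    sample(c("S", "Q"), 2, replace = TRUE),
    sample(TM_ALPHABET, 10, replace = TRUE))
}

# one protein as a character vector plus the planted-feature annotation
.build_protein <- function(len, comp, category) {
  if (category == "secreted") {
    sp <- .make_signal_peptide()
    body <- .rand_residues(max(len - length(sp), 15L), comp)
    chars <- c(sp, body)
    segs <- list(sp_hregion = c(6L, 15L))
    n_tm <- 0L
  } else if (category == "transmembrane") {
    n_tm <- sample.int(3L, 1)
    n_loop_res <- max(len - n_tm * 21L, (n_tm + 1L) * 5L)
    cuts <- sort(sample.int(n_loop_res - 1L, n_tm))
    loop_lens <- diff(c(0L, cuts, n_loop_res))
    chars <- character(0)
    segs <- list()
    for (k in seq_len(n_tm)) {
      chars <- c(chars, .rand_residues(loop_lens[k], comp))
      start <- length(chars) + 1L
      chars <- c(chars, sample(TM_ALPHABET, 21, replace = TRUE))
      segs[[paste0("tm", k)]] <- c(start, start + 20L)
    }
    chars <- c(chars, .rand_residues(loop_lens[n_tm + 1L], comp))
  } else {
    chars <- .rand_residues(len, comp)
    segs <- list()
    n_tm <- 0L
  }
  list(chars = chars, segments = segs, n_tm = n_tm)
}

.draw_lengths <- function(n, median, sigma) {
  pmax(30L, as.integer(round(rlnorm(n, log(median), sigma))))
}

#' Generate a seeded synthetic proteome with ground truth
#'
#' Draws protein lengths from the spec's log-normal law and residues i.i.d.
#' from the (shifted) composition; plants an N-terminal signal peptide in
#' \code{round(frac_secreted * n)} proteins and 1-3 hydrophobic
#' transmembrane 21-mers (alphabet L/I/V/F) in \code{round(frac_tm * n)}
#' proteins. The output is fully determined by the spec seed. The ground
#' truth table records every protein's planted category, so localization and
#' classification operations can be scored without re-deriving anything.
#'
#' @param spec a [synthetic_spec()].
#' @param proteome_id id stamped on the records (default "synthetic").
#' @return list with \code{records} (proteome data frame) and \code{truth}
#'   (data frame: \code{protein_id}, \code{category}, \code{n_tm_segments},
#'   \code{has_signal_peptide}).
#' @export
generate_proteome <- function(spec, proteome_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, .generate_proteome_impl(spec, proteome_id))
}

.generate_proteome_impl <- function(spec, proteome_id) {
  n <- spec$n_proteins
  n_tm <- round(spec$frac_tm * n)
  n_sec <- round(spec$frac_secreted * n)
  categories <- c(rep("transmembrane", n_tm), rep("secreted", n_sec),
                  rep("cytoplasmic", n - n_tm - n_sec))
  lens <- .draw_lengths(n, spec$length_median, spec$length_sigma)
  built <- lapply(seq_len(n), function(i) {
    .build_protein(lens[i], spec$composition, categories[i])
  })
  ids <- sprintf("%s_p%04d", proteome_id, seq_len(n))
  records <- data.frame(
    protein_id = ids, proteome_id = proteome_id,
    sequence = vapply(built, function(b) paste(b$chars, collapse = ""),
                      character(1)),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    protein_id = ids, category = categories,
    n_tm_segments = vapply(built, function(b) b$n_tm, integer(1)),
    has_signal_peptide = categories == "secreted",
    stringsAsFactors = FALSE)
  list(records = records, truth = truth,
       segments = lapply(built, function(b) b$segments))
}

#' Generate an orthologous "marine"/"freshwater" proteome pair
#'
#' Emulates a pair of closely related genomes adapted to different habitats.
#' Proteome A is drawn under a composition with a positive acidic shift
#' (\code{acid_delta} Mole% onto D/E, the marine signature) and proteome B's
#' residues follow a composition with a positive basic shift
#' (\code{basic_delta} onto K/R/H, the freshwater signature). Shared
#' proteins are generated in A, copied to B, and re-sampled site by site:
#' with probability \code{mutation_rate} a site is redrawn from B's
#' composition, which biases homologs toward B's residue usage while keeping
#' identity recognizable. Sites inside planted transmembrane segments or
#' signal-peptide hydrophobic cores are redrawn from the hydrophobic
#' alphabet instead, mimicking the purifying selection that keeps membrane
#' spans hydrophobic. Unique proteins are drawn fresh per side. Secreted
#' proteins can receive an extra habitat shift (\code{secreted_extra_delta})
#' on top of the global one, emulating the stronger adaptation of proteins
#' exposed to the extracellular medium; transmembrane proteins receive only
#' \code{tm_shift_factor} of the habitat shift, since membrane-embedded
#' chains meet the aqueous phase over a small part of their surface.
#'
#' @param n_shared,n_unique_each counts of orthologous and side-specific
#'   proteins.
#' @param acid_delta,basic_delta Mole% shifts for A (acidic) and B (basic).
#' @param secreted_extra_delta additional Mole% shift applied to secreted
#'   proteins on both sides (acidic for A, basic for B).
#' @param tm_shift_factor fraction of the habitat shift applied to
#'   transmembrane proteins (default 0.25).
#' @param mutation_rate per-site substitution probability for shared
#'   proteins.
#' @param frac_secreted,frac_tm planted-feature fractions (applied to the
#'   shared set and each unique set).
#' @param length_median,length_sigma length law.
#' @param seed integer seed; the pair is fully seed-determined.
#' @return list with \code{a}, \code{b} (proteome data frames), \code{truth}
#'   (per-protein genome, category, orthology), and the two localization
#'   tables \code{loc_a}, \code{loc_b} derived from ground truth.
#' @export
generate_pair <- function(n_shared = 80, n_unique_each = 15, acid_delta = 1.0,
                          basic_delta = 1.0, secreted_extra_delta = 0,
                          tm_shift_factor = 0.25, mutation_rate = 0.2,
                          frac_secreted = 0.15, frac_tm = 0.2,
                          length_median = 250, length_sigma = 0.45, seed = 1) {
  with_seed(seed, {
    comp_a <- shift_composition(acid_delta = acid_delta)
    comp_b <- shift_composition(basic_delta = basic_delta)
    comp_a_sec <- shift_composition(acid_delta = acid_delta + secreted_extra_delta)
    comp_b_sec <- shift_composition(basic_delta = basic_delta + secreted_extra_delta)
    comp_a_tm <- shift_composition(acid_delta = tm_shift_factor * acid_delta)
    comp_b_tm <- shift_composition(basic_delta = tm_shift_factor * basic_delta)
    alloc <- function(n) {
      n_tm <- round(frac_tm * n); n_sec <- round(frac_secreted * n)
      c(rep("transmembrane", n_tm), rep("secreted", n_sec),
        rep("cytoplasmic", n - n_tm - n_sec))
    }
    comp_for <- function(category, side) {
      if (category == "secreted") {
        if (side == "a") comp_a_sec else comp_b_sec
      } else if (category == "transmembrane") {
        if (side == "a") comp_a_tm else comp_b_tm
      } else {
        if (side == "a") comp_a else comp_b
      }
    }
    build_set <- function(n, side, prefix) {
      cats <- alloc(n)
      lens <- .draw_lengths(n, length_median, length_sigma)
      built <- lapply(seq_len(n), function(i) {
        .build_protein(lens[i], comp_for(cats[i], side), cats[i])
      })
      list(built = built, cats = cats,
           ids = sprintf("%s_%s%04d", side, prefix, seq_len(n)))
    }
    shared_a <- build_set(n_shared, "a", "core")
    # derive B's orthologs by per-site redraw toward B's composition
    shared_b_chars <- lapply(seq_len(n_shared), function(i) {
      chars <- shared_a$built[[i]]$chars
      segs <- shared_a$built[[i]]$segments
      in_seg <- rep(FALSE, length(chars))
      for (s in segs) in_seg[seq(s[1], s[2])] <- TRUE
      mut <- runif(length(chars)) < mutation_rate
      comp_b_i <- comp_for(shared_a$cats[i], "b")
      if (any(mut & !in_seg)) {
        chars[mut & !in_seg] <- .rand_residues(sum(mut & !in_seg), comp_b_i)
      }
      if (any(mut & in_seg)) {
        chars[mut & in_seg] <- sample(TM_ALPHABET, sum(mut & in_seg),
                                      replace = TRUE)
      }
      chars
    })
    uniq_a <- build_set(n_unique_each, "a", "uniq")
    uniq_b <- build_set(n_unique_each, "b", "uniq")
    seq_of <- function(built) {
      vapply(built, function(x) paste(x$chars, collapse = ""), character(1))
    }
    ids_b_shared <- sub("^a_", "b_", shared_a$ids)
    a <- data.frame(
      protein_id = c(shared_a$ids, uniq_a$ids), proteome_id = "a",
      sequence = c(seq_of(shared_a$built), seq_of(uniq_a$built)),
      stringsAsFactors = FALSE)
    b <- data.frame(
      protein_id = c(ids_b_shared, uniq_b$ids), proteome_id = "b",
      sequence = c(vapply(shared_b_chars, paste, character(1), collapse = ""),
                   seq_of(uniq_b$built)),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      protein_id = c(a$protein_id, b$protein_id),
      genome = c(rep("a", nrow(a)), rep("b", nrow(b))),
      category = c(shared_a$cats, uniq_a$cats, shared_a$cats, uniq_b$cats),
      ortholog_id = c(ids_b_shared, rep(NA, n_unique_each),
                      shared_a$ids, rep(NA, n_unique_each)),
      stringsAsFactors = FALSE)
    loc_of <- function(ids, cats) {
      data.frame(protein_id = ids, category = cats,
                 n_tm_segments = ifelse(cats == "transmembrane", 1L, 0L),
                 has_signal_peptide = cats == "secreted",
                 evidence = "imported", stringsAsFactors = FALSE)
    }
    list(a = a, b = b, truth = truth,
         loc_a = loc_of(a$protein_id, c(shared_a$cats, uniq_a$cats)),
         loc_b = loc_of(b$protein_id, c(shared_a$cats, uniq_b$cats)))
  })
}

#' Generate a multi-habitat cohort of synthetic proteomes
#'
#' Emulates a comparison panel of habitat-adapted genomes. Each habitat has
#' a characteristic composition shift scaled by \code{delta}: marine
#' +\code{delta} Mole% acidic, freshwater +\code{delta} basic, brackish
#' +\code{delta}/2 acidic, halophile +3.5 x \code{delta} acidic combined
#' with -2.5 x \code{delta} basic (the extreme "salt-in" signature: a
#' strongly acidified proteome whose basic peak nearly vanishes). On top of
#' the habitat shift, each proteome receives
#' a small seeded log-normal jitter of its composition (sd 0.02 on the log
#' scale) emulating genome-to-genome variability. \code{delta = 0} yields a
#' structureless null cohort. Taxon labels are assigned round-robin within
#' each habitat and carry no compositional signal of their own.
#'
#' @param n_per_habitat proteomes per habitat.
#' @param habitats habitat labels drawn from
#'   \code{c("freshwater","brackish","marine","halophile")}.
#' @param delta Mole% shift scale (the study condition is 1.0).
#' @param n_proteins proteins per proteome.
#' @param n_taxa number of round-robin taxon labels.
#' @param length_median,length_sigma length law.
#' @param seed integer seed.
#' @param dir optional directory: when given, FASTA files and a
#'   \code{metadata.tsv} are written there.
#' @return list with \code{proteomes} (named list of record data frames) and
#'   \code{metadata} (proteome_id, habitat, taxon).
#' @export
generate_cohort <- function(n_per_habitat = 20,
                            habitats = c("freshwater", "marine"),
                            delta = 1.0, n_proteins = 300, n_taxa = 3,
                            length_median = 250, length_sigma = 0.45,
                            seed = 1, dir = NULL) {
  if (length(habitats) < 2) stopf("a cohort needs at least 2 habitats")
  if (!all(habitats %in% HABITAT_LEVELS)) {
    stopf("habitats must be drawn from: %s",
          paste(HABITAT_LEVELS, collapse = ", "))
  }
  shifts <- list(
    freshwater = c(acid = 0, basic = delta),
    brackish = c(acid = delta / 2, basic = 0),
    marine = c(acid = delta, basic = 0),
    halophile = c(acid = 3.5 * delta, basic = -2.5 * delta)
  )
  with_seed(seed, {
    proteomes <- list()
    meta <- list()
    for (h in habitats) {
      for (i in seq_len(n_per_habitat)) {
        pid <- sprintf("%s_%02d", h, i)
        sh <- shifts[[h]]
        jitter <- exp(rnorm(20, 0, 0.02))
        base <- BASELINE_COMPOSITION[AA_STANDARD] * jitter
        comp <- shift_composition(base, sh[["acid"]], sh[["basic"]])
        spec <- synthetic_spec(
          n_proteins = n_proteins, length_median = length_median,
          length_sigma = length_sigma,
          seed = sample.int(.Machine$integer.max, 1))
        spec$composition <- comp
        pr <- .generate_proteome_impl(spec, pid)
        proteomes[[pid]] <- pr$records
        meta[[pid]] <- data.frame(
          proteome_id = pid, habitat = h,
          taxon = sprintf("taxon%d", ((i - 1) %% n_taxa) + 1),
          stringsAsFactors = FALSE)
      }
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (pid in names(proteomes)) {
        write_proteome(proteomes[[pid]], file.path(dir, paste0(pid, ".faa")))
      }
      write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(proteomes = proteomes, metadata = metadata)
  })
}
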