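make_proteome <- function(seqs, ids, pid) {
  data.frame(protein_id = ids, proteome_id = pid, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("identical proteomes self-hit at 100% identity and full coverage", {
  set.seed(51)
  seqs <- vapply(c(80, 120, 150), random_protein, character(1))
  a <- make_proteome(seqs, c("x1", "x2", "x3"), "a")
  b <- make_proteome(seqs, c("y1", "y2", "y3"), "b")
  hits <- all_vs_all_hits(a, b)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$subject_id, c("y1", "y2", "y3"))
  expect_equal(hits$percent_identity, rep(100, 3))
  expect_equal(hits$alignable_fraction_of_query, rep(1, 3))
  expect_true(all(hits$e_value_proxy < 1e-10))
})

test_that("disjoint short random proteomes produce no hits via the prefilter", {
  set.seed(52)
  a <- make_proteome(vapply(rep(50, 3), random_protein, character(1)),
                     paste0("a", 1:3), "a")
  b <- make_proteome(vapply(rep(50, 3), random_protein, character(1)),
                     paste0("b", 1:3), "b")
  hits <- all_vs_all_hits(a, b)
  expect_equal(nrow(hits), 0)
})

test_that("a single substitution in 100 residues gives 99% identity", {
  set.seed(53)
  s <- random_protein(100)
  chars <- strsplit(s, "")[[1]]
  chars[50] <- if (chars[50] == "A") "G" else "A"
  a <- make_proteome(s, "q", "a")
  b <- make_proteome(paste(chars, collapse = ""), "s", "b")
  hits <- all_vs_all_hits(a, b)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$percent_identity, 99.0, tolerance = 0.51)
})

test_that("alignment scores agree with a quadratic-space Smith-Waterman oracle", {
  mat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  set.seed(54)
  for (i in 1:20) {
    base <- random_protein(40)
    chars <- strsplit(base, "")[[1]]
    # partner: mutate a few sites and delete a short block to force gaps
    idx <- sample(40, 6)
    chars[idx] <- sample(c("A", "G", "S", "T", "K", "D"), 6, replace = TRUE)
    del <- sample(5:30, 1)
    partner <- paste(chars[-(del:(del + 2))], collapse = "")
    a <- make_proteome(base, "q", "a")
    b <- make_proteome(partner, "s", "b")
    hits <- all_vs_all_hits(a, b, min_identity = 0, min_coverage = 0)
    if (nrow(hits) == 1) {
      expect_equal(hits$score, oracle_sw_score(base, partner, mat),
                   tolerance = 1e-9)
    }
  }
})

test_that("AAI and POCP are 100 on self-comparison and symmetric", {
  set.seed(55)
  seqs <- vapply(rep(150, 5), random_protein, character(1))
  a <- make_proteome(seqs, paste0("a", 1:5), "a")
  b <- make_proteome(seqs, paste0("b", 1:5), "b")
  hab <- all_vs_all_hits(a, b); hba <- all_vs_all_hits(b, a)
  aai <- compute_aai(hab, hba)
  expect_equal(aai$aai, 100)
  expect_equal(aai$n_rbh_pairs, 5)
  expect_equal(compute_pocp(hab, hba, 5, 5), 100)
  # symmetry in argument order
  aai_rev <- compute_aai(hba, hab)
  expect_equal(aai_rev$aai, aai$aai)
  expect_equal(aai_rev$n_rbh_pairs, aai$n_rbh_pairs)
})

test_that("empty hit lists give NA AAI with a warning and zero POCP", {
  empty <- all_vs_all_hits(
    make_proteome(strrep("A", 50), "a1", "a"),
    make_proteome(strrep("W", 50), "b1", "b"))
  expect_warning(aai <- compute_aai(empty, empty), "no reciprocal")
  expect_true(is.na(aai$aai))
  expect_equal(compute_pocp(empty, empty, 1, 1), 0)
  expect_error(compute_pocp(empty, empty, 0, 0), "empty")
})

test_that("POCP counts conserved proteins on a toy 3-vs-3 example", {
  set.seed(56)
  shared <- vapply(rep(120, 2), random_protein, character(1))
  a <- make_proteome(c(shared, random_protein(120)), paste0("a", 1:3), "a")
  b <- make_proteome(c(shared, random_protein(120)), paste0("b", 1:3), "b")
  hab <- all_vs_all_hits(a, b); hba <- all_vs_all_hits(b, a)
  expect_equal(compute_pocp(hab, hba, 3, 3), 100 * 4 / 6, tolerance = 1e-9)
})

test_that("core/flexible partition recovers planted orthology", {
  pair <- generate_pair(n_shared = 25, n_unique_each = 6, mutation_rate = 0.2,
                        seed = 57)
  hab <- all_vs_all_hits(pair$a, pair$b)
  hba <- all_vs_all_hits(pair$b, pair$a)
  rbh <- rbh_pairs(hab, hba)
  part <- core_flexible_partition(rbh, pair$a$protein_id, pair$b$protein_id)
  truth_a <- pair$truth[pair$truth$genome == "a", ]
  expect_setequal(part$core_a,
                  truth_a$protein_id[!is.na(truth_a$ortholog_id)])
  expect_setequal(part$flexible_a,
                  truth_a$protein_id[is.na(truth_a$ortholog_id)])
  # partition property
  expect_setequal(c(part$core_a, part$flexible_a), pair$a$protein_id)
  expect_setequal(c(part$core_b, part$flexible_b), pair$b$protein_id)
})

test_that("AAI tracks the planted per-site substitution rate", {
  pair <- generate_pair(n_shared = 30, n_unique_each = 0, mutation_rate = 0.1,
                        seed = 58)
  hab <- all_vs_all_hits(pair$a, pair$b)
  hba <- all_vs_all_hits(pair$b, pair$a)
  aai <- compute_aai(hab, hba)
  expect_lt(abs(aai$aai - 90), 2)
})

test_that("identical proteomes compare with all-core, zero composition delta", {
  set.seed(59)
  seqs <- vapply(rep(150, 6), random_protein, character(1))
  a <- make_proteome(seqs, paste0("a", 1:6), "a")
  b <- make_proteome(seqs, paste0("b", 1:6), "b")
  cmp <- compare_pair(a, b)
  expect_equal(cmp$aai, 100)
  expect_equal(cmp$pocp, 100)
  expect_length(cmp$partition$flexible_a, 0)
  expect_equal(unname(cmp$composition_delta), rep(0, 20))
  expect_equal(cmp$spectra$a$whole$rel_freq, cmp$spectra$b$whole$rel_freq)
})

test_that("the marine member of a synthetic pair is the more acidic one", {
  # sizes and divergence emulate real neighbor pairs (a few hundred proteins,
  # per-site divergence ~0.3 as implied by AAI near 70%); at much smaller
  # sizes the per-pair direction is genuinely underpowered
  pair <- generate_pair(n_shared = 200, n_unique_each = 40, acid_delta = 1.0,
                        basic_delta = 1.0, mutation_rate = 0.3, seed = 60)
  cmp <- compare_pair(pair$a, pair$b, pair$loc_a, pair$loc_b)
  expect_equal(cmp$higher_acid, "a")
  expect_gt(cmp$acid_fraction[["a"]], cmp$acid_fraction[["b"]])
  # the acidic excess persists in the core (where orthologs differ only by
  # the mutation_rate fraction of drifted sites, so non-strict) and is
  # strict in the fully habitat-specific flexible subset
  expect_gte(acid_neutral_basic(cmp$spectra$a$core)[["acid_fraction"]],
             acid_neutral_basic(cmp$spectra$b$core)[["acid_fraction"]])
  expect_gt(acid_neutral_basic(cmp$spectra$a$flexible)[["acid_fraction"]],
            acid_neutral_basic(cmp$spectra$b$flexible)[["acid_fraction"]])
  # and as a D+E Mole% excess in the composition delta
  expect_gt(cmp$composition_delta[["D"]] + cmp$composition_delta[["E"]], 0)
})
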