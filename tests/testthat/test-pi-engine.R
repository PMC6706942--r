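test_that("net charge reaches its asymptotic limits at extreme pH", {
  # KRKR: 4 basic side chains + Nterm fully protonated near pH 0
  expect_gt(net_charge("KRKR", 0), 4.99)
  expect_lt(net_charge("KRKR", 0), 5)
  # DDEE: 4 acidic side chains + Cterm fully deprotonated near pH 14
  expect_lt(net_charge("DDEE", 14), -4.99)
  expect_gt(net_charge("DDEE", 14), -5)
})

test_that("single lysine at pH 7 matches the three-term hand evaluation", {
  # Nterm + K side chain + Cterm under EMBOSS constants, evaluated with an
  # explicit per-group loop (independent of the package's matrix route)
  expect_equal(net_charge("K", 7), oracle_charge("K", 7), tolerance = 1e-12)
  # frozen value from evaluating the three Henderson-Hasselbalch terms
  expect_equal(net_charge("K", 7), 0.975736, tolerance = 1e-6)
})

test_that("ambiguity codes contribute zero charge", {
  expect_equal(net_charge("KXBZK", 7), net_charge("KK", 7))
  expect_equal(net_charge("DUOD", 5), net_charge("DD", 5))
})

test_that("pH outside [0, 14] is a domain error", {
  expect_error(net_charge("K", -0.5), "pH")
  expect_error(net_charge("K", 14.5), "pH")
})

test_that("a sequence with no ionizable side chains returns the terminal midpoint", {
  # charge is antisymmetric around (pKa_Nterm + pKa_Cterm)/2 = 6.10
  expect_equal(isoelectric_point("GGG"), 6.10, tolerance = 2e-3)
  expect_equal(isoelectric_point("GAVLIPFW"), 6.10, tolerance = 2e-3)
})

test_that("bisection pI matches the grid-search oracle on fixed and random cases", {
  expect_equal(isoelectric_point("EEKKH"), oracle_grid_pi("EEKKH"),
               tolerance = 2e-3)
  set.seed(101)
  for (i in 1:50) {
    s <- random_protein(sample(30:200, 1))
    expect_equal(isoelectric_point(s), oracle_grid_pi(s), tolerance = 2e-3)
  }
})

test_that("net charge decreases strictly in pH when an ionizable group exists", {
  set.seed(102)
  for (i in 1:20) {
    s <- random_protein(sample(30:100, 1))
    q <- net_charge(s, seq(0, 14, by = 0.5))
    expect_true(all(diff(q) < 0))
  }
})

test_that("appending D never raises the pI and appending K never lowers it", {
  set.seed(103)
  for (i in 1:60) {
    s <- random_protein(sample(10:80, 1))
    p0 <- isoelectric_point(s)
    expect_lte(isoelectric_point(paste0(s, "D")), p0 + 2e-3)
    expect_gte(isoelectric_point(paste0(s, "K")), p0 - 2e-3)
  }
})

test_that("self-concatenation leaves the pI unchanged in side-chain-only mode", {
  set.seed(104)
  for (i in 1:15) {
    # ensure at least one acidic and one basic group so the zero exists
    s <- paste0("DK", random_protein(sample(20:60, 1)))
    p1 <- isoelectric_point(s, include_termini = FALSE)
    p2 <- isoelectric_point(paste0(s, s), include_termini = FALSE)
    expect_equal(p1, p2, tolerance = 2e-3)
  }
})

test_that("batch protein_pi agrees with the scalar solver and counts charges", {
  set.seed(105)
  seqs <- vapply(sample(30:120, 10), random_protein, character(1))
  names(seqs) <- sprintf("s%02d", 1:10)
  tab <- protein_pi(seqs)
  for (i in seq_along(seqs)) {
    expect_equal(tab$pI[i], isoelectric_point(seqs[[i]]), tolerance = 2e-3)
    chars <- strsplit(seqs[[i]], "")[[1]]
    expect_equal(tab$acidic_count[i], sum(chars %in% c("D", "E")))
    expect_equal(tab$basic_count[i], sum(chars %in% c("K", "R", "H")))
  }
})

test_that("amino-acid composition is Mole% over standard residues only", {
  comp <- aa_composition("DK")
  expect_equal(unname(comp$mole_percent[["D"]]), 50)
  expect_equal(unname(comp$mole_percent[["K"]]), 50)
  expect_equal(sum(comp$mole_percent), 100)

  # ambiguity codes excluded from numerator and denominator
  comp2 <- aa_composition("DX")
  expect_equal(unname(comp2$mole_percent[["D"]]), 100)
  expect_equal(comp2$n_residues, 1)

  set.seed(106)
  comp3 <- aa_composition(vapply(rep(80, 5), random_protein, character(1)))
  expect_equal(sum(comp3$mole_percent), 100, tolerance = 1e-9)

  expect_error(aa_composition("XXX"), "no standard residues")
})

test_that("charged fractions sum acidic and basic Mole%", {
  seq <- paste0(strrep("D", 2), strrep("E", 3), strrep("K", 1),
                strrep("H", 1), strrep("R", 1), strrep("G", 92))
  cf <- charged_fractions(aa_composition(seq))
  expect_equal(unname(cf["acidic"]), 5)
  expect_equal(unname(cf["basic"]), 3)
  expect_equal(unname(cf["charged"]), 8)

  cf0 <- charged_fractions(aa_composition(strrep("G", 50)))
  expect_equal(unname(cf0), c(0, 0, 0))
})

test_that("alternative pKa sets change the pI as their constants dictate", {
  s <- "EEKKHDDRY"
  pis <- vapply(c("emboss", "bjellqvist", "ipc_protein"), function(nm) {
    isoelectric_point(s, pka = nm)
  }, numeric(1))
  expect_true(length(unique(round(pis, 2))) > 1)
  for (nm in names(pis)) {
    expect_equal(pis[[nm]],
                 oracle_grid_pi(s, pka = pka_set(nm)$pka),
                 tolerance = 2e-3)
  }
})

test_that("custom pKa sets are validated", {
  expect_error(pka_set("nosuch"), "unknown pKa set")
  expect_error(make_pka_set("bad", c(Nterm = 8.6)), "nine groups")
  bad <- EMBOSS_PKA; bad[["K"]] <- 15
  expect_error(make_pka_set("bad", bad), "in \\(0, 14\\)")
})
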