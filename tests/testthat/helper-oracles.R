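# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (per-residue loops, grid search, exhaustive
# enumeration, textbook DP) so that they share no code path with the package
# implementation they check.

EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
                Y = 10.1, H = 6.5, K = 10.8, R = 12.5)

# per-residue Henderson-Hasselbalch sum, written as an explicit loop
oracle_charge <- function(sequence, pH, pka = EMBOSS_PKA) {
  chars <- strsplit(sequence, "")[[1]]
  q <- 1 / (1 + 10^(pH - pka[["Nterm"]])) - 1 / (1 + 10^(pka[["Cterm"]] - pH))
  for (ch in chars) {
    if (ch %in% c("H", "K", "R")) {
      q <- q + 1 / (1 + 10^(pH - pka[[ch]]))
    } else if (ch %in% c("D", "E", "C", "Y")) {
      q <- q - 1 / (1 + 10^(pka[[ch]] - pH))
    }
  }
  q
}

# grid-search pI: argmin |charge| over pH = 0, step, ..., 14
oracle_grid_pi <- function(sequence, step = 0.001, pka = EMBOSS_PKA) {
  grid <- seq(0, 14, by = step)
  chars <- strsplit(sequence, "")[[1]]
  n_pos <- c(H = 0, K = 0, R = 0)
  n_neg <- c(D = 0, E = 0, C = 0, Y = 0)
  tab <- table(chars)
  for (g in names(n_pos)) if (g %in% names(tab)) n_pos[g] <- tab[[g]]
  for (g in names(n_neg)) if (g %in% names(tab)) n_neg[g] <- tab[[g]]
  q <- 1 / (1 + 10^(grid - pka[["Nterm"]])) - 1 / (1 + 10^(pka[["Cterm"]] - grid))
  for (g in names(n_pos)) q <- q + n_pos[g] / (1 + 10^(grid - pka[[g]]))
  for (g in names(n_neg)) q <- q - n_neg[g] / (1 + 10^(pka[[g]] - grid))
  grid[which.min(abs(q))]
}

# vectorized grid pI for many sequences at once (counts %*% charge table)
oracle_grid_pi_batch <- function(sequences, step = 0.001, pka = EMBOSS_PKA) {
  grid <- seq(0, 14, by = step)
  groups <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  signs <- c(Nterm = 1, Cterm = -1, D = -1, E = -1, C = -1, Y = -1,
             H = 1, K = 1, R = 1)
  fr <- sapply(groups, function(g) {
    if (signs[[g]] > 0) 1 / (1 + 10^(grid - pka[[g]]))
    else -1 / (1 + 10^(pka[[g]] - grid))
  })
  counts <- t(vapply(sequences, function(s) {
    tab <- table(strsplit(s, "")[[1]])
    cnt <- c(Nterm = 1, Cterm = 1, D = 0, E = 0, C = 0, Y = 0, H = 0,
             K = 0, R = 0)
    for (g in intersect(names(tab), groups)) cnt[g] <- cnt[g] + tab[[g]]
    cnt
  }, numeric(9)))
  q <- counts %*% t(fr)
  grid[apply(abs(q), 1, which.min)]
}

random_protein <- function(len, letters = c("A", "C", "D", "E", "F", "G", "H",
                                            "I", "K", "L", "M", "N", "P", "Q",
                                            "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# one-way PERMANOVA pseudo-F computed directly from the definition
oracle_permanova_f <- function(d, groups) {
  d2 <- d^2
  N <- nrow(d2)
  a <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / N
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ((sst - ssw) / (a - 1)) / (ssw / (N - a))
}

# exact permutation p-value for two equal groups by exhaustive enumeration of
# all distinct label assignments (choose(N, n1)); includes the observed one
oracle_exact_p <- function(d, groups) {
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  N <- nrow(d)
  idx1 <- utils::combn(N, sum(groups == lev[1]))
  f_obs <- oracle_permanova_f(d, groups)
  fs <- apply(idx1, 2, function(members) {
    g <- rep(lev[2], N)
    g[members] <- lev[1]
    oracle_permanova_f(d, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# quadratic-space affine-gap Smith-Waterman score (Gotoh), gap open `open`
# plus `ext` per gapped residue (a length-L gap costs open + L * ext)
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[x[i - 1], y[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# small FASTA writer used by round-trip tests (independent of the package)
write_fasta_lines <- function(ids, seqs, path, wrap = NULL) {
  lines <- unlist(Map(function(id, s) {
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", id), body)
  }, ids, seqs))
  writeLines(lines, path)
  path
}
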