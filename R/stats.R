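#' Bray-Curtis dissimilarity between two frequency vectors
#'
#' \eqn{BC(p, q) = \sum_i |p_i - q_i| / \sum_i (p_i + q_i)}, the standard
#' abundance-based dissimilarity; on relative-frequency vectors that each sum
#' to 1 it reduces to half the L1 distance. Defined as 0 when both vectors
#' are all-zero.
#'
#' @param p,q non-negative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\] for non-negative inputs.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stopf("`p` and `q` must have equal length")
  if (any(p < 0) || any(q < 0)) stopf("frequency vectors must be non-negative")
  denom <- sum(p + q)
  if (denom == 0) return(0)
  sum(abs(p - q)) / denom
}

#' Bray-Curtis distance matrix over a set of profiles
#'
#' @param profiles numeric matrix, one row per proteome (rows named with
#'   proteome ids), or a list of \code{pi_spectrum} objects.
#' @return a symmetric base matrix of dissimilarities with proteome ids as
#'   dimnames (pass through \code{as.dist()} for dist-based tooling).
#' @export
bray_curtis_matrix <- function(profiles) {
  profiles <- as_profile_matrix(profiles)
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(profiles[i, ], profiles[j, ])
    }
  }
  d
}

as_profile_matrix <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) && !is.matrix(profiles)) {
    labels <- vapply(profiles, function(s) s$label, character(1))
    profiles <- do.call(rbind, lapply(profiles, function(s) s$rel_freq))
    rownames(profiles) <- labels
  }
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("p", seq_len(nrow(profiles)))
  }
  profiles
}

# pseudo-F and R^2 for a squared-distance matrix and a grouping, following
# the one-way PERMANOVA decomposition:
#   SST = (1/N) sum_{i<j} d_ij^2,  SSW = sum_g (1/n_g) sum_{i<j in g} d_ij^2
.permanova_f <- function(d2, groups) {
  N <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  sst <- sum(d2[upper.tri(d2)]) / N
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssa <- sst - ssw
  f <- if (ssw <= .Machine$double.eps * sst) {
    Inf
  } else {
    (ssa / (a - 1)) / (ssw / (N - a))
  }
  list(F = f, r2 = if (sst > 0) ssa / sst else 0, ssa = ssa, ssw = ssw,
       sst = sst)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (one-way, single factor):
#' partitions the total sum of squared interpoint distances into among- and
#' within-group components, forms the pseudo-F statistic
#' \eqn{F = (SSA/(a-1)) / (SSW/(N-a))} and \eqn{R^2 = SSA/SST}, and obtains
#' the p-value by permuting group labels over objects. The p-value uses the
#' \eqn{(1+b)/(1+m)} estimator (observed configuration counted once), so it
#' is never exactly 0 and has resolution \eqn{1/(m+1)}.
#'
#' @param d symmetric distance matrix (base matrix or \code{dist}).
#' @param groups vector of group labels, one per object; at least two
#'   groups, none equal to the whole set.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream; results are
#'   reproducible bit-exact given (\code{n_permutations}, \code{seed}).
#' @return object of class \code{permanova_result}: list with
#'   \code{pseudo_F}, \code{r_squared}, \code{p_value}, \code{n_permutations},
#'   \code{seed}, \code{ss} (the three sums of squares).
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stopf("`d` must be a symmetric distance matrix")
  N <- nrow(d)
  if (length(groups) != N) stopf("`groups` must have one label per object")
  if (N < 3) stopf("PERMANOVA needs at least 3 objects")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least two groups")
  if (any(tab == N)) stopf("a group equal to the whole set is not testable")
  d2 <- d^2
  obs <- .permanova_f(d2, groups)
  b <- 0L
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      fp <- .permanova_f(d2, groups[sample.int(N)])$F
      if (fp >= obs$F - 1e-12) b <- b + 1L
    }
  })
  structure(list(pseudo_F = obs$F, r_squared = obs$r2,
                 p_value = (1 + b) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 ss = c(among = obs$ssa, within = obs$ssw, total = obs$sst)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Principal component analysis of pI profiles
#'
#' Column-centers the profile matrix and eigendecomposes its covariance
#' (via singular value decomposition). Components are ordered by decreasing
#' explained variance, and each component's sign is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' eigen-solvers.
#'
#' @param profiles numeric matrix (one row per proteome) or list of
#'   \code{pi_spectrum} objects.
#' @param n_components number of components to return (default 2); truncated
#'   to the matrix rank with a warning when larger.
#' @return list with \code{scores} (n x k), \code{loadings} (p x k),
#'   \code{explained_variance_ratio} (length k).
#' @export
pca_profiles <- function(profiles, n_components = 2) {
  m <- as_profile_matrix(profiles)
  if (nrow(m) < 2) stopf("PCA needs at least two profiles")
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  rank <- sum(pos)
  k <- n_components
  if (k > rank) {
    warning(sprintf("n_components truncated from %d to rank %d", k, rank),
            call. = FALSE)
    k <- rank
  }
  ev <- sv$d^2 / (nrow(m) - 1)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       loadings = loadings[, seq_len(k), drop = FALSE],
       explained_variance_ratio = (ev / sum(ev))[seq_len(k)])
}

#' Nearest-centroid habitat classification from spectrum aggregates
#'
#' Formalizes the rule of thumb that a proteome's acid/neutral/basic pI
#' balance identifies its habitat of origin: each habitat's reference
#' exemplars are averaged into a centroid in (acid, neutral, basic)-fraction
#' space, and a query profile is assigned to the nearest centroid under
#' Euclidean distance. Ties break to the lexicographically smaller label.
#'
#' @param profile a \code{pi_spectrum}, or a numeric length-3 vector of
#'   (acid, neutral, basic) fractions.
#' @param references data frame with columns \code{label},
#'   \code{acid_fraction}, \code{neutral_fraction}, \code{basic_fraction}
#'   (one row per reference exemplar; at least one per label).
#' @return list with \code{label} (winning habitat) and \code{margin}
#'   (distance to runner-up centroid minus distance to winner; 0 on a tie).
#' @export
classify_habitat <- function(profile, references) {
  if (inherits(profile, "pi_spectrum")) profile <- acid_neutral_basic(profile)
  profile <- as.numeric(profile)
  if (length(profile) != 3) stopf("`profile` must give 3 aggregate fractions")
  need <- c("label", "acid_fraction", "neutral_fraction", "basic_fraction")
  if (!is.data.frame(references) || !all(need %in% names(references)) ||
      nrow(references) == 0) {
    stopf("`references` must be a non-empty data frame with columns %s",
          paste(need, collapse = ", "))
  }
  feats <- as.matrix(references[, need[-1]])
  labs <- as.character(references$label)
  cent <- do.call(rbind, lapply(sort(unique(labs)), function(l) {
    colMeans(feats[labs == l, , drop = FALSE])
  }))
  rownames(cent) <- sort(unique(labs))
  if (nrow(cent) < 2) {
    return(list(label = rownames(cent)[1], margin = Inf))
  }
  dists <- sqrt(rowSums(sweep(cent, 2, profile)^2))
  ord <- order(dists, rownames(cent))    # lexicographic tie-break
  list(label = rownames(cent)[ord[1]],
       margin = unname(dists[ord[2]] - dists[ord[1]]))
}
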