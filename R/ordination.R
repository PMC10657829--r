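#' Bray-Curtis dissimilarity between prescription profiles
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)`; on presence/absence
#' profiles this reduces to `1 - 2 * shared / (n_i + n_j)` (one minus the
#' Sorensen similarity).
#'
#' @param profiles prescription-by-herb matrix (binary or dose-weighted),
#'   e.g. from [incidence_matrix()].
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(profiles) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 2)
  zero <- rowSums(abs(profiles)) == 0
  if (any(zero))
    stop("all-zero profile row(s): ",
         paste(rownames(profiles)[zero] %||% which(zero), collapse = ", "))
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    xi <- profiles[i, ]
    for (j in (i + 1):n) {
      xj <- profiles[j, ]
      d[i, j] <- d[j, i] <- sum(abs(xi - xj)) / sum(xi + xj)
    }
  }
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Gower double-centering of `-d^2 / 2`, eigendecomposition, coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues — possible for non-Euclidean dissimilarities such as
#' Bray-Curtis — are reported but excluded from the variance-explained
#' denominator; no Cailliez/Lingoes correction is applied.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of axes to retain (truncated with a warning if it exceeds
#'   the number of positive eigenvalues).
#' @return list: `coordinates` (n x k), `variance_explained` (percent per
#'   retained axis), `eigenvalues` (full spectrum, decreasing).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), max(abs(d - t(d))) < 1e-12, all(abs(diag(d)) < 1e-12))
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 1) * 1e-12 & ev > 0)
  if (k > length(pos)) {
    warning("k exceeds number of positive eigenvalues; truncating to ", length(pos))
    k <- length(pos)
  }
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       variance_explained = 100 * ev[pos[seq_len(k)]] / sum(ev[pos]),
       eigenvalues = ev)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Pseudo-F from the partition of the squared-dissimilarity sums:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `F = (SS_between / (g - 1)) / (SS_within / (n - g))`.
#' The p-value permutes group labels with the +1 correction,
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor-like group labels, one per row of `d`.
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list: `pseudo_F`, `p_value`, `n_permutations`, `seed`, `ss`
#'   (between/within/total sums of squares).
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("group(s) of size 1: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  d2 <- d^2
  ss_for <- function(g) {
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_w
  }
  ss_total <- sum(d2) / (2 * n)
  g <- length(tab)
  f_stat <- function(grp) {
    ss_w <- ss_for(grp)
    ((ss_total - ss_w) / (g - 1)) / (ss_w / (n - g))
  }
  f_obs <- f_stat(groups)
  perm_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      f_stat(sample(groups)) >= f_obs
    }, logical(1)))
  })
  ss_w <- ss_for(groups)
  list(pseudo_F = f_obs,
       p_value = (1 + perm_ge) / (1 + n_permutations),
       n_permutations = n_permutations, seed = seed,
       ss = c(between = ss_total - ss_w, within = ss_w, total = ss_total))
}

#' Two-class PLS-DA by NIPALS deflation
#'
#' Partial least squares of the column-centered profile matrix against a
#' centered +/-1 class vector; each component's captured percent of total
#' predictor variance is the Frobenius mass of its rank-one reconstruction.
#' Scores of successive components are mutually orthogonal, and over a
#' full-rank decomposition the captured percents sum to 100.
#'
#' @param profiles prescription-by-herb matrix.
#' @param labels two-class label vector.
#' @param n_components number of latent components.
#' @return list: `scores` (n x k), `loadings` (p x k), `weights`,
#'   `percent_variation` (percent of X variance per component), `classes`.
#' @export
plsda <- function(profiles, labels, n_components = 2) {
  X <- scale(as.matrix(profiles), center = TRUE, scale = FALSE)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("plsda requires exactly two classes")
  y <- ifelse(as.character(labels) == classes[2], 1, -1)
  y <- y - mean(y)
  total_var <- sum(X^2)
  n <- nrow(X); p <- ncol(X)
  k <- min(n_components, n - 1, p)
  scores <- matrix(0, n, k)
  loadings <- matrix(0, p, k, dimnames = list(colnames(profiles), NULL))
  weights <- matrix(0, p, k, dimnames = list(colnames(profiles), NULL))
  pct <- numeric(k)
  for (a in seq_len(k)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k <- a - 1L; break }
    w <- w / nw
    t_a <- X %*% w
    p_a <- crossprod(X, t_a) / sum(t_a^2)
    scores[, a] <- t_a
    loadings[, a] <- p_a
    weights[, a] <- w
    pct[a] <- 100 * sum(t_a^2) * sum(p_a^2) / total_var
    X <- X - tcrossprod(t_a, p_a)
  }
  list(scores = scores[, seq_len(k), drop = FALSE],
       loadings = loadings[, seq_len(k), drop = FALSE],
       weights = weights[, seq_len(k), drop = FALSE],
       percent_variation = pct[seq_len(k)],
       classes = classes)
}
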