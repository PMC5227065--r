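# Penetration-level statistics.  Every test here consumes one value (or
# one compartment triplet, or one difference map) per penetration - never
# raw channels - so pseudo-replication across the correlated channels of a
# probe is excluded by construction.

#' Paired signed-rank test across penetrations
#'
#' Wilcoxon signed-rank test on paired per-penetration values (exact for
#' small samples without ties, normal approximation otherwise), with an
#' optional Bonferroni factor for multiple comparisons.
#'
#' @param a,b Paired numeric vectors, one value per penetration.
#' @param alternative Test sidedness (default two-sided).
#' @param n_comparisons Bonferroni factor (default 1 = no correction).
#' @return List: statistic, p.value (corrected), p.uncorrected, n, method.
#' @export
paired_test <- function(a, b, alternative = "two.sided", n_comparisons = 1) {
  stopifnot(length(a) == length(b))
  if (length(a) < 5) stop("need at least 5 penetration pairs")
  if (all(a - b == 0)) stop("all paired differences are zero")
  ht <- wilcox.test(a, b, paired = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic),
       p.value = min(1, ht$p.value * n_comparisons),
       p.uncorrected = ht$p.value,
       n = length(a), n_comparisons = n_comparisons,
       method = "Wilcoxon signed-rank test (paired)")
}

#' Rank-sum test between independent groups (cross-task comparisons)
#'
#' @param a,b Numeric vectors from two independent sets of penetrations.
#' @inheritParams paired_test
#' @return As [paired_test()].
#' @export
ranksum_test <- function(a, b, alternative = "two.sided", n_comparisons = 1) {
  ht <- wilcox.test(a, b, paired = FALSE, alternative = alternative)
  list(statistic = unname(ht$statistic),
       p.value = min(1, ht$p.value * n_comparisons),
       p.uncorrected = ht$p.value,
       n = c(length(a), length(b)), n_comparisons = n_comparisons,
       method = "Wilcoxon rank-sum test")
}

#' One-way repeated-measures ANOVA over laminar compartments
#'
#' Repeated-measures ANOVA with the three laminar compartments (deep,
#' layer 4, superficial) as within-penetration levels.  The
#' Greenhouse-Geisser epsilon is estimated from the sample covariance of
#' the compartment scores and applied to the degrees of freedom whenever
#' it is below 1.  Post-hoc pairwise signed-rank tests
#' (Bonferroni-corrected) are attached.
#'
#' @param x Numeric matrix, penetrations x compartments, with column
#'   names; default column order `deep`, `layer4`, `superficial`.
#' @param posthoc Run pairwise signed-rank tests (default TRUE).
#' @return `lam_anova`: F, df, epsilon, p (sphericity-corrected),
#'   p.uncorrected, posthoc table.
#' @export
compartment_anova <- function(x, posthoc = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 penetrations")
  if (k < 2) stop("need at least 2 compartments")
  if (anyNA(x)) stop("compartment matrix must be complete")
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(k))
  grand <- mean(x)
  comp_m <- colMeans(x)
  subj_m <- rowMeans(x)
  ss_comp <- n * sum((comp_m - grand)^2)
  ss_subj <- k * sum((subj_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_comp - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- (ss_comp / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon via orthonormalized contrasts of the
  # sample covariance of the repeated measures
  S <- stats::cov(x)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  eps <- min(eps, 1)
  p_unc <- pf(Fval, df1, df2, lower.tail = FALSE)
  p <- if (eps < 1) pf(Fval, eps * df1, eps * df2, lower.tail = FALSE) else p_unc
  ph <- NULL
  if (posthoc && k >= 2) {
    prs <- combn(k, 2)
    ph <- data.frame(
      a = colnames(x)[prs[1, ]], b = colnames(x)[prs[2, ]],
      p.value = apply(prs, 2, function(ij)
        min(1, wilcox.test(x[, ij[1]], x[, ij[2]], paired = TRUE)$p.value *
              ncol(prs))),
      stringsAsFactors = FALSE)
  }
  structure(list(F = Fval, df = c(df1, df2), epsilon = eps,
                 df_corrected = eps * c(df1, df2),
                 p.value = p, p.uncorrected = p_unc, n = n,
                 posthoc = ph),
            class = "lam_anova")
}

#' @export
print.lam_anova <- function(x, ...) {
  cat(sprintf("<lam_anova> F(%.2f, %.2f) = %.3f, p = %.4g (GG epsilon = %.3f, n = %d)\n",
              x$df_corrected[1], x$df_corrected[2], x$F, x$p.value,
              x$epsilon, x$n))
  invisible(x)
}

#' Consistency of laminar profiles across penetrations
#'
#' Pearson correlations between laminar profiles.  Within a task, all
#' N(N-1)/2 penetration pairs are evaluated; between tasks, the same
#' penetration is compared across tasks (N matched pairs).  Significance
#' of the mean correlation is a signed-rank test of the pairwise r values
#' against zero.  The shuffle control randomly permutes the channels of
#' one member of each pair, destroying the laminar structure while
#' preserving the value distribution.
#'
#' @param profiles Channel x N matrix (or list of per-channel vectors) of
#'   laminar profiles, one column per penetration.
#' @param profiles_b Optional second matrix for the between-task mode
#'   (matched columns).
#' @param shuffle Apply the channel-shuffle control (default FALSE).
#' @param n_shuffle Number of shuffle replicates per pair (default 1).
#' @param seed RNG seed for the shuffles.
#' @return List: `r` (pairwise correlations), `mean_r`, `p` (signed-rank
#'   vs 0), `n_pairs`, `mode`.
#' @export
profile_consistency <- function(profiles, profiles_b = NULL, shuffle = FALSE,
                                n_shuffle = 1L, seed = NULL) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(cbind, profiles)
  profiles <- as.matrix(profiles)
  if (!is.null(seed)) set.seed(seed)
  maybe_shuffle <- function(v, do) if (do) v[sample(length(v))] else v
  rs <- numeric(0)
  if (is.null(profiles_b)) {
    N <- ncol(profiles)
    if (N < 2) stop("need at least 2 profiles for the within-task mode")
    prs <- combn(N, 2)
    reps <- if (shuffle) n_shuffle else 1L
    for (r in seq_len(reps)) {
      for (j in seq_len(ncol(prs))) {
        a <- profiles[, prs[1, j]]
        b <- maybe_shuffle(profiles[, prs[2, j]], shuffle)
        if (sd(a, na.rm = TRUE) == 0 || sd(b, na.rm = TRUE) == 0) {
          warning("constant profile; pair skipped")
          next
        }
        rs <- c(rs, cor(a, b, use = "complete.obs"))
      }
    }
    mode <- "within_task"
    n_pairs <- ncol(prs)
  } else {
    if (is.list(profiles_b) && !is.data.frame(profiles_b))
      profiles_b <- do.call(cbind, profiles_b)
    profiles_b <- as.matrix(profiles_b)
    if (ncol(profiles) != ncol(profiles_b))
      stop("between-task mode needs matched penetrations")
    reps <- if (shuffle) n_shuffle else 1L
    for (r in seq_len(reps)) {
      for (j in seq_len(ncol(profiles))) {
        a <- profiles[, j]
        b <- maybe_shuffle(profiles_b[, j], shuffle)
        if (sd(a, na.rm = TRUE) == 0 || sd(b, na.rm = TRUE) == 0) {
          warning("constant profile; pair skipped")
          next
        }
        rs <- c(rs, cor(a, b, use = "complete.obs"))
      }
    }
    mode <- "between_task"
    n_pairs <- ncol(profiles)
  }
  p <- if (length(rs) >= 5 && any(rs != 0))
    wilcox.test(rs, mu = 0)$p.value else NA_real_
  list(r = rs, mean_r = mean(rs), p = p, n_pairs = n_pairs,
       mode = mode, shuffled = shuffle)
}

# Union-find connected-component labelling of suprathreshold cells on a
# channel x time grid (4-connectivity), restricted to the sparse set of
# suprathreshold indices so permutation nulls stay cheap.
label_components <- function(idx, nr) {
  m <- length(idx)
  if (!m) return(integer(0))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row <- (idx - 1L) %% nr + 1L
  up_j <- match(ifelse(row > 1L, idx - 1L, NA_integer_), idx)
  left_j <- match(idx - nr, idx)
  for (j in seq_len(m)) {
    for (jj in c(up_j[j], left_j[j])) {
      if (!is.na(jj)) {
        ra <- find(j); rb <- find(jj)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  vapply(seq_len(m), find, integer(1))
}

cluster_masses <- function(tmat, threshold) {
  nr <- nrow(tmat)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- which(!is.na(tmat) & sgn * tmat > threshold)
    if (!length(mask)) next
    lab <- label_components(mask, nr)
    for (l in unique(lab)) {
      cells <- mask[lab == l]
      out[[length(out) + 1L]] <- list(sign = sgn, cells = cells,
                                      mass = sum(tmat[cells]))
    }
  }
  out
}

# Vectorised max |cluster mass| over sign-flip permutations.
max_null_masses <- function(X, n, p, nr, threshold, signs) {
  ss <- colSums(X^2)
  vapply(seq_len(ncol(signs)), function(b) {
    m <- as.numeric(crossprod(signs[, b], X)) / n
    v <- (ss - n * m^2) / (n - 1)
    tvec <- m / sqrt(v / n)
    tvec[!is.finite(tvec)] <- 0
    tmat <- matrix(tvec, nr)
    cl <- cluster_masses(tmat, threshold)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }, numeric(1))
}

#' Cluster-based sign-flip permutation test on laminar difference maps
#'
#' Tests the reliability of a laminar (channel x time) modulation pattern
#' across penetrations.  A t-map across penetrations is thresholded
#' (default |t| > 2); contiguous suprathreshold cells of common sign
#' (4-connectivity) form clusters whose mass is the summed t.  The null
#' distribution of the maximum cluster mass is obtained by randomly
#' flipping the sign of whole penetrations, which is exchangeable under
#' the null of no condition difference; cluster p-values are the
#' add-one-smoothed fraction of permutations whose maximum mass reaches
#' the observed mass, controlling the family-wise error over the map.
#'
#' @param maps Per-penetration difference maps: an n x channel x time
#'   array or a list of channel x time matrices (common depth grid).
#' @param threshold Cluster-forming t threshold (default 2).
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @return `lam_clusters`: `clusters` data frame (id, sign, mass,
#'   n_cells, p.value), `t` map, `max_null`, `n_perm`, `seed`.
#' @export
cluster_permutation <- function(maps, threshold = 2, n_perm = 1000L,
                                seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    maps <- array(unlist(lapply(maps, t)), c(dims[2], dims[1], length(maps)))
    maps <- aperm(maps, c(3, 2, 1))   # n x channel x time
  }
  stopifnot(length(dim(maps)) == 3L)
  n <- dim(maps)[1]
  nr <- dim(maps)[2]
  X <- matrix(maps, nrow = n)   # n x (channel*time), channel fastest
  m <- colMeans(X)
  v <- apply(X, 2, var)
  tvec <- m / sqrt(v / n)
  tvec[!is.finite(tvec)] <- 0
  tmat <- matrix(tvec, nr)
  obs <- cluster_masses(tmat, threshold)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  max_null <- max_null_masses(X, n, ncol(X), nr, threshold, signs)
  clusters <- if (length(obs)) {
    data.frame(id = seq_along(obs),
               sign = vapply(obs, `[[`, numeric(1), "sign"),
               mass = vapply(obs, `[[`, numeric(1), "mass"),
               n_cells = vapply(obs, function(o) length(o$cells), integer(1)),
               p.value = vapply(obs, function(o)
                 (1 + sum(max_null >= abs(o$mass))) / (n_perm + 1), numeric(1)))
  } else {
    data.frame(id = integer(0), sign = numeric(0), mass = numeric(0),
               n_cells = integer(0), p.value = numeric(0))
  }
  structure(list(clusters = clusters,
                 cluster_cells = lapply(obs, `[[`, "cells"),
                 t = tmat, threshold = threshold,
                 max_null = max_null, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n = n),
            class = "lam_clusters")
}

#' @export
print.lam_clusters <- function(x, ...) {
  cat(sprintf("<lam_clusters> %d cluster(s), |t| > %g, %d sign-flip permutations (n = %d)\n",
              nrow(x$clusters), x$threshold, x$n_perm, x$n))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
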