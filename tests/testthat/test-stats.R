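# Penetration-level statistics: signed-rank/rank-sum tests, the
# repeated-measures compartment ANOVA with Greenhouse-Geisser correction,
# profile-consistency correlations and the cluster permutation test.

test_that("paired_test handles extreme, degenerate and corrected cases", {
  set.seed(1)
  a <- rnorm(10)
  b <- a + runif(10, 0.5, 1.5)   # all-positive shifts: minimal p at n = 10
  res <- paired_test(b, a)
  expect_lt(res$p.value, 0.01)
  expect_equal(res$p.value, wilcox.test(b, a, paired = TRUE)$p.value)
  expect_error(paired_test(a, a), "zero")
  expect_error(paired_test(a[1:3], a[1:3] + 1), "at least 5")
  res2 <- paired_test(b, a, n_comparisons = 3)
  expect_equal(res2$p.value, min(1, res2$p.uncorrected * 3))
  # unpaired variant for cross-task comparisons
  r3 <- ranksum_test(rnorm(8) + 2, rnorm(9))
  expect_lt(r3$p.value, 0.01)
  expect_match(r3$method, "rank-sum")
})

test_that("compartment_anova matches aov() and corrects sphericity", {
  set.seed(8)
  n <- 12
  x <- cbind(deep = rnorm(n, 0.3), layer4 = rnorm(n, 0.1),
             superficial = rnorm(n, 0.3)) + rnorm(n) # subject effects
  res <- compartment_anova(x)
  # independent route: base aov with an Error(subject) stratum
  df <- data.frame(y = as.vector(x),
                   comp = factor(rep(colnames(x), each = n)),
                   subj = factor(rep(seq_len(n), 3)))
  aov_tab <- summary(aov(y ~ comp + Error(subj / comp), df))
  F_aov <- aov_tab[["Error: subj:comp"]][[1]]["comp", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)
  expect_true(res$epsilon > 0.5 && res$epsilon <= 1)
  expect_equal(res$p.value,
               pf(res$F, res$epsilon * 2, res$epsilon * 2 * (n - 1),
                  lower.tail = FALSE))
  expect_error(compartment_anova(x[1:2, ]), "at least 3")
  expect_equal(nrow(res$posthoc), 3)
})

test_that("compartment_anova detects a strong laminar effect with post-hocs", {
  set.seed(9)
  n <- 24
  x <- cbind(deep = rnorm(n, 0.30, 0.05), layer4 = rnorm(n, 0.10, 0.05),
             superficial = rnorm(n, 0.30, 0.05))
  res <- compartment_anova(x)
  expect_lt(res$p.value, 0.001)
  ph <- res$posthoc
  vs_l4 <- ph[ph$a == "layer4" | ph$b == "layer4", ]
  expect_true(all(vs_l4$p.value < 0.01))
})

test_that("profile_consistency evaluates N(N-1)/2 pairs and flags shuffles", {
  set.seed(10)
  base <- rnorm(24)
  profs <- sapply(1:4, function(i) base + rnorm(24, sd = 0.01))
  res <- profile_consistency(profs)
  expect_equal(res$n_pairs, 6)
  expect_equal(length(res$r), 6)
  expect_true(all(res$r > 0.99))
  # identical profiles: every r exactly 1
  same <- profile_consistency(cbind(base, base, base))
  expect_true(all(same$r == 1))
  # shuffle control on strongly consistent profiles: mean r near 0
  sh <- profile_consistency(profs, shuffle = TRUE, n_shuffle = 150,
                            seed = 2)
  expect_equal(length(sh$r), 6 * 150)
  se <- sd(sh$r) / sqrt(length(sh$r))
  expect_lt(abs(sh$mean_r), 3 * se + 0.02)
  # between-task mode: matched pairs only
  btw <- profile_consistency(profs, profs)
  expect_equal(length(btw$r), 4)
  expect_equal(btw$r, rep(1, 4), tolerance = 1e-12)
  expect_warning(profile_consistency(cbind(rep(1, 24), base)),
                 "constant profile")
})

test_that("cluster_permutation returns no clusters on all-zero maps", {
  maps <- lapply(1:8, function(i) matrix(0, 10, 12))
  res <- cluster_permutation(maps, n_perm = 100, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_error(cluster_permutation(maps, n_perm = 50), "at least 100")
})

test_that("cluster_permutation localizes an injected laminar effect", {
  set.seed(11)
  n <- 12
  maps <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(20 * 15, sd = 0.5), 20, 15)
    m[4:7, 5:10] <- m[4:7, 5:10] - 2      # sink band confined to rows 4-7
    m
  })
  res <- cluster_permutation(maps, n_perm = 199, seed = 3)
  expect_gt(nrow(res$clusters), 0)
  top <- which.max(abs(res$clusters$mass))
  expect_lt(res$clusters$p.value[top], 0.01)
  expect_equal(res$clusters$sign[top], -1)
  rows <- (res$cluster_cells[[top]] - 1) %% 20 + 1
  expect_true(all(rows >= 3 & rows <= 8))
  # seed-determinism
  res2 <- cluster_permutation(maps, n_perm = 199, seed = 3)
  expect_identical(res$clusters, res2$clusters)
  expect_identical(res$max_null, res2$max_null)
})

test_that("cluster p-values live in (0, 1] and clusters are disjoint", {
  set.seed(12)
  maps <- lapply(1:9, function(i) matrix(rnorm(8 * 10), 8, 10))
  res <- cluster_permutation(maps, n_perm = 120, seed = 5)
  if (nrow(res$clusters)) {
    expect_true(all(res$clusters$p.value > 0 & res$clusters$p.value <= 1))
    all_cells <- unlist(res$cluster_cells)
    expect_equal(length(all_cells), length(unique(all_cells)))
  }
  succeed()
})
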