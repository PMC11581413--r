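# worked six-node pair used throughout: {12|34|56} vs {123|456}
p_a <- part(c(1, 1, 2, 2, 3, 3))
p_b <- part(c(1, 1, 1, 2, 2, 2))

test_that("contingency tables count shared nodes", {
  p1 <- part(c(1, 1, 1, 2, 2))
  expect_equal(contingency_table(p1, p1), diag(c(3, 2)))

  all_one <- part(rep(1, 5))
  expect_equal(contingency_table(all_one, p1), matrix(c(3, 2), 1, 2))

  expect_equal(contingency_table(p_a, p_b),
               matrix(c(2, 1, 0, 0, 1, 2), 3, 2))

  expect_error(contingency_table(p1, part(rep(1, 4))), "same node set")
})

test_that("two-way harmonic purity matches hand computation", {
  expect_equal(purity_harmonic(p_a, p_a), 1)
  # u = (2+1+2)/6, v = (2+2)/6, harmonic mean = 40/54
  expect_equal(purity_harmonic(p_a, p_b), 40 / 54)
  expect_equal(purity_harmonic(p_b, p_a), 40 / 54)

  # singletons are trivially pure one way: result = 2v/(1+v)
  singl <- part(1:6)
  v <- purity_harmonic(p_b, p_b)  # = 1, sanity
  expect_equal(v, 1)
  u_other <- sum(apply(contingency_table(p_b, singl), 1, max)) / 6
  expect_equal(purity_harmonic(singl, p_b), 2 * u_other / (1 + u_other))
})

test_that("NMI equals a direct entropy/MI computation", {
  expect_equal(nmi(p_a, p_a), 1)

  # brute-force from the worked table [[2,0],[1,1],[0,2]]
  tab <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2) / 6
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  I <- 0
  for (i in 1:3) for (j in 1:2)
    if (tab[i, j] > 0)
      I <- I + tab[i, j] * log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
  expect_equal(nmi(p_a, p_b), I / ((H(rowSums(tab)) + H(colSums(tab))) / 2))

  # degenerate conventions
  expect_equal(nmi(part(rep(1, 4)), part(rep(2, 4))), 1)
  expect_equal(nmi(part(rep(1, 4)), part(c(1, 1, 2, 2))), 0)
})

test_that("NMI of independent labelings is near zero for large N", {
  set.seed(1)
  vals <- replicate(20, {
    nmi(part(sample.int(4, 1000, replace = TRUE)),
        part(sample.int(4, 1000, replace = TRUE)))
  })
  expect_lt(mean(vals), 0.01)
})

test_that("mutual information is bounded by the smaller entropy", {
  set.seed(2)
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  for (i in 1:50) {
    p1 <- random_partition(30)
    p2 <- random_partition(30)
    tab <- contingency_table(p1, p2) / 30
    I <- nmi(p1, p2) * (H(rowSums(tab)) + H(colSums(tab))) / 2
    expect_gte(I, -1e-12)
    expect_lte(I, min(H(rowSums(tab)), H(colSums(tab))) + 1e-12)
  }
})

test_that("ARI equals the pair-enumeration oracle", {
  expect_equal(ari(p_a, p_a), 1)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    p1 <- random_partition(n)
    p2 <- random_partition(n)
    expect_equal(ari(p1, p2), ari_pair_oracle(p1, p2), tolerance = 1e-12)
  }
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:20) {
    p1 <- random_partition(25)
    p2 <- random_partition(25)
    expect_equal(ari(p1, p2),
                 mclust::adjustedRandIndex(p1$membership, p2$membership),
                 tolerance = 1e-12)
  }
})

test_that("ARI of all-in-one vs all-singletons is zero", {
  expect_equal(ari(part(rep(1, 6)), part(1:6)), 0)
})

test_that("objective distances reduce to p-norms", {
  expect_equal(objective_distance(2.5, 2.5), 0)
  expect_equal(objective_distance(-3.2, -1.2, p = 1), 2)
  expect_equal(objective_distance(c(-1, 2), c(1, -1), p = 2), sqrt(13))
  expect_error(objective_distance(1, 2, p = 0.5), "p must")
})

test_that("distance matrices assemble the scalar metrics", {
  parts <- list(p_a, p_b, part(c(1, 2, 1, 2, 1, 2)))
  for (m in c("purity", "nmi", "ari")) {
    fn <- switch(m, purity = purity_harmonic, nmi = nmi, ari = ari)
    D <- partition_distances(parts, m)
    expect_s3_class(D, "subject_dist")
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(D[i, j], 1 - fn(parts[[i]], parts[[j]]), tolerance = 1e-12)
  }

  same <- partition_distances(list(p_a, p_a, p_a), "nmi")
  expect_true(all(same == 0))

  # intrinsic route and the incompatible-algorithm guard
  lv <- lapply(c(-0.5, 0.2, 0.4), function(v) part(1:3, objective = v,
                                                   algorithm = "louvain"))
  Do <- partition_distances(lv, "objective")
  expect_equal(Do[1, 3], 0.9)
  sg <- part(1:3, objective = -1, algorithm = "spinglass")
  expect_error(partition_distances(c(lv[1:2], list(sg)), "objective"),
               "incompatible")
})

test_that("negative ARI yields distances above one", {
  p1 <- part(c(1, 1, 2, 2))
  p2 <- part(c(1, 2, 1, 2))
  expect_lt(ari(p1, p2), 0)
  D <- partition_distances(list(p1, p2), "ari")
  expect_gt(D[1, 2], 1)
})

test_that("metrics are symmetric, bounded, and relabel-invariant", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    p1 <- random_partition(n)
    p2 <- random_partition(n)
    for (fn in list(purity_harmonic, nmi, ari))
      expect_equal(fn(p1, p2), fn(p2, p1), tolerance = 1e-12)
    expect_true(purity_harmonic(p1, p2) >= 0 && purity_harmonic(p1, p2) <= 1)
    expect_true(nmi(p1, p2) >= 0 && nmi(p1, p2) <= 1 + 1e-12)
    expect_lte(ari(p1, p2), 1)
    # relabel p2's communities arbitrarily
    relab <- sample(100, max(p2$membership))
    p2r <- partition(stats::setNames(relab[p2$membership],
                                     names(p2$membership)))
    for (fn in list(purity_harmonic, nmi, ari))
      expect_equal(fn(p1, p2), fn(p1, p2r), tolerance = 1e-12)
  }
})

test_that("cohorts from two planted structures separate under NMI", {
  set.seed(6)
  des <- sim_design(30, 3, within = c(8, 8), between = c(1, 8),
                    perturb_prob = 0.1)
  coh <- simulate_cohort(6, 6, des, des, shared_master = FALSE)
  parts <- detect_cohort(coh, "louvain")
  D <- partition_distances(parts, "nmi")
  grp <- coh$group
  within_d <- c(D[grp == 1, grp == 1][upper.tri(diag(6))],
                D[grp == 0, grp == 0][upper.tri(diag(6))])
  between_d <- D[grp == 1, grp == 0]
  expect_lt(mean(within_d), mean(between_d))
})
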