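test_that("fingerprints encode genotypes with IUPAC het codes and '-' for missing", {
  g <- rbind(
    c(0L, 1L, NA),
    c(2L, 2L, 0L)
  )
  gm <- toy_gm(g, chrom = "chr01", ref = "A", alt = "C")
  fp <- fingerprint_strings(gm)
  expect_equal(unname(fp), c("AM-", "CCA"))
  expect_equal(nchar(fp), c(s1 = 3L, s2 = 3L))

  # zero loci -> empty strings
  fp0 <- fingerprint_strings(subset_loci(gm, integer(0)))
  expect_equal(unname(fp0), c("", ""))

  # round trip to codes
  back <- fingerprint_codes(fp, gm$loci)
  expect_equal(unname(back), unname(g))
})

test_that("p-distance matches hand counts and complements similarity", {
  expect_equal(unname(p_distance(c(a = "AC-", b = "AG-"))[1, 2]), 0.5)

  ds <- simulate_dataset(sim_config(n_loci = 500L, seed = 29L))
  d <- p_distance(ds$gm)
  sm <- pairwise_similarity(ds$gm)
  expect_equal(d, 1 - sm$similarity, ignore_attr = TRUE)
  expect_equal(diag(d), rep(0, 40), ignore_attr = TRUE)

  # identical samples at distance zero
  g <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L))
  expect_equal(p_distance(toy_gm(g))[1, 2], 0, ignore_attr = TRUE)
})

test_that("NJ recovers topology and branch lengths exactly from additive distances", {
  set.seed(30)
  for (n_tips in 5:8) {
    ref <- ape::rtree(n_tips, rooted = FALSE)
    ref$edge.length <- runif(length(ref$edge.length), 0.05, 1)
    d <- cophenetic(ref)
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(ref), got), 0, ignore_attr = TRUE)
    expect_equal(
      cophenetic(got)[rownames(d), colnames(d)], d,
      tolerance = 1e-8
    )
  }
})

test_that("three taxa resolve to the forced star with exact lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")], d)
})

test_that("negative NJ branch estimates are clamped without breaking totals", {
  # a non-additive matrix known to force a negative internal estimate
  d <- matrix(c(
    0, 1, 6, 6,
    1, 0, 6, 6,
    6, 6, 0, 1,
    6, 6, 1, 0
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 3] <- d[3, 1] <- 2 # distort additivity
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ on the simulated panel groups cultivars into monophyletic clades", {
  ds <- structure_fixture()
  tr <- nj_tree(p_distance(ds$gm))
  expect_true(all(clades_monophyletic(tr, ds$varieties)))
})

test_that("bootstrap supports are deterministic and strong for well-separated cultivars", {
  ds <- structure_fixture(n_loci = 600L)
  b1 <- bootstrap_support(ds$gm, B = 100L, seed = 7L)
  b2 <- bootstrap_support(ds$gm, B = 100L, seed = 7L)
  expect_identical(b1$support, b2$support)
  expect_equal(length(b1$support), n_samples(ds$gm) - 2L)

  # cultivar clades carry high support (the clade straddling the
  # unrooted-representation root has no own edge and reports NA)
  v <- ds$varieties
  sups <- vapply(unique(v$variety), function(cult) {
    tips <- v$sample[v$variety == cult]
    node <- ape::getMRCA(b1$tree, tips)
    b1$support[node - n_samples(ds$gm)]
  }, numeric(1))
  expect_true(all(is.na(sups) | sups >= 0.95))
  expect_gte(sum(!is.na(sups)), 3L)

  # B = 0 -> no supports
  expect_equal(length(bootstrap_support(ds$gm, B = 0L)$support), 0L)
})

test_that("PCA separates the four cultivars and satisfies the spectral identity", {
  ds <- structure_fixture()
  pca <- pca_grm(ds$gm)
  expect_true(all(diff(pca$var_frac[pca$var_frac > 0]) <= 1e-12))
  expect_lte(sum(pca$var_frac[pca$var_frac > 0]), 1 + 1e-8)

  # coordinates reproduce the GRM
  coords <- as.matrix(pca$scores[, -1])
  full <- pca_grm(ds$gm, n_comp = n_samples(ds$gm))
  cfull <- as.matrix(full$scores[, -1])
  expect_equal(cfull %*% t(cfull), pca$grm, tolerance = 1e-6,
    ignore_attr = TRUE)

  # cluster separation vs cultivar labels
  sil <- cluster::silhouette(
    as.integer(factor(ds$truth$sample_variety)),
    dist(coords[, 1:3])
  )
  expect_gt(mean(sil[, "sil_width"]), 0.8)

  # identical samples get identical coordinates
  g <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L))
  p2 <- pca_grm(toy_gm(g), n_comp = 2L)
  expect_equal(
    as.numeric(p2$scores[1, -1]), as.numeric(p2$scores[2, -1]),
    tolerance = 1e-6
  )
  expect_error(pca_grm(toy_gm(matrix(0L, 3, 2))), "monomorphic")
})

test_that("admixture at K = 1 reduces to pooled frequencies with closed-form likelihood", {
  ds <- structure_fixture(n_loci = 300L)
  fit <- admixture_em(ds$gm, 1L, seed = 2L, n_restarts = 1L)
  expect_equal(unname(fit$Q[, 1]), rep(1, 40))
  g <- ds$gm$geno
  p_pool <- colMeans(g, na.rm = TRUE) / 2
  p_pool <- pmin(pmax(p_pool, 1e-6), 1 - 1e-6)
  ll <- sum(t(g) * log(p_pool) + (2 - t(g)) * log(1 - p_pool), na.rm = TRUE)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and Q stays on the simplex", {
  ds <- structure_fixture(n_loci = 400L)
  fit <- admixture_em(ds$gm, 4L, seed = 3L, n_restarts = 2L, max_iter = 300L)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 40), tolerance = 1e-12)
  expect_true(all(fit$Q >= 0))
  expect_true(all(fit$F > 0 & fit$F < 1))
})

test_that("admixture at K = 4 recovers the simulated cultivars", {
  ds <- structure_fixture()
  fit <- admixture_em(ds$gm, 4L, seed = 5L, n_restarts = 4L)
  expect_gte(mean(apply(fit$Q, 1L, max)), 0.9)

  assigned <- apply(fit$Q, 1L, which.max)
  truth <- as.integer(factor(ds$truth$sample_variety))
  perms <- perms4()
  agree <- max(vapply(seq_len(nrow(perms)), function(i) {
    mean(perms[i, ][assigned] == truth)
  }, numeric(1)))
  expect_gte(agree, 0.95)
})

test_that("cross-validation selects K = 1 for an unstructured population and is deterministic", {
  ds <- simulate_dataset(
    sim_config(n_varieties = 1L, n_per_variety = 30L, n_loci = 400L, seed = 33L)
  )
  cv <- cv_choose_k(ds$gm, k_range = 1:3, folds = 3L, seed = 6L,
    n_restarts = 2L, max_iter = 300L)
  expect_equal(cv$k_best, 1L)

  cv2 <- cv_choose_k(ds$gm, k_range = 1:3, folds = 3L, seed = 6L,
    n_restarts = 2L, max_iter = 300L)
  expect_identical(cv$cv_mean, cv2$cv_mean)
})

test_that("tripartite consistency: PCA, NJ clades and admixture labels agree on the fixture", {
  ds <- structure_fixture()
  v <- ds$varieties

  tr <- nj_tree(p_distance(ds$gm))
  expect_true(all(clades_monophyletic(tr, v)))

  pca <- pca_grm(ds$gm, n_comp = 3L)
  km <- stats::kmeans(as.matrix(pca$scores[, -1]), centers = 4L, nstart = 10L)
  tab <- table(km$cluster, v$variety)
  expect_equal(sum(apply(tab, 1L, max)), 40L) # pure clusters

  fit <- admixture_em(ds$gm, 4L, seed = 9L, n_restarts = 4L)
  assigned <- apply(fit$Q, 1L, which.max)
  tab2 <- table(assigned, v$variety)
  expect_equal(sum(apply(tab2, 1L, max)), 40L)
})
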