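test_that("separated clouds give a perfect block consensus at k = 2", {
  x <- two_clouds(n_per = 10, sep = 50, seed = 1)
  res <- consensus_cluster(x, k_range = 2:3, n_iterations = 100, seed = 3)
  M <- res$M[["2"]]
  within <- c(M[1:10, 1:10][upper.tri(M[1:10, 1:10])],
              M[11:20, 11:20][upper.tri(M[11:20, 11:20])])
  between <- M[1:10, 11:20]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
})

test_that("subsample_frac = 1 makes every consensus entry 0 or 1", {
  x <- two_clouds(n_per = 8, sep = 10, seed = 2)
  res <- consensus_cluster(x, k_range = 2:4, n_iterations = 5,
                           subsample_frac = 1, seed = 1)
  for (M in res$M) expect_true(all(M %in% c(0, 1)))
})

test_that("consensus clustering validates its resampling parameters", {
  x <- two_clouds(n_per = 5, seed = 3)
  expect_error(consensus_cluster(x, k_range = 1:3), "k_range")
  expect_error(consensus_cluster(x, k_range = 2:3, subsample_frac = 0), "subsample_frac")
  expect_error(consensus_cluster(x, k_range = 2:9, subsample_frac = 0.8),
               "below the subsample size")
})

test_that("the AUC-CDF rule selects k where the curve stops rising", {
  auc <- c(`2` = 0.60, `3` = 0.80, `4` = 0.90, `5` = 0.901, `6` = 0.902)
  expect_equal(select_k(auc), 4)
  flat <- c(`2` = 0.7, `3` = 0.7, `4` = 0.7)
  expect_equal(select_k(flat), 2)
  rising <- c(`2` = 0.2, `3` = 0.4, `4` = 0.8)
  expect_warning(k <- select_k(rising), "max")
  expect_equal(k, 4)
  expect_error(select_k(c(`2` = 0.5)), "at least two")
})

test_that("select_k recovers the planted k on noise-free data", {
  # the <1% threshold compares AUC changes against all compound pairs, so the
  # library must be large enough that splitting one drug off a planted
  # cluster moves the AUC by less than 1%: 150 drugs suffices for k* <= 10
  for (k_star in c(3, 5, 10)) {
    lib <- simulate_bam_library(
      scenario_config(n_train_drugs = 150, n_test_drugs = 1,
                      n_clusters = k_star, grid_h = 20, grid_w = 16,
                      within_cluster_sd = 0, replicate_sd = 0, seed = k_star))
    ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
    ts <- tscore_library(lib, "training")
    model <- fit_pca(ts[ids], n_components = 20)
    pp <- project_library(ts[ids], model)
    res <- consensus_cluster(pp, k_range = 2:12, n_iterations = 5,
                             subsample_frac = 1, seed = 1)
    expect_equal(select_k(res), k_star)
  }
})

test_that("cut_clusters recovers block structure and singleton patterns", {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 1
  M[4:6, 4:6] <- 1
  diag(M) <- 1
  res <- fake_consensus(M, 2)
  asg <- cut_clusters(res, 2)
  expect_equal(unname(asg$labels[1:3]), rep(asg$labels[[1]], 3))
  expect_equal(unname(asg$labels[4:6]), rep(asg$labels[[4]], 3))
  expect_false(asg$labels[[1]] == asg$labels[[4]])

  # representative pattern of a singleton cluster is that drug's map
  M2 <- diag(3)
  M2[1:2, 1:2] <- 1
  res2 <- fake_consensus(M2, 2)
  maps <- list(matrix(1, 2, 2), matrix(2, 2, 2), matrix(9, 2, 2))
  names(maps) <- rownames(res2$M[["2"]])
  asg2 <- cut_clusters(res2, 2, tscore_bams = maps)
  singleton <- asg2$labels[[3]]
  expect_equal(asg2$patterns[[singleton]], maps[[3]])
  expect_error(cut_clusters(res2, 5), "no consensus matrix")
})

test_that("coherence test flags perfectly separated consensus scores", {
  # one drug: 17 in-cluster scores of 1 vs 161 out-of-cluster scores of 0
  n <- 179
  labels <- c(rep(1L, 18), rep(2L, n - 18))
  names(labels) <- sprintf("d%03d", seq_len(n))
  M <- matrix(0, n, n, dimnames = list(names(labels), names(labels)))
  M[1:18, 1:18] <- 1
  M[19:n, 19:n] <- 1
  diag(M) <- 1
  asg <- structure(list(labels = labels, k = 2L), class = "cluster_assignment")
  out <- coherence_tests(fake_consensus(M, 2), asg)
  expect_lt(max(out$q_consensus), 1e-5)
})

test_that("coherence tests hold their size under random labels", {
  # unstructured cloud + random labels: rejection rate should match the
  # attainable size of the normal-approximation rank-sum rule
  n <- 40; k <- 4
  n1 <- n / k - 1; n2 <- n - n / k
  # attainable size: enumerate the exact null of the rank-sum statistic
  w <- 0:(n1 * n2)
  p_w <- pnorm((w - n1 * n2 / 2 - 0.5) / sqrt(n1 * n2 * (n + 1) / 12),
               lower.tail = FALSE)
  alpha_attain <- sum(dwilcox(w, n1, n2)[p_w < 0.05])
  fracs <- vapply(1:200, function(s) {
    set.seed(s)
    pp <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(sprintf("d%02d", 1:n), NULL))
    labels <- setNames(sample(rep(1:k, n / k)), rownames(pp))
    asg <- structure(list(labels = labels, k = k), class = "cluster_assignment")
    sim <- -as.matrix(dist(pp))  # higher = more similar; null under label shuffle
    out <- coherence_tests(sim, asg, phenoprints = pp)
    mean(out$p_consensus < 0.05)
  }, 0)
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - alpha_attain), 3 * se)
})

test_that("consensus matrices are permutation-equivariant", {
  x <- two_clouds(n_per = 6, sep = 8, seed = 5)
  res <- consensus_cluster(x, k_range = 2:3, n_iterations = 3,
                           subsample_frac = 1, seed = 1)
  perm <- sample(nrow(x))
  res_p <- consensus_cluster(x[perm, ], k_range = 2:3, n_iterations = 3,
                             subsample_frac = 1, seed = 1)
  expect_equal(res_p$M[["2"]], res$M[["2"]][perm, perm])
})

test_that("the planted partition is recovered exactly without noise", {
  lib <- simulate_bam_library(small_config(seed = 6, within_cluster_sd = 0,
                                           replicate_sd = 0))
  ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
  ts <- tscore_library(lib, "training")
  model <- fit_pca(ts[ids], n_components = 10)
  pp <- project_library(ts[ids], model)
  res <- consensus_cluster(pp, k_range = 2:8, n_iterations = 50, seed = 2)
  asg <- cut_clusters(res, lib$config$n_clusters)
  ari <- mclust::adjustedRandIndex(asg$labels,
                                   lib$ground_truth$clusters[ids])
  expect_equal(ari, 1)
})

test_that("cluster recovery degrades monotonically with replicate noise", {
  sds <- c(0, 2, 4, 8, 16)
  ari <- vapply(sds, function(s) {
    lib <- simulate_bam_library(small_config(seed = 7, replicate_sd = s))
    ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
    ts <- tscore_library(lib, "training")
    pp <- project_library(ts[ids], fit_pca(ts[ids], n_components = 10))
    res <- consensus_cluster(pp, k_range = 2:6, n_iterations = 100, seed = 8)
    asg <- cut_clusters(res, lib$config$n_clusters)
    mclust::adjustedRandIndex(asg$labels, lib$ground_truth$clusters[ids])
  }, 0)
  expect_true(all(diff(ari) <= 0.05))
})
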