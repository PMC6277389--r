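test_that("scenario_config validates its fields", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_clusters = 0), ">= 1")
  expect_error(scenario_config(replicate_sd = -1), ">= 0")
  expect_error(scenario_config(atc_purity = 1.2), "\\[0, 1\\]")
  expect_error(scenario_config(n_train_drugs = 5, n_clusters = 6), "exceed")
})

test_that("cluster templates are distinct, mirror-symmetric and normalized", {
  tpl2 <- make_cluster_templates(2, 60, 40, seed = 1)
  expect_length(tpl2, 2)
  expect_lt(abs(cor(as.vector(tpl2[[1]]), as.vector(tpl2[[2]]))), 0.5)

  tpl1 <- make_cluster_templates(1, 60, 40, seed = 1)
  expect_length(tpl1, 1)

  tpl10 <- make_cluster_templates(10, 60, 40, seed = 7)
  for (i in seq_len(9)) {
    for (j in (i + 1):10) {
      expect_lt(abs(cor(as.vector(tpl10[[i]]), as.vector(tpl10[[j]]))), 0.5)
    }
  }
  for (m in tpl10) {
    expect_equal(m, m[, rev(seq_len(ncol(m)))])  # midline mirror symmetry
    expect_true(all(is.finite(m)))
    affected <- abs(m) > 0.2 * max(abs(m))
    expect_equal(mean(abs(m[affected])), 1, tolerance = 1e-10)
  }

  expect_error(make_cluster_templates(2, 4, 4, seed = 1), "too small")
})

test_that("library has the study's arm sizes and integer BAMs", {
  lib <- simulate_bam_library(scenario_config(seed = 3))
  tab <- lib$drug_table
  expect_equal(sum(tab$set == "training"), 179)
  expect_equal(sum(tab$set == "test"), 121)
  train_ids <- tab$compound_id[tab$set == "training"]
  expect_true(all(lengths(lib$bams[train_ids]) == 5))
  expect_length(lib$bams[["DMSO"]], 50)
  expect_true(all(vapply(lib$bams[[train_ids[1]]],
                         function(b) is.integer(b), TRUE)))
  # training drugs have exactly one planted cluster; test drugs have no ATC
  expect_true(all(train_ids %in% names(lib$ground_truth$clusters)))
  expect_true(all(tab$atc_codes[tab$set == "test"] == ""))
  expect_true(all(nzchar(tab$atc_codes[tab$set == "training"])))
})

test_that("generation is deterministic and seed-driven", {
  a <- simulate_bam_library(small_config(seed = 9))
  b <- simulate_bam_library(small_config(seed = 9))
  c <- simulate_bam_library(small_config(seed = 10))
  expect_identical(a$bams, b$bams)
  expect_identical(a$drug_table, b$drug_table)
  expect_false(identical(a$bams, c$bams))
})

test_that("noise-free limit collapses replicates onto the planted map", {
  lib <- simulate_bam_library(small_config(seed = 2, within_cluster_sd = 0,
                                           replicate_sd = 0))
  ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
  for (id in ids[1:5]) {
    reps <- lib$bams[[id]]
    for (r in reps[-1]) expect_identical(r, reps[[1]])
  }
  # drugs of the same cluster share the identical map
  cl <- lib$ground_truth$clusters[ids]
  same <- ids[cl == cl[1]]
  expect_identical(lib$bams[[same[1]]][[1]], lib$bams[[same[2]]][[1]])
})

test_that("replicate means concentrate on the planted maps (CLT bound)", {
  frac_ok <- vapply(1:3, function(s) {
    lib <- simulate_bam_library(small_config(seed = s))
    ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
    bound <- 3 * lib$config$replicate_sd / sqrt(lib$config$n_replicates)
    ok <- vapply(ids, function(id) {
      m <- Reduce(`+`, lib$bams[[id]]) / length(lib$bams[[id]])
      mean(abs(m - lib$ground_truth$planted_maps[[id]]) <= bound)
    }, 0)
    mean(ok)
  }, 0)
  expect_true(all(frac_ok >= 0.99))
})

test_that("DMSO control arm is signal-free", {
  lib <- simulate_bam_library(scenario_config(seed = 5))
  dmso <- lib$bams[["DMSO"]]
  overall_mean <- mean(vapply(dmso, mean, 0))
  expect_lt(abs(overall_mean), lib$config$replicate_sd / 5)
})

test_that("assign_atc links clusters and categories as configured", {
  lib <- simulate_bam_library(small_config(seed = 4))
  gt <- lib$ground_truth
  # purity 1: every training drug carries its cluster's linked category
  tab1 <- assign_atc(gt, atc_purity = 1, n_atc_categories = 4, seed = 1)
  train <- tab1[tab1$set == "training", ]
  linked <- attr(tab1, "linked_atc")
  expect_true(all(train$atc_codes ==
                    linked[as.character(gt$clusters[train$compound_id])]))
  # purity 1/n_categories: label distribution independent of cluster
  tab0 <- assign_atc(gt, atc_purity = 1 / 4, n_atc_categories = 4, seed = 1)
  train0 <- tab0[tab0$set == "training", ]
  own <- linked[as.character(gt$clusters[train0$compound_id])]
  # each drug's chance of matching its own category is 1/4 by construction
  expect_lt(abs(mean(train0$atc_codes == own) - 0.25), 0.25)
})

test_that("planted ATC links are detectable by the hypergeometric test", {
  # at default purity 0.6, the linked category of each cluster should be
  # flagged at p < 0.05 in at least 95% of seeds (planted labels as clusters)
  lib <- simulate_bam_library(scenario_config(seed = 1))
  gt <- lib$ground_truth
  train_ids <- lib$drug_table$compound_id[lib$drug_table$set == "training"]
  asg <- structure(list(labels = gt$clusters[train_ids], k = 10),
                   class = "cluster_assignment")
  hits <- vapply(1:100, function(s) {
    tab <- assign_atc(gt, atc_purity = 0.6, n_atc_categories = 7, seed = s)
    res <- hypergeom_overrep(asg, tab)$table
    linked <- attr(tab, "linked_atc")
    vapply(seq_along(linked), function(cl) {
      res$p[res$cluster == cl & res$category == linked[[cl]]] < 0.05
    }, TRUE)
  }, logical(10))
  per_cluster_rate <- rowMeans(hits)
  expect_true(all(per_cluster_rate >= 0.95))
})

test_that("simulate_movie honors degenerate and ground-truth contracts", {
  zero_tpl <- matrix(0, 8, 8)
  mv0 <- simulate_movie(zero_tpl, duration_pre_s = 30, duration_post_s = 30,
                        fs = 2, n_layers = 1, baseline_rate_hz = 0,
                        drift_amp = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(mv0$events), 0)
  expect_equal(length(unique(as.vector(mv0$movie))), 1)  # constant movie

  tpl <- matrix(0, 8, 8); tpl[3, 4] <- 1
  mv <- simulate_movie(tpl, duration_pre_s = 60, duration_post_s = 60,
                       fs = 2, n_layers = 1, baseline_rate_hz = 0.1,
                       rate_per_unit = 0.3, drift_amp = 0, noise_sd = 0,
                       seed = 2)
  # self-consistency: planted times lie inside the recording
  expect_true(all(mv$events$time_s >= 0 & mv$events$time_s <= 120))
  # Poisson check on the boosted ROI, pooled over replicate movies
  total <- 0
  for (s in 1:20) {
    m <- simulate_movie(tpl, 60, 60, fs = 2, n_layers = 1,
                        baseline_rate_hz = 0.1, rate_per_unit = 0.3,
                        drift_amp = 0, noise_sd = 0, seed = 100 + s)
    ev <- m$events
    total <- total + sum(ev$roi_row == 3 & ev$roi_col == 4 & ev$time_s > 60)
  }
  lambda <- 20 * (0.1 + 0.3) * 60
  expect_lt(abs(total - lambda), 4 * sqrt(lambda))

  expect_error(simulate_movie(zero_tpl, fs = 0.5), "fs")
  expect_error(simulate_movie(zero_tpl, duration_pre_s = 0), "positive")
  expect_message(
    simulate_movie(matrix(-10, 8, 8), 10, 10, fs = 2, n_layers = 1,
                   baseline_rate_hz = 0.1, noise_sd = 0, seed = 1),
    "clipping")
})

test_that("movie generation is reproducible from its seed", {
  tpl <- matrix(0, 8, 8)
  a <- simulate_movie(tpl, 20, 20, fs = 2, n_layers = 1, seed = 5)
  b <- simulate_movie(tpl, 20, 20, fs = 2, n_layers = 1, seed = 5)
  expect_identical(a$movie, b$movie)
  expect_identical(a$events, b$events)
})
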