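# Shared fixtures, built in code at test time.

# A down-scaled scenario for fast unit tests (same noise structure as the
# default: within_cluster_sd = 0.25 * amp, replicate_sd = 0.5 * amp).
small_config <- function(seed = 1L, ...) {
  scenario_config(n_train_drugs = 40L, n_test_drugs = 12L, n_clusters = 4L,
                  grid_h = 20L, grid_w = 16L, n_atc_categories = 4L,
                  n_dmso_replicates = 10L, seed = seed, ...)
}

# Two well-separated Gaussian point clouds in d dimensions.
two_clouds <- function(n_per = 10L, d = 5L, sep = 50, sd = 1, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
             matrix(rnorm(n_per * d, sep, sd), n_per, d))
  rownames(x) <- sprintf("c%d_%02d", rep(1:2, each = n_per), seq_len(2 * n_per))
  x
}

# Independent reference implementation of threshold-crossing transient
# counting: literal state-machine loop over the dF/F samples.
ref_count_transients <- function(dff, fs, refractory_s = 1) {
  thr <- mean(dff) + 2 * sd(dff)
  cnt <- 0L
  last <- -Inf
  for (i in 2:length(dff)) {
    if (dff[i] > thr && dff[i - 1] <= thr && (i - last) >= refractory_s * fs) {
      cnt <- cnt + 1L
      last <- i
    }
  }
  cnt
}

# Synthetic dF/F trace with planted, well-separated transient kernels over
# bounded (uniform) noise, so the mean + 2 SD rule detects exactly the
# planted events: the noise never reaches the threshold and the kernel decays
# back under it within the refractory period.
planted_trace <- function(n = 600, fs = 5, event_times_s, amp = 0.1,
                          noise_sd = 0.02, decay_s = 0.4, seed = 1L) {
  set.seed(seed)
  bound <- noise_sd * sqrt(3)
  x <- runif(n, -bound, bound)
  t_s <- (seq_len(n) - 1) / fs
  for (et in event_times_s) {
    idx <- which(t_s >= et)
    x[idx] <- x[idx] + amp * exp(-(t_s[idx] - et) / decay_s)
  }
  x
}

# Fake consensus_result wrapping a given consensus matrix for cut/coherence
# tests that do not need the resampling machinery.
fake_consensus <- function(M, k) {
  ids <- rownames(M) %||% sprintf("item_%02d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  structure(list(M = stats::setNames(list(M), as.character(k)),
                 auc = NULL, k_range = k, linkage = "average", ids = ids),
            class = "consensus_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
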