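#' Scenario configuration for the synthetic screening library
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study conditions the pipeline is calibrated against: a training library of
#' 179 ATC-coded drugs in 10 latent phenotype clusters with 5 replicate brain
#' activity maps (BAMs) each, a test library of 121 unlabeled compounds, a
#' 50-replicate DMSO control arm, and 7 ATC therapeutic categories
#' statistically linked to the clusters.
#'
#' @param n_train_drugs number of training (ATC-coded) drugs.
#' @param n_test_drugs number of unlabeled test compounds.
#' @param n_clusters number of planted phenotype clusters.
#' @param n_replicates biological replicates (larvae) per compound.
#' @param grid_h,grid_w ROI grid dimensions (rows x columns).
#' @param n_layers number of imaged z-planes.
#' @param effect_amplitude mean absolute transient-count change in a cluster
#'   template's affected regions (counts per 10-min epoch).
#' @param within_cluster_sd SD of a drug's per-ROI deviation from its cluster
#'   template (counts); default `0.25 * effect_amplitude`.
#' @param replicate_sd per-replicate measurement noise SD (counts); default
#'   `0.5 * effect_amplitude`.
#' @param atc_purity probability that a training drug carries its cluster's
#'   linked ATC category rather than a random other category.
#' @param n_atc_categories number of ATC level-2 categories in play.
#' @param n_dmso_replicates replicates in the signal-free DMSO control arm.
#' @param seed integer seed; all generator randomness flows through it.
#'
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_train_drugs = 179L,
                            n_test_drugs = 121L,
                            n_clusters = 10L,
                            n_replicates = 5L,
                            grid_h = 60L,
                            grid_w = 40L,
                            n_layers = 2L,
                            effect_amplitude = 8,
                            within_cluster_sd = 0.25 * effect_amplitude,
                            replicate_sd = 0.5 * effect_amplitude,
                            atc_purity = 0.6,
                            n_atc_categories = 7L,
                            n_dmso_replicates = 50L,
                            seed = 1L) {
  cfg <- list(
    n_train_drugs = as.integer(n_train_drugs),
    n_test_drugs = as.integer(n_test_drugs),
    n_clusters = as.integer(n_clusters),
    n_replicates = as.integer(n_replicates),
    grid_h = as.integer(grid_h),
    grid_w = as.integer(grid_w),
    n_layers = as.integer(n_layers),
    effect_amplitude = effect_amplitude,
    within_cluster_sd = within_cluster_sd,
    replicate_sd = replicate_sd,
    atc_purity = atc_purity,
    n_atc_categories = as.integer(n_atc_categories),
    n_dmso_replicates = as.integer(n_dmso_replicates),
    seed = as.integer(seed)
  )
  counts <- c("n_train_drugs", "n_test_drugs", "n_clusters", "n_replicates",
              "grid_h", "grid_w", "n_layers", "n_atc_categories",
              "n_dmso_replicates")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("`", f, "` must be >= 1", call. = FALSE)
  }
  for (f in c("effect_amplitude", "within_cluster_sd", "replicate_sd")) {
    if (cfg[[f]] < 0) stop("`", f, "` must be >= 0", call. = FALSE)
  }
  if (cfg$atc_purity < 0 || cfg$atc_purity > 1) {
    stop("`atc_purity` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_clusters > cfg$n_train_drugs) {
    stop("`n_clusters` cannot exceed `n_train_drugs`", call. = FALSE)
  }
  class(cfg) <- "scenario_config"
  cfg
}

# ATC level-2 category codes available to the generator (subset used is
# determined by n_atc_categories).
atc_category_codes <- function(n) {
  codes <- c("N03", "N04", "N05", "N06", "A10", "C07", "R06", "M03", "S01",
             "V03", "N02", "C01")
  if (n > length(codes)) stop("at most ", length(codes), " ATC categories supported")
  codes[seq_len(n)]
}

#' Generate planted cluster effect templates
#'
#' Each template is a smooth, signed per-ROI effect map built from 3--5
#' contiguous anatomical blocks: full-width horizontal bands (forebrain /
#' midbrain / hindbrain style) and lateralized patch pairs mirrored about the
#' vertical midline. Templates are scaled so the mean absolute value over
#' affected ROIs is 1, and are regenerated until all pairwise Pearson
#' correlations fall below 0.5.
#'
#' @param n_clusters number of templates (>= 1).
#' @param grid_h,grid_w ROI grid dimensions, each >= 8.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per template.
#'
#' @return A list of `n_clusters` numeric `grid_h x grid_w` matrices.
#' @export
make_cluster_templates <- function(n_clusters, grid_h = 60L, grid_w = 40L,
                                   seed = 1L, max_tries = 200L) {
  if (n_clusters < 1L) stop("`n_clusters` must be >= 1", call. = FALSE)
  if (grid_h < 8L || grid_w < 8L) {
    stop("grid too small to place anatomical blocks (need at least 8x8)",
         call. = FALSE)
  }
  with_seed(seed, {
    templates <- vector("list", n_clusters)
    flat <- list()
    for (cl in seq_len(n_clusters)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        tpl <- random_template(grid_h, grid_w)
        v <- as.vector(tpl)
        if (length(flat) == 0L ||
            all(vapply(flat, function(u) abs(stats::cor(u, v)) < 0.5, TRUE))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", n_clusters,
             " mutually distinct templates on this grid", call. = FALSE)
      }
      templates[[cl]] <- tpl
      flat[[cl]] <- v
    }
    templates
  })
}

# One random block-structured, midline-symmetric, signed effect map with mean
# absolute amplitude 1 over its affected region.
random_template <- function(h, w) {
  m <- matrix(0, h, w)
  n_blocks <- sample(3:5, 1L)
  half <- floor(w / 2)
  for (b in seq_len(n_blocks)) {
    amp <- sample(c(-1, 1), 1L) * stats::runif(1, 0.6, 1.4)
    if (stats::runif(1) < 0.5) {
      # horizontal band spanning the full width
      bh <- sample(max(2L, floor(h / 8)):max(3L, floor(h / 3)), 1L)
      r0 <- sample(seq_len(h - bh + 1L), 1L)
      m[r0:(r0 + bh - 1L), ] <- m[r0:(r0 + bh - 1L), ] + amp
    } else {
      # lateralized patch pair, mirrored about the vertical midline
      bh <- sample(max(2L, floor(h / 10)):max(3L, floor(h / 4)), 1L)
      bw <- sample(2L:max(3L, floor(half / 2)), 1L)
      r0 <- sample(seq_len(h - bh + 1L), 1L)
      c0 <- sample(seq_len(half - bw + 1L), 1L)
      rows <- r0:(r0 + bh - 1L)
      cols <- c0:(c0 + bw - 1L)
      m[rows, cols] <- m[rows, cols] + amp
      m[rows, w + 1L - rev(cols)] <- m[rows, w + 1L - rev(cols)] + amp
    }
  }
  m <- smooth_map(smooth_map(m))
  affected <- abs(m) > 0.2 * max(abs(m))
  m / mean(abs(m[affected]))
}

# Separable binomial smoothing (kernel 1-4-6-4-1); symmetric, so midline
# mirror symmetry of the input is preserved.
smooth_map <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  sm_dim <- function(x) {
    n <- length(x)
    xp <- c(x[2:1], x, x[n:(n - 1)])  # reflect edges
    vapply(seq_len(n), function(i) sum(xp[i:(i + 4)] * k), 0)
  }
  m <- apply(m, 2L, sm_dim)
  t(apply(m, 1L, sm_dim))
}

#' Simulate a synthetic BAM screening library with planted ground truth
#'
#' Draws each replicate BAM as `cluster template x effect_amplitude +
#' drug-specific offset + replicate noise`, rounded to integers (BAM entries
#' are differences of transient counts). Training and test compounds are both
#' assigned to planted clusters; test compounds carry no ATC codes. A
#' signal-free DMSO control arm (noise-only BAMs) is included.
#'
#' @param config a [scenario_config()].
#'
#' @return An object of class `bam_library`: a list with elements
#'   `bams` (named list: drug id -> list of replicate integer matrices),
#'   `drug_table` (data frame: `compound_id`, `name`, `atc_codes`, `set`),
#'   `ground_truth` (planted clusters, templates, per-drug effect maps,
#'   cluster-linked ATC categories) and `config`.
#' @export
simulate_bam_library <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(derive_seed(config$seed, "simulate"), {
    templates <- make_cluster_templates(config$n_clusters, config$grid_h,
                                        config$grid_w,
                                        seed = derive_seed(config$seed, "templates"))
    n_tr <- config$n_train_drugs
    n_te <- config$n_test_drugs
    train_ids <- sprintf("drug_%03d", seq_len(n_tr))
    test_ids <- sprintf("cmpd_%03d", seq_len(n_te))
    # near-balanced planted partition for both sets
    cl_train <- sample(rep_len(seq_len(config$n_clusters), n_tr))
    cl_test <- sample(rep_len(seq_len(config$n_clusters), n_te))
    clusters <- stats::setNames(c(cl_train, cl_test), c(train_ids, test_ids))

    planted <- lapply(clusters, function(cl) {
      templates[[cl]] * config$effect_amplitude +
        matrix(stats::rnorm(config$grid_h * config$grid_w,
                            sd = config$within_cluster_sd),
               config$grid_h, config$grid_w)
    })
    names(planted) <- names(clusters)

    draw_reps <- function(map, n) {
      lapply(seq_len(n), function(i) {
        r <- round(map + matrix(stats::rnorm(length(map),
                                             sd = config$replicate_sd),
                                nrow(map), ncol(map)))
        storage.mode(r) <- "integer"
        r
      })
    }
    bams <- lapply(planted, draw_reps, n = config$n_replicates)
    zero_map <- matrix(0, config$grid_h, config$grid_w)
    bams[["DMSO"]] <- draw_reps(zero_map, config$n_dmso_replicates)

    ground_truth <- structure(
      list(clusters = clusters,
           templates = templates,
           planted_maps = planted,
           linked_atc = NULL),
      class = "bam_ground_truth")

    drug_table <- assign_atc(ground_truth,
                             atc_purity = config$atc_purity,
                             n_atc_categories = config$n_atc_categories,
                             train_ids = train_ids, test_ids = test_ids,
                             seed = derive_seed(config$seed, "atc"))
    ground_truth$linked_atc <- attr(drug_table, "linked_atc")

    structure(list(bams = bams, drug_table = drug_table,
                   ground_truth = ground_truth, config = config),
              class = "bam_library")
  })
}

#' Re-simulate replicate acquisitions for selected compounds
#'
#' Draws a fresh, independent set of replicate BAMs for the given compounds
#' from their planted effect maps at the library's replicate noise level —
#' the in-silico analog of putting new larvae through the imaging rig.
#'
#' @param library a [simulate_bam_library()] result.
#' @param drug_ids compounds to re-acquire (default: all non-control).
#' @param seed integer seed for the new acquisition.
#'
#' @return Named list: drug id -> list of replicate integer matrices.
#' @export
resimulate_replicates <- function(library, drug_ids = NULL, seed = 1L) {
  stopifnot(inherits(library, "bam_library"))
  cfg <- library$config
  drug_ids <- drug_ids %||% names(library$ground_truth$planted_maps)
  missing <- setdiff(drug_ids, names(library$ground_truth$planted_maps))
  if (length(missing)) {
    stop("no planted map for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(library$ground_truth$planted_maps[drug_ids], function(map) {
      lapply(seq_len(cfg$n_replicates), function(i) {
        r <- round(map + matrix(stats::rnorm(length(map), sd = cfg$replicate_sd),
                                nrow(map), ncol(map)))
        storage.mode(r) <- "integer"
        r
      })
    })
    names(out) <- drug_ids
    out
  })
}

#' Assign ATC categories statistically linked to planted clusters
#'
#' Each planted cluster is linked to one ATC level-2 category (cyclically when
#' there are more clusters than categories). A training drug receives its
#' cluster's linked category with probability `atc_purity` and a uniformly
#' random other category otherwise; test drugs receive no code.
#'
#' @param ground_truth a `bam_ground_truth` (from [simulate_bam_library()]).
#' @param atc_purity probability in \[0, 1\].
#' @param n_atc_categories number of categories.
#' @param train_ids,test_ids compound id vectors; defaults taken from
#'   `ground_truth` name prefixes.
#' @param seed integer seed.
#'
#' @return A drug-table data frame (`compound_id`, `name`, `atc_codes`, `set`)
#'   with the cluster-to-category link in `attr(, "linked_atc")`.
#' @export
assign_atc <- function(ground_truth, atc_purity = 0.6, n_atc_categories = 7L,
                       train_ids = NULL, test_ids = NULL, seed = 1L) {
  if (atc_purity < 0 || atc_purity > 1) {
    stop("`atc_purity` must lie in [0, 1]", call. = FALSE)
  }
  ids <- names(ground_truth$clusters)
  train_ids <- train_ids %||% ids[startsWith(ids, "drug_")]
  test_ids <- test_ids %||% ids[startsWith(ids, "cmpd_")]
  categories <- atc_category_codes(n_atc_categories)
  n_clusters <- length(ground_truth$templates)
  linked <- stats::setNames(
    categories[((seq_len(n_clusters) - 1L) %% n_atc_categories) + 1L],
    seq_len(n_clusters))
  with_seed(seed, {
    codes <- vapply(train_ids, function(id) {
      own <- linked[[ground_truth$clusters[[id]]]]
      if (stats::runif(1) < atc_purity) {
        own
      } else {
        sample(setdiff(categories, own), 1L)
      }
    }, "")
    tab <- data.frame(
      compound_id = c(train_ids, test_ids, "DMSO"),
      name = c(train_ids, test_ids, "DMSO"),
      atc_codes = c(codes, rep("", length(test_ids)), ""),
      set = c(rep("training", length(train_ids)),
              rep("test", length(test_ids)), "control"),
      stringsAsFactors = FALSE)
    attr(tab, "linked_atc") <- linked
    tab
  })
}

#' Simulate a multi-plane calcium movie with planted transients
#'
#' Per-ROI inhomogeneous Poisson events (baseline rate before treatment,
#' baseline plus template-scaled rate after) are convolved with a fast-rise /
#' exponential-decay calcium-indicator kernel, rendered as pixel blocks,
#' and corrupted with slow sinusoidal illumination drift and white noise.
#'
#' @param effect_template per-ROI rate-change map (Hz per unit); its
#'   dimensions set the ROI grid. Post-treatment rates that would go negative
#'   are clipped to 0 with a message.
#' @param duration_pre_s,duration_post_s epoch durations in seconds
#'   (defaults 600 and 900: 10 min before, 15 min after treatment).
#' @param fs frame rate in Hz (>= 1).
#' @param n_layers number of z-planes.
#' @param baseline_rate_hz pre-treatment event rate per ROI.
#' @param rate_per_unit rate change (Hz) per unit of template amplitude.
#' @param f_baseline baseline fluorescence (a.u.).
#' @param event_amplitude fluorescence jump per event (a.u.).
#' @param rise_s,decay_s indicator-kernel time constants.
#' @param drift_amp,drift_freq_hz relative amplitude and frequency of the
#'   illumination drift sinusoid (frequency below the 0.2 Hz filter cutoff).
#' @param noise_sd white-noise SD per pixel (a.u.).
#' @param block_px pixels per ROI side (3 x 3 pixels of 1.69 um^2 gives the
#'   15.21 um^2 ROI).
#' @param seed integer seed.
#'
#' @return A list of class `calcium_movie`: `movie` (array time x plane x
#'   pixel-rows x pixel-cols), `events` (data frame plane/roi_row/roi_col/
#'   time_s of planted transients), `fs`, `pixel_area` (um^2),
#'   `plane_spacing` (um), `pre_frames`, `post_frames`, `grid` dims.
#' @export
simulate_movie <- function(effect_template,
                           duration_pre_s = 600,
                           duration_post_s = 900,
                           fs = 5,
                           n_layers = 2L,
                           baseline_rate_hz = 0.1,
                           rate_per_unit = 0.05,
                           f_baseline = 100,
                           event_amplitude = 30,
                           rise_s = 0.1,
                           decay_s = 1,
                           drift_amp = 0.02,
                           drift_freq_hz = 0.02,
                           noise_sd = 1,
                           block_px = 3L,
                           seed = 1L) {
  if (fs < 1) stop("`fs` must be >= 1 Hz", call. = FALSE)
  if (duration_pre_s <= 0 || duration_post_s <= 0) {
    stop("epoch durations must be positive", call. = FALSE)
  }
  gh <- nrow(effect_template)
  gw <- ncol(effect_template)
  n_pre <- round(duration_pre_s * fs)
  n_post <- round(duration_post_s * fs)
  n_t <- n_pre + n_post
  t_s <- (seq_len(n_t) - 1) / fs

  # indicator kernel: difference of exponentials, unit peak
  kt <- seq(0, 5 * decay_s, by = 1 / fs)
  kern <- exp(-kt / decay_s) - exp(-kt / rise_s)
  kern <- kern / max(kern)

  post_rate <- baseline_rate_hz + effect_template * rate_per_unit
  n_clip <- sum(post_rate < 0)
  if (n_clip > 0) {
    message("clipping ", n_clip, " negative post-treatment rates to 0")
    post_rate[post_rate < 0] <- 0
  }

  with_seed(seed, {
    movie <- array(0, dim = c(n_t, n_layers, gh * block_px, gw * block_px))
    ev_plane <- integer(0); ev_row <- integer(0); ev_col <- integer(0)
    ev_time <- numeric(0)
    drift <- 1 + drift_amp * sin(2 * pi * drift_freq_hz * t_s)
    for (p in seq_len(n_layers)) {
      for (i in seq_len(gh)) {
        for (j in seq_len(gw)) {
          n_ev_pre <- stats::rpois(1L, baseline_rate_hz * duration_pre_s)
          n_ev_post <- stats::rpois(1L, post_rate[i, j] * duration_post_s)
          times <- c(stats::runif(n_ev_pre, 0, duration_pre_s),
                     stats::runif(n_ev_post, duration_pre_s,
                                  duration_pre_s + duration_post_s))
          trace <- rep(f_baseline, n_t)
          if (length(times)) {
            idx <- pmin(n_t, floor(times * fs) + 1L)
            impulses <- numeric(n_t)
            for (ix in idx) impulses[ix] <- impulses[ix] + 1
            resp <- stats::convolve(impulses, rev(kern), type = "open")[seq_len(n_t)]
            trace <- trace + event_amplitude * resp
            ev_plane <- c(ev_plane, rep(p, length(times)))
            ev_row <- c(ev_row, rep(i, length(times)))
            ev_col <- c(ev_col, rep(j, length(times)))
            ev_time <- c(ev_time, sort(times))
          }
          trace <- trace * drift
          rows <- ((i - 1L) * block_px + 1L):(i * block_px)
          cols <- ((j - 1L) * block_px + 1L):(j * block_px)
          px <- length(rows) * length(cols)
          noise <- if (noise_sd > 0) {
            matrix(stats::rnorm(n_t * px, sd = noise_sd), n_t, px)
          } else {
            matrix(0, n_t, px)
          }
          movie[, p, rows, cols] <- array(trace + noise, dim = c(n_t, length(rows), length(cols)))
        }
      }
    }
    events <- data.frame(plane = ev_plane, roi_row = ev_row, roi_col = ev_col,
                         time_s = ev_time)
    structure(list(movie = movie, events = events, fs = fs,
                   pixel_area = 15.21 / block_px^2, plane_spacing = 100,
                   pre_frames = seq_len(n_pre),
                   post_frames = (n_pre + 1L):n_t,
                   grid = c(gh, gw), block_px = block_px),
              class = "calcium_movie")
  })
}

#' Write a calcium movie to multi-page TIFF (one file per z-plane)
#'
#' @param movie a [simulate_movie()] result.
#' @param path_prefix output prefix; files are `<prefix>_plane<k>.tif`.
#' @return Invisibly, the written file paths.
#' @export
write_movie_tiff <- function(movie, path_prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF movies requires the 'tiff' package", call. = FALSE)
  }
  d <- dim(movie$movie)
  mx <- max(movie$movie)
  paths <- character(d[2])
  for (p in seq_len(d[2])) {
    frames <- lapply(seq_len(d[1]), function(t) movie$movie[t, p, , ] / mx)
    paths[p] <- paste0(path_prefix, "_plane", p, ".tif")
    tiff::writeTIFF(frames, paths[p], bits.per.sample = 16L)
  }
  invisible(paths)
}
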