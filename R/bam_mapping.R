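#' Standard brain template for a ROI grid
#'
#' An elliptical brain mask on the ROI grid with two anterior-lateral eye
#' regions excluded and the vertical midline recorded for mirror-symmetry
#' registration. The retained region is the mask minus the eye regions.
#'
#' @param grid_h,grid_w ROI grid dimensions.
#' @return A list of class `brain_template`: `mask` (logical matrix, brain),
#'   `eye_mask` (logical matrix), `retained` (mask & !eye), `midline_col`
#'   (column coordinate of the midline, `(grid_w + 1) / 2`).
#' @export
brain_template <- function(grid_h = 60L, grid_w = 40L) {
  cy <- (grid_h + 1) / 2
  cx <- (grid_w + 1) / 2
  ry <- grid_h * 0.47
  rx <- grid_w * 0.44
  yy <- matrix(seq_len(grid_h), grid_h, grid_w)
  xx <- matrix(seq_len(grid_w), grid_h, grid_w, byrow = TRUE)
  mask <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  # eyes: two lateral discs in the anterior third, mirror-symmetric
  er <- max(2, round(min(grid_h, grid_w) / 10))
  ey <- round(grid_h * 0.18)
  ex1 <- round(grid_w * 0.16)
  ex2 <- grid_w + 1 - ex1
  eye <- ((yy - ey)^2 + (xx - ex1)^2 <= er^2) |
    ((yy - ey)^2 + (xx - ex2)^2 <= er^2)
  structure(list(mask = mask, eye_mask = eye & mask,
                 retained = mask & !eye,
                 midline_col = cx, grid = c(grid_h, grid_w)),
            class = "brain_template")
}

#' Mesh a calcium movie into ROI traces
#'
#' Tiles each frame into square pixel blocks of area `roi_area` and averages
#' intensity within each block, per frame and z-plane.
#'
#' @param movie a `calcium_movie` (array `time x plane x rows x cols` in
#'   `$movie`, with `$pixel_area` in um^2 per pixel).
#' @param roi_area ROI area in um^2; must map to an integer pixel block.
#'   Default 15.21 um^2.
#' @return A list of class `roi_trace_set`: `traces` (array `time x plane x
#'   grid_h x grid_w`), `fs`, `roi_area`, `grid`, plus the movie's epoch
#'   frame indices.
#' @export
mesh_rois <- function(movie, roi_area = 15.21) {
  d <- dim(movie$movie)
  block <- sqrt(roi_area / movie$pixel_area)
  if (abs(block - round(block)) > 1e-6) {
    valid <- round(block)
    stop(sprintf(
      "roi_area %.4g um^2 is not an integer pixel block at %.4g um^2/pixel; nearest valid roi_area is %.4g um^2",
      roi_area, movie$pixel_area, valid^2 * movie$pixel_area), call. = FALSE)
  }
  block <- as.integer(round(block))
  if (d[3] %% block != 0 || d[4] %% block != 0) {
    stop("frame dimensions are not divisible by the ROI block size", call. = FALSE)
  }
  gh <- d[3] %/% block
  gw <- d[4] %/% block
  traces <- array(0, dim = c(d[1], d[2], gh, gw))
  for (i in seq_len(gh)) {
    rows <- ((i - 1L) * block + 1L):(i * block)
    for (j in seq_len(gw)) {
      cols <- ((j - 1L) * block + 1L):(j * block)
      sub <- movie$movie[, , rows, cols, drop = FALSE]
      traces[, , i, j] <- apply(sub, c(1, 2), mean)
    }
  }
  structure(list(traces = traces, fs = movie$fs, roi_area = roi_area,
                 grid = c(gh, gw), pre_frames = movie$pre_frames,
                 post_frames = movie$post_frames),
            class = "roi_trace_set")
}

#' Zero-phase high-pass filter for fluorescence traces
#'
#' Second-order Butterworth high-pass applied forward and backward
#' (`signal::filtfilt`), removing slow illumination fluctuations and the DC
#' component. Default cutoff 0.2 Hz.
#'
#' @param trace numeric time series.
#' @param cutoff_hz cutoff frequency, `0 < cutoff_hz < fs/2`.
#' @param fs sampling rate in Hz.
#' @return The filtered trace (zero-mean fluctuation component).
#' @export
highpass <- function(trace, cutoff_hz = 0.2, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("`cutoff_hz` must lie in (0, fs/2)", call. = FALSE)
  }
  min_len <- ceiling(3 * 2 * fs / cutoff_hz)
  if (length(trace) < min_len) {
    stop("trace too short for filter warm-up (need >= ", min_len, " samples)",
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "high")
  # demean first: filtfilt does not estimate initial conditions, so a raw DC
  # offset would leak an edge transient into the output
  as.numeric(signal::filtfilt(bf, trace - mean(trace)))
}

#' Count calcium transients in a filtered fluorescence trace
#'
#' The trace is converted to dF/F against a baseline `f0` (the epoch mean of
#' the unfiltered trace), and events are counted as upward crossings of
#' `mean + 2 * SD` of the dF/F curve, separated by a refractory period.
#'
#' @param filtered_trace high-pass-filtered fluorescence fluctuations
#'   (`F - F0` scale), length >= 10.
#' @param f0 baseline fluorescence (> 0); if `NULL`, `filtered_trace` is
#'   treated as a raw trace: `f0 = mean(trace)` and the baseline is
#'   subtracted before thresholding.
#' @param fs sampling rate in Hz (needed for the refractory period).
#' @param refractory_s minimum separation between counted events (s).
#' @param min_amplitude optional absolute floor (dF/F units) for the
#'   threshold. The mean + 2 SD rule self-scales: in a near-silent epoch it
#'   drops to twice the noise SD and fires on noise alone. A floor around
#'   the smallest credible transient amplitude (e.g. 0.05) suppresses that;
#'   the default 0 keeps the pure mean + 2 SD rule.
#' @return Integer event count.
#' @export
count_transients <- function(filtered_trace, f0 = NULL, fs = 1,
                             refractory_s = 1, min_amplitude = 0) {
  if (length(filtered_trace) < 10L) {
    stop("trace must have at least 10 samples", call. = FALSE)
  }
  if (is.null(f0)) {
    f0 <- mean(filtered_trace)
    filtered_trace <- filtered_trace - f0
  }
  if (!is.finite(f0) || f0 <= 0) {
    stop("baseline fluorescence F0 must be positive", call. = FALSE)
  }
  dff <- filtered_trace / f0
  s <- stats::sd(dff)
  # a flat trace has no transients; guard against counting numerical jitter
  if (!is.finite(s) || s < 1e-9) return(0L)
  thr <- max(mean(dff) + 2 * s, min_amplitude)
  above <- dff > thr
  crossings <- which(above[-1L] & !above[-length(above)]) + 1L
  if (!length(crossings)) return(0L)
  refr <- refractory_s * fs
  kept <- crossings[1L]
  last <- crossings[1L]
  for (cx in crossings[-1L]) {
    if (cx - last >= refr) {
      kept <- c(kept, cx)
      last <- cx
    }
  }
  length(kept)
}

#' Per-epoch transient counts for all ROIs of a movie
#'
#' For each ROI, plane and epoch: the epoch's raw trace is high-pass filtered,
#' converted to dF/F against the epoch-mean baseline, and transients are
#' counted with [count_transients()].
#'
#' @param rois a [mesh_rois()] result.
#' @param cutoff_hz high-pass cutoff (default 0.2 Hz).
#' @param refractory_s event refractory period (s).
#' @param min_amplitude threshold floor passed to [count_transients()].
#' @return List with integer arrays `c0` and `c1` (`grid_h x grid_w x
#'   n_layers`) and epoch durations `dur0_s`, `dur1_s`.
#' @export
count_epoch_transients <- function(rois, cutoff_hz = 0.2, refractory_s = 1,
                                   min_amplitude = 0) {
  d <- dim(rois$traces)
  gh <- d[3]; gw <- d[4]; np <- d[2]
  c0 <- array(0L, dim = c(gh, gw, np))
  c1 <- array(0L, dim = c(gh, gw, np))
  for (p in seq_len(np)) {
    for (i in seq_len(gh)) {
      for (j in seq_len(gw)) {
        for (ep in 1:2) {
          idx <- if (ep == 1) rois$pre_frames else rois$post_frames
          raw <- rois$traces[idx, p, i, j]
          f0 <- mean(raw)
          filt <- highpass(raw, cutoff_hz, rois$fs)
          n <- count_transients(filt, f0 = f0, fs = rois$fs,
                                refractory_s = refractory_s,
                                min_amplitude = min_amplitude)
          if (ep == 1) c0[i, j, p] <- n else c1[i, j, p] <- n
        }
      }
    }
  }
  list(c0 = c0, c1 = c1,
       dur0_s = length(rois$pre_frames) / rois$fs,
       dur1_s = length(rois$post_frames) / rois$fs)
}

#' Register a mean image to the brain template
#'
#' Coarse-to-fine grid search over a similarity transform (rotation,
#' translation, isotropic scale) maximizing the sum of (a) Jaccard overlap of
#' the Otsu-thresholded foreground with the template mask and (b) left-right
#' mirror correlation about the template midline.
#'
#' @param image numeric matrix on the ROI grid (e.g. mean fluorescence map).
#' @param template a [brain_template()].
#' @param rot_range_deg rotation search half-range (degrees; default 20).
#' @param rot_step_deg fine rotation step (default 0.5).
#' @param trans_range translation search half-range in ROIs.
#' @param scales candidate isotropic scales.
#' @return A list of class `bam_transform`: `rotation_deg`, `dy`, `dx`,
#'   `scale`, `score` and the identity-relative score improvement.
#' @export
register_to_template <- function(image, template,
                                 rot_range_deg = 20, rot_step_deg = 0.5,
                                 trans_range = 4,
                                 scales = c(0.9, 0.95, 1, 1.05, 1.1)) {
  thr <- otsu_threshold(image)
  fg <- image > thr
  if (!any(fg)) stop("no foreground found after background removal", call. = FALSE)
  img <- image - min(image)

  score_tf <- function(rot, dy, dx, sc) {
    tf <- transform_image(img, rot, dy, dx, sc, fill = 0)
    fg_t <- tf > (thr - min(image))
    inter <- sum(fg_t & template$mask)
    uni <- sum(fg_t | template$mask)
    jacc <- if (uni > 0) inter / uni else 0
    v <- tf[template$mask]
    m <- mirror_map(tf)[template$mask]
    mc <- if (stats::sd(v) > 0 && stats::sd(m) > 0) stats::cor(v, m) else 0
    jacc + mc
  }

  search <- function(rots, dys, dxs, scs, best) {
    for (sc in scs) for (rot in rots) for (dy in dys) for (dx in dxs) {
      s <- score_tf(rot, dy, dx, sc)
      if (s > best$score + 1e-12) {
        best <- list(rotation_deg = rot, dy = dy, dx = dx, scale = sc, score = s)
      }
    }
    best
  }

  id_score <- score_tf(0, 0, 0, 1)
  best <- list(rotation_deg = 0, dy = 0, dx = 0, scale = 1, score = id_score)
  best <- search(seq(-rot_range_deg, rot_range_deg, by = 2),
                 seq(-trans_range, trans_range, by = 2),
                 seq(-trans_range, trans_range, by = 2),
                 scales, best)
  best <- search(seq(best$rotation_deg - 2, best$rotation_deg + 2,
                     by = rot_step_deg),
                 seq(best$dy - 1, best$dy + 1, by = 1),
                 seq(best$dx - 1, best$dx + 1, by = 1),
                 best$scale, best)
  if (best$score <= id_score && !(best$rotation_deg == 0 && best$dy == 0 &&
                                  best$dx == 0 && best$scale == 1)) {
    warning("no candidate improved on the identity transform; returning identity")
    best <- list(rotation_deg = 0, dy = 0, dx = 0, scale = 1, score = id_score)
  }
  best$improvement <- best$score - id_score
  class(best) <- "bam_transform"
  best
}

#' Apply a registration transform to a per-ROI map
#'
#' Resamples the map under the similarity transform and masks it to the
#' template's retained region (eye-region ROIs and out-of-template ROIs are
#' set to `NA`).
#'
#' @param map numeric ROI matrix.
#' @param transform a [register_to_template()] result.
#' @param template a [brain_template()].
#' @return The registered map with `NA` outside the retained region.
#' @export
apply_transform <- function(map, transform, template) {
  out <- transform_image(map, transform$rotation_deg, transform$dy,
                         transform$dx, transform$scale, fill = 0)
  out[!template$retained] <- NA_real_
  out
}

#' Compute a brain activity map (BAM) from epoch transient counts
#'
#' The BAM entry is the change in calcium-transient counts between the
#' post-treatment and pre-treatment epochs, summed across z-planes. When the
#' two epochs differ in duration, counts are first rate-normalized to a
#' common reference duration (default 10 min) and rounded to the nearest
#' integer, so equal event rates yield a zero entry.
#'
#' @param c0,c1 integer count arrays (`grid_h x grid_w x n_layers`, or
#'   matrices for a single layer) for the pre- and post-treatment epochs.
#' @param dur0_s,dur1_s epoch durations in seconds.
#' @param normalize rate-normalize to `reference_s` before differencing
#'   (default `TRUE`); with `FALSE`, raw counts are differenced.
#' @param reference_s reference duration (default 600 s = 10 min).
#' @return Integer matrix of per-ROI count changes.
#' @export
compute_bam <- function(c0, c1, dur0_s = 600, dur1_s = 600, normalize = TRUE,
                        reference_s = 600) {
  if (is.matrix(c0)) c0 <- array(c0, dim = c(dim(c0), 1L))
  if (is.matrix(c1)) c1 <- array(c1, dim = c(dim(c1), 1L))
  if (!identical(dim(c0), dim(c1))) {
    stop("pre and post count grids have mismatched dimensions", call. = FALSE)
  }
  if (any(c0 < 0) || any(c1 < 0)) stop("counts must be non-negative", call. = FALSE)
  if (normalize) {
    c0 <- round(c0 * reference_s / dur0_s)
    c1 <- round(c1 * reference_s / dur1_s)
  }
  a <- apply(c1 - c0, c(1, 2), sum)
  storage.mode(a) <- "integer"
  a
}

#' Convenience: calcium movie to BAM
#'
#' Meshes the movie into ROIs, filters and counts transients per epoch, and
#' differences the counts into a BAM. Optionally registers the mean image to
#' a brain template first and masks eye-region ROIs out of the result.
#'
#' @param movie a `calcium_movie`.
#' @param template optional [brain_template()] on the ROI grid.
#' @inheritParams mesh_rois
#' @inheritParams count_epoch_transients
#' @return Integer BAM matrix (with `NA` outside the retained region when a
#'   template is supplied).
#' @export
movie_to_bam <- function(movie, template = NULL, roi_area = 15.21,
                         cutoff_hz = 0.2, refractory_s = 1) {
  rois <- mesh_rois(movie, roi_area)
  counts <- count_epoch_transients(rois, cutoff_hz, refractory_s)
  bam <- compute_bam(counts$c0, counts$c1, counts$dur0_s, counts$dur1_s)
  if (!is.null(template)) {
    # register on the ROI-scale mean image of the pre-treatment epoch
    mean_roi <- apply(rois$traces[rois$pre_frames, 1, , , drop = FALSE],
                      c(3, 4), mean)
    tf <- register_to_template(mean_roi, template)
    bam_t <- apply_transform(bam, tf, template)
    bam <- round(bam_t)
  }
  bam
}

#' Compute a T-score BAM across replicate BAMs
#'
#' Per ROI, the one-sample T statistic of the replicate BAM values:
#' `t = mean / (sd / sqrt(n))`. Where the replicate SD is exactly zero the
#' statistic is 0 if the mean is also 0, otherwise the SD is floored at
#' `eps` so the statistic stays finite. The default floor of 1 is the
#' rounding quantum of BAM values (counts are integers): replicate agreement
#' tighter than one count is quantization, not evidence, and the floor keeps
#' the capped statistic on the same scale as genuine T values so degenerate
#' ROIs cannot dominate the PCA.
#'
#' @param bams list of >= 2 replicate BAM matrices with identical dimensions
#'   (or a 3-D array with replicates along the third dimension).
#' @param eps SD floor for the degenerate zero-SD, nonzero-mean case
#'   (default 1 count).
#' @return Numeric T-score matrix with attribute `n` (replicate count).
#' @export
compute_tscore_bam <- function(bams, eps = 1) {
  if (is.array(bams) && length(dim(bams)) == 3L) {
    bams <- lapply(seq_len(dim(bams)[3]), function(i) bams[, , i])
  }
  n <- length(bams)
  if (n < 2L) stop("need at least 2 replicates (SD undefined otherwise)",
                   call. = FALSE)
  dims <- lapply(bams, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("replicate BAMs have mismatched dimensions", call. = FALSE)
  }
  x <- matrix(vapply(bams, as.numeric, numeric(prod(dims[[1]]))),
              nrow = prod(dims[[1]]))  # cells x reps
  m <- rowMeans(x)
  s <- sqrt(pmax(rowSums((x - m)^2) / (n - 1), 0))
  zero_sd <- s == 0
  t <- m / (pmax(s, eps) / sqrt(n))
  t[zero_sd & m == 0] <- 0
  t <- matrix(t, dims[[1]][1], dims[[1]][2])
  attr(t, "n") <- n
  t
}

#' T-score BAMs for every compound of a synthetic library
#'
#' @param library a [simulate_bam_library()] result.
#' @param set which compound sets to include.
#' @param eps SD floor passed to [compute_tscore_bam()].
#' @return Named list of T-score matrices (drug id -> matrix).
#' @export
tscore_library <- function(library, set = c("training", "test", "control"),
                           eps = 1) {
  stopifnot(inherits(library, "bam_library"))
  set <- match.arg(set, several.ok = TRUE)
  ids <- library$drug_table$compound_id[library$drug_table$set %in% set]
  out <- lapply(library$bams[ids], compute_tscore_bam, eps = eps)
  names(out) <- ids
  out
}
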