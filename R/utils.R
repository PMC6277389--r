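# Internal helpers shared across modules.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber user state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a stage-specific
#' seed inside the 32-bit integer range, so each pipeline stage gets its own
#' reproducible randomness stream from a single user-facing seed.
#'
#' @param seed master seed (integer).
#' @param stage stage name (character scalar).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + offset) %% 2147483647)
}

# Otsu's threshold on a numeric image: maximize between-class variance over a
# fixed-bin histogram. Used to strip dark background before registration.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(findInterval(x, seq(r[1], r[2], length.out = n_bins + 1L),
                             rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- seq(r[1], r[2], length.out = n_bins + 1L)[-1L] - diff(r) / (2 * n_bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# Sample `img` (matrix, rows = y, cols = x) under a similarity transform with
# bilinear interpolation. The transform maps output coordinates back into the
# input: rotation (degrees, about the grid center), translation (rows, cols)
# and isotropic scale. Out-of-range samples take `fill`.
transform_image <- function(img, rotation_deg = 0, dy = 0, dx = 0, scale = 1,
                            fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  th <- rotation_deg * pi / 180
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  # inverse map: undo translation, then rotation/scale about the center
  sy <- (cos(th) * (gy - dy) - sin(th) * (gx - dx)) / scale + cy
  sx <- (sin(th) * (gy - dy) + cos(th) * (gx - dx)) / scale + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0;   fx <- sx - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- rep(fill, length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fy) * (1 - fx) * val(y0, x0) +
    (1 - fy) * fx * val(y0, x0 + 1L) +
    fy * (1 - fx) * val(y0 + 1L, x0) +
    fy * fx * val(y0 + 1L, x0 + 1L)
  matrix(out, h, w)
}

# Mirror a grid map about the vertical midline (column axis).
mirror_map <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

`%||%` <- function(a, b) if (is.null(a)) b else a
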