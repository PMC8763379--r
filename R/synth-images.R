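# Synthetic sonomyography frame generator.
#
# Image model: a fixed "speckle" base texture (spatially smoothed white
# noise) stands in for the resting ultrasound view of the forearm. Each
# motion class owns a smooth deformation template -- a displacement field
# plus a local intensity-gain field -- emulating how muscle deformation
# warps and brightens/darkens regions of the image. A cue cycle ramps the
# deformation amplitude up over the move segment, holds it, ramps it down,
# and rests. Repetition-level variability perturbs the template's amplitude
# and spatial center; per-frame Gaussian noise sits on top.

# Row-normalized Gaussian smoothing matrix (n x n, band of +/- 4 sigma).
gaussian_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

# Smooth a matrix with a separable Gaussian kernel of given sigma.
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  Kh <- gaussian_smoother(nrow(mat), sigma)
  Kw <- gaussian_smoother(ncol(mat), sigma)
  Kh %*% mat %*% t(Kw)
}

# Smoothed standard-normal random field (unit sd, mean 0) drawn from the
# current RNG state.
random_smooth_field <- function(h, w, sigma) {
  f <- smooth_field(matrix(stats::rnorm(h * w), h, w), sigma)
  s <- stats::sd(f)
  if (s == 0) f else (f - mean(f)) / s
}

# Bilinear sampling of matrix `mat` at fractional (row, col) coordinates,
# clamped to the image border.
bilinear_sample <- function(mat, yi, xi) {
  h <- nrow(mat); w <- ncol(mat)
  yi <- pmin(pmax(yi, 1), h)
  xi <- pmin(pmax(xi, 1), w)
  y0 <- pmin(floor(yi), h - 1L); x0 <- pmin(floor(xi), w - 1L)
  fy <- yi - y0; fx <- xi - x0
  i00 <- (x0 - 1) * h + y0
  v <- (1 - fy) * (1 - fx) * mat[i00] +
    fy * (1 - fx) * mat[i00 + 1] +
    (1 - fy) * fx * mat[i00 + h] +
    fy * fx * mat[i00 + h + 1]
  matrix(v, h, w)
}

# Maximum displacement (pixels) and intensity-gain amplitude at
# class_separation = 1. Fixed internal scales of the image model.
.smg_disp_scale <- 3
.smg_gain_scale <- 0.15

#' Generate the deformation template of one motion class
#'
#' Each motion class is assigned a smooth spatial deformation pattern:
#' per-pixel displacement fields (`dx`, `dy`, in pixels) and a local
#' intensity-gain field (`gain`). Pattern magnitude scales linearly with
#' `class_separation`; with `class_separation = 0` every class collapses to
#' the rest (zero) field. `class_id = 0` is the reserved rest index and
#' always returns the zero field.
#'
#' The template is drawn from an RNG substream keyed by the configuration
#' seed and the class id, so the same configuration always yields the same
#' template regardless of the caller's RNG state.
#'
#' @param cfg an [image_gen_config()].
#' @param class_id integer in `0:n_classes`; 0 denotes rest.
#' @return an object of class `smg_template`: list with `H x W` matrices
#'   `dx`, `dy`, `gain`.
#' @export
make_class_template <- function(cfg, class_id) {
  stopifnot(inherits(cfg, "smg_image_config"))
  if (class_id < 0L || class_id > cfg$n_classes) {
    stop(sprintf("class_id must be in 0..%d (0 = rest)", cfg$n_classes),
         call. = FALSE)
  }
  h <- cfg$frame_height; w <- cfg$frame_width
  if (class_id == 0L || cfg$class_separation == 0) {
    z <- matrix(0, h, w)
    return(structure(list(dx = z, dy = z, gain = z), class = "smg_template"))
  }
  sigma <- min(h, w) / 6 # deformation varies on a muscle-compartment scale
  tpl <- with_substream(cfg$seed, "template", class_id, {
    list(
      dx = random_smooth_field(h, w, sigma),
      dy = random_smooth_field(h, w, sigma),
      gain = random_smooth_field(h, w, sigma)
    )
  })
  a <- cfg$class_separation
  structure(list(dx = a * .smg_disp_scale * tpl$dx,
                 dy = a * .smg_disp_scale * tpl$dy,
                 gain = a * .smg_gain_scale * tpl$gain),
            class = "smg_template")
}

# Shift a field's spatial pattern by (oy, ox) pixels (bilinear, clamped).
shift_field <- function(mat, oy, ox) {
  if (oy == 0 && ox == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  yi <- rep(seq_len(h), times = w) - oy
  xi <- rep(seq_len(w), each = h) - ox
  bilinear_sample(mat, yi, xi)
}

# Warp the base texture by `amplitude` times the template: backward
# bilinear sampling along the displacement field, then local gain.
warp_frame <- function(base, template, amplitude) {
  if (amplitude == 0) return(base)
  h <- nrow(base); w <- ncol(base)
  yi <- rep(seq_len(h), times = w) - amplitude * as.vector(template$dy)
  xi <- rep(seq_len(w), each = h) - amplitude * as.vector(template$dx)
  out <- bilinear_sample(base, yi, xi)
  out * (1 + amplitude * template$gain)
}

# Base speckle texture for one dataset (drawn from the "speckle" substream).
make_base_speckle <- function(cfg) {
  with_substream(cfg$seed, "speckle", 0L, {
    f <- random_smooth_field(cfg$frame_height, cfg$frame_width,
                             cfg$speckle_smoothness)
    pmin(pmax(0.5 + 0.12 * f, 0), 1)
  })
}

#' Generate a synthetic cued-motion dataset
#'
#' Simulates one full data-collection dataset: for every motion class and
#' repetition, a 4-second cue cycle of frames at `frame_rate` fps -- one
#' second each of move (deformation ramping up), hold (full deformation),
#' return (ramping down) and rest. Hold frames are the base speckle warped
#' by the class template (perturbed per repetition) plus frame noise; rest
#' frames are base speckle plus noise and carry motion label `"rest"`.
#' Intensities are clipped to `[0, 1]` after noise.
#'
#' The output is bit-for-bit reproducible from the configuration: all
#' random draws come from substreams keyed on `cfg$seed`.
#'
#' @param cfg an [image_gen_config()].
#' @param subject,session,phase metadata labels stored with every frame.
#' @return an [smg_dataset()] with
#'   `n_classes * n_repetitions * 4 * frame_rate` frames.
#' @examples
#' cfg <- image_gen_config(n_classes = 2, n_repetitions = 2,
#'                         frame_height = 20, frame_width = 28,
#'                         frame_rate = 4, seed = 7)
#' d <- generate_dataset(cfg)
#' table(d$info$role)
#' @export
generate_dataset <- function(cfg, subject = "S1", session = 1L,
                             phase = "none") {
  stopifnot(inherits(cfg, "smg_image_config"))
  base <- make_base_speckle(cfg)
  templates <- lapply(seq_len(cfg$n_classes),
                      function(j) make_class_template(cfg, j))
  fr <- cfg$frame_rate
  h <- cfg$frame_height; w <- cfg$frame_width
  n_cycle <- 4L * fr
  n_total <- cfg$n_classes * cfg$n_repetitions * n_cycle
  frames <- array(0, dim = c(h, w, n_total))
  info <- vector("list", cfg$n_classes * cfg$n_repetitions)
  # amplitude profile over one cue cycle (move ramp, hold, return ramp, rest)
  profile <- c(seq_len(fr) / fr, rep(1, fr), 1 - seq_len(fr) / fr, rep(0, fr))
  roles <- rep(c("move", "hold", "return", "rest"), each = fr)
  pos <- 0L
  for (j in seq_len(cfg$n_classes)) {
    for (r in seq_len(cfg$n_repetitions)) {
      k <- (j - 1L) * cfg$n_repetitions + r
      cycle <- with_substream(cfg$seed, "repetition", k, {
        amp <- 1 + stats::rnorm(1L, 0, cfg$rep_jitter)
        off <- stats::rnorm(2L, 0, cfg$rep_jitter * 4) # pixels
        tpl <- templates[[j]]
        if (any(off != 0)) {
          tpl <- structure(list(dx = shift_field(tpl$dx, off[1L], off[2L]),
                                dy = shift_field(tpl$dy, off[1L], off[2L]),
                                gain = shift_field(tpl$gain, off[1L], off[2L])),
                           class = "smg_template")
        }
        out <- array(0, dim = c(h, w, n_cycle))
        for (t in seq_len(n_cycle)) {
          fimg <- warp_frame(base, tpl, amp * profile[t])
          if (cfg$frame_noise > 0) {
            fimg <- fimg + matrix(stats::rnorm(h * w, 0, cfg$frame_noise), h, w)
          }
          out[, , t] <- pmin(pmax(fimg, 0), 1)
        }
        out
      })
      frames[, , pos + seq_len(n_cycle)] <- cycle
      info[[k]] <- data.frame(
        subject = subject, session = session, phase = phase,
        motion = ifelse(roles == "rest", "rest", sprintf("motion%d", j)),
        repetition = r, role = roles,
        frame_index = pos + seq_len(n_cycle),
        stringsAsFactors = FALSE
      )
      pos <- pos + n_cycle
    }
  }
  smg_dataset(frames, do.call(rbind, info))
}
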