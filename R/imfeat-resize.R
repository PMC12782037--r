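#' Resize a frame under the global-aspect-ratio convention
#'
#' All frames of a dataset are scaled by the *same* factor
#' `s = T / G`, where `G` is the maximum pixel dimension over the whole
#' dataset (see [compute_global_max_dim()]). This preserves the size
#' ratios between specimens, which carry the biomass signal: an object
#' twice as long in the raw frames stays twice as long in every network
#' input. The scaled content is centered on a `T x T` canvas and padded
#' with pixels sampled at random from the frame's own border, so padding
#' matches the background statistics.
#'
#' @param frame frame list from [render_frames()] or numeric matrix.
#' @param G global maximum dimension (px); must be at least the frame's
#'   own larger dimension.
#' @param T_px target side length (px).
#' @param seed integer seed for the border-pixel sampling.
#' @return `T_px x T_px` numeric matrix.
#' @export
resize_with_global_aspect <- function(frame, G, T_px = 224, seed = 1) {
  px <- if (is.list(frame)) frame$pixels else frame
  h <- nrow(px); w <- ncol(px)
  if (G < max(h, w)) {
    abort_invalid("global max dim G = ", G, " is smaller than the frame's ",
                  "own max dimension ", max(h, w))
  }
  stopifnot(T_px >= 1)
  s <- T_px / G
  out_h <- max(1L, round(h * s)); out_w <- max(1L, round(w * s))
  # area-average (box-filter) resampling: preserves the energy of
  # thin structures (legs, cerci) that plain decimation would drop
  content <- box_resize_matrix(h, out_h) %*% px %*%
    t(box_resize_matrix(w, out_w))

  border <- c(px[1, ], px[h, ], px[, 1], px[, w])
  canvas <- with_substream(seed, "pad", {
    matrix(sample(border, T_px * T_px, replace = TRUE), T_px, T_px)
  })
  off_i <- (T_px - out_h) %/% 2L
  off_j <- (T_px - out_w) %/% 2L
  canvas[off_i + seq_len(out_h), off_j + seq_len(out_w)] <- content
  canvas
}

# n_out x n_in row-normalized box-overlap weights: output pixel i
# averages the source interval [(i-1) * n_in / n_out, i * n_in / n_out]
box_resize_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    u <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
    ov <- pmin(hi, u + 1) - pmax(lo, u)
    keep <- ov > 1e-12
    A[i, u[keep] + 1] <- ov[keep] / r
  }
  A
}
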