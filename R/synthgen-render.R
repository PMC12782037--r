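#' Render two-view silhouette frames for one specimen
#'
#' Emulates a two-camera specimen imaging device: frames are split
#' between two perpendicular cameras, each frame shows the specimen at a
#' random in-plane rotation, and camera 1 sees the body width compressed
#' by the specimen's dorsoventral factor (perpendicular views differ in
#' projection, not content). The silhouette is an ellipse body with a
#' tapered abdomen, optional appendage pairs and an optional rectangular
#' case; its major-axis extent equals `length_mm * px_per_mm` within
#' about 2 px of rasterization error. With probability `junk_rate` a
#' frame is replaced by a small non-target blob (bubble/debris
#' analogue), flagged in the frame metadata.
#'
#' @param specimen one-row data.frame from [generate_specimens()].
#' @param n_frames number of frames (>= 1), alternating cameras.
#' @param img_size integer `c(height, width)` in px.
#' @param px_per_mm pixel calibration (> 0).
#' @param junk_rate probability a frame is a non-target blob.
#' @param seed integer seed.
#' @return list of frames; each frame is a list with `pixels` (numeric
#'   matrix in `[0, 1]`, row-major, origin top-left), `specimen_id`,
#'   `camera_id` (0/1), `frame_index`, `px_per_mm`, `nontarget`
#'   (ground-truth junk flag).
#' @export
render_frames <- function(specimen, n_frames, img_size = c(80, 80),
                          px_per_mm = 3, junk_rate = 0, seed = 1) {
  stopifnot(n_frames >= 1, px_per_mm > 0)
  h <- img_size[1]; w <- img_size[2]
  diam_px <- specimen$length_mm * px_per_mm
  if (diam_px + 4 > min(h, w)) {
    abort_invalid(
      "specimen ", specimen$specimen_id, " (length ", round(specimen$length_mm, 2),
      " mm) needs a frame of at least ", ceiling(diam_px + 4),
      " px at ", px_per_mm, " px/mm; got ", h, "x", w
    )
  }
  with_substream(seed, paste0("frames:", specimen$specimen_id), {
    lapply(seq_len(n_frames), function(k) {
      cam <- (k - 1L) %% 2L
      junk <- stats::runif(1) < junk_rate
      mask <- if (junk) {
        junk_blob_mask(h, w)
      } else {
        silhouette_mask(specimen, h, w, px_per_mm, camera_id = cam)
      }
      px <- matrix(0.08 + stats::rnorm(h * w, 0, 0.02), h, w)
      px[mask] <- 0.85 + stats::rnorm(sum(mask), 0, 0.03)
      px <- pmin(pmax(px, 0), 1)
      list(
        pixels = px, specimen_id = specimen$specimen_id,
        camera_id = cam, frame_index = k, px_per_mm = px_per_mm,
        nontarget = junk
      )
    })
  })
}

# Rasterize the parametric silhouette at a random rotation and small
# random offset. Consumes RNG; callers manage the stream.
silhouette_mask <- function(specimen, h, w, px_per_mm, camera_id = 0) {
  a <- specimen$length_mm * px_per_mm / 2          # semi-major axis (px)
  b <- a / specimen$elongation                     # semi-minor axis (px)
  if (camera_id == 0) b <- max(b * specimen$dorso_factor, 0.6)
  theta <- stats::runif(1, 0, pi)
  slack <- (min(h, w) - 2 * a - 4) / 2
  cy <- (h + 1) / 2 + stats::runif(1, -1, 1) * max(slack / 2, 0)
  cx <- (w + 1) / 2 + stats::runif(1, -1, 1) * max(slack / 2, 0)

  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), w), h, w) - cy
  u <- xs * cos(theta) + ys * sin(theta)           # along body axis
  v <- -xs * sin(theta) + ys * cos(theta)          # across body axis

  # body: ellipse for the head half, linearly tapered abdomen aft
  half_w <- ifelse(
    u <= 0,
    b * sqrt(pmax(1 - (u / a)^2, 0)),
    b * sqrt(pmax(1 - (u / a)^2, 0)) * (1 - specimen$taper * u / a)
  )
  mask <- abs(u) <= a & abs(v) <= half_w
  # small circular caps at head and tail pin the rasterized major-axis
  # extent to L * px_per_mm even where the profile tapers to a point
  mask <- mask | ((u - (a - 0.6))^2 + v^2 <= 0.8^2) |
    ((u + (a - 0.6))^2 + v^2 <= 0.8^2)

  # appendage pairs: thin bars across the body, kept inside the central
  # 90% of the length so they never extend the maximum Feret diameter
  n_app <- specimen$n_appendages
  if (n_app > 0) {
    reach <- b + specimen$appendage_len * a
    reach <- min(reach, 0.62 * a)
    upos <- seq(-0.42, 0.42, length.out = max(n_app, 2))[seq_len(n_app)] * a
    bar_w <- max(0.08 * a, 1.3)
    for (uj in upos) {
      mask <- mask | (abs(u - uj) <= bar_w & abs(v) <= reach)
    }
  }

  if (isTRUE(specimen$cased)) {
    # species-specific case geometry (length fraction and aspect);
    # width capped so the case never extends the maximum Feret extent
    clf <- specimen$case_len_frac %||% 0.72
    asp <- specimen$case_aspect %||% 3
    cl <- clf * a
    cw <- min(cl / asp, 0.43 * a)
    mask <- mask | (abs(u) <= cl & abs(v) <= cw)
  }
  mask
}

junk_blob_mask <- function(h, w) {
  r <- stats::runif(1, 0.012, 0.028) * min(h, w)
  cy <- stats::runif(1, r + 2, h - r - 2)
  cx <- stats::runif(1, r + 2, w - r - 2)
  ecc <- stats::runif(1, 0.5, 1)
  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), w), h, w) - cy
  (xs / r)^2 + (ys / (r * ecc))^2 <= 1
}
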