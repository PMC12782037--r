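#' Morphometric features of a binary mask
#'
#' The three features the imaging device exports, with fixed, documented
#' pixel conventions (conventions differ by more than 10% between image
#' libraries, so they are pinned here):
#' * `area()`: foreground pixel count / `px_per_mm`^2.
#' * `max_feret()`: maximum Euclidean distance between the *centers* of
#'   any two foreground boundary pixels (computed via the convex hull,
#'   equal to the brute-force pairwise maximum).
#' * `perimeter()`: length of the Moore-traced outer boundary polygon of
#'   the mask (unit steps between 4-neighbors, sqrt(2) for diagonals).
#'   A single-pixel mask has perimeter 0 under this convention
#'   (degenerate polygon).
#'
#' @param mask logical matrix (TRUE = foreground), non-empty.
#' @param px_per_mm pixel calibration (> 0).
#' @return numeric scalar in mm^2 (`area`) or mm (`max_feret`,
#'   `perimeter`).
#' @name morphometrics
NULL

#' @rdname morphometrics
#' @export
area <- function(mask, px_per_mm = 1) {
  check_mask(mask)
  sum(mask) / px_per_mm^2
}

#' @rdname morphometrics
#' @export
max_feret <- function(mask, px_per_mm = 1) {
  check_mask(mask)
  bp <- boundary_pixels(mask)
  if (nrow(bp) == 1) return(0)
  hull <- bp[grDevices::chull(bp[, 2], bp[, 1]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2)) / px_per_mm
}

#' @rdname morphometrics
#' @export
perimeter <- function(mask, px_per_mm = 1) {
  check_mask(mask)
  comp <- largest_component(mask)
  trace_moore_length(comp) / px_per_mm
}

check_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) abort_invalid("empty mask: no foreground pixels")
  invisible(TRUE)
}

# Moore-neighbor boundary tracing; returns the traced closed-polygon
# length in px (0 for an isolated pixel). The walk is deterministic in
# the (pixel, backtrack) state, so the boundary cycle is the orbit of
# the state reached after the first advance; we sum step lengths around
# that cycle exactly once.
trace_moore_length <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  at <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  # clockwise from North, in (row, col) screen coordinates
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  dir_index <- matrix(NA_integer_, 3, 3)
  for (k in 1:8) dir_index[dirs[k, 1] + 2, dirs[k, 2] + 2] <- k

  advance <- function(p, b) {
    start_dir <- dir_index[b[1] - p[1] + 2, b[2] - p[2] + 2]
    prev_pos <- b
    for (k in 0:7) {
      d <- dirs[(start_dir - 1 + k) %% 8 + 1, ]
      q <- p + d
      if (at(q[1], q[2])) {
        return(list(p = q, b = prev_pos, step = sqrt(sum((q - p)^2))))
      }
      prev_pos <- q
    }
    NULL                              # no foreground neighbor
  }

  rows <- which(mask, arr.ind = TRUE)
  r0 <- min(rows[, 1])
  c0 <- min(rows[rows[, 1] == r0, 2])
  s <- c(r0, c0)
  b0 <- c(r0 - 1, c0)                 # north of start: background
  first <- advance(s, b0)
  if (is.null(first)) return(0)       # isolated pixel
  anchor <- first
  p <- first$p; b <- first$b
  total <- 0
  max_iter <- 8L * sum(mask) + 8L
  for (iter in seq_len(max_iter)) {
    nxt <- advance(p, b)
    total <- total + nxt$step
    p <- nxt$p; b <- nxt$b
    if (all(p == anchor$p) && all(b == anchor$b)) return(total)
  }
  total
}

# convex hull area of boundary pixel centers (px^2, shoelace)
hull_area_px <- function(mask) {
  bp <- boundary_pixels(mask)
  if (nrow(bp) < 3) return(0)
  hull <- bp[grDevices::chull(bp[, 2], bp[, 1]), , drop = FALSE]
  x <- hull[, 2]; y <- hull[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Compute per-frame features for a set of frames
#'
#' Segments each frame and computes area, maximum Feret diameter,
#' perimeter and solidity (area / convex-hull area of the mask, both in
#' px). Frames whose segmentation is empty get NA features and an
#' immediate non-target flag.
#'
#' @param frames list of frames from [render_frames()].
#' @param threshold passed to [segment()].
#' @return data.frame: specimen_id, camera_id, frame_index, area_mm2,
#'   mfd_mm, perimeter_mm, solidity, nontarget_flag.
#' @export
compute_features <- function(frames, threshold = "auto") {
  rows <- lapply(frames, function(fr) {
    ppm <- fr$px_per_mm
    mask <- tryCatch(segment(fr, threshold), error = function(e) NULL)
    if (is.null(mask)) {
      return(data.frame(
        specimen_id = fr$specimen_id, camera_id = fr$camera_id,
        frame_index = fr$frame_index, area_mm2 = NA_real_,
        mfd_mm = NA_real_, perimeter_mm = NA_real_, solidity = NA_real_,
        nontarget_flag = TRUE, stringsAsFactors = FALSE
      ))
    }
    npix <- sum(mask)
    ha <- hull_area_px(mask)
    data.frame(
      specimen_id = fr$specimen_id, camera_id = fr$camera_id,
      frame_index = fr$frame_index,
      area_mm2 = npix / ppm^2,
      mfd_mm = max_feret(mask, ppm),
      perimeter_mm = perimeter(mask, ppm),
      solidity = if (ha > 0) npix / ha else Inf,
      nontarget_flag = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag frames whose features look like non-target objects
#'
#' Automated stand-in for the manual removal of frames showing bubbles,
#' forceps or debris: frames with area outside `area_bounds` (mm^2) or
#' solidity outside `solidity_bounds` are flagged. Nothing is deleted;
#' downstream stages simply skip flagged frames.
#'
#' @param features data.frame from [compute_features()].
#' @param area_bounds numeric `c(min, max)` in mm^2.
#' @param solidity_bounds numeric `c(min, max)`.
#' @return the features data.frame with `nontarget_flag` updated.
#' @export
flag_nontarget <- function(features, area_bounds = c(0, Inf),
                           solidity_bounds = c(0, Inf)) {
  bad <- is.na(features$area_mm2) |
    features$area_mm2 < area_bounds[1] | features$area_mm2 > area_bounds[2] |
    features$solidity < solidity_bounds[1] |
    features$solidity > solidity_bounds[2]
  features$nontarget_flag <- features$nontarget_flag | bad
  features
}
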