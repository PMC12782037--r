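#' Segment a frame into a single-specimen binary mask
#'
#' Thresholds the grayscale frame (automatic bimodal Otsu threshold by
#' default, or a fixed numeric threshold) and keeps only the largest
#' 8-connected foreground component; smaller components (bubbles,
#' debris) are discarded under the single-specimen cuvette assumption.
#'
#' @param frame a frame list from [render_frames()] or a plain numeric
#'   matrix in `[0, 1]`.
#' @param threshold `"auto"` for Otsu's method, or a numeric cut; pixels
#'   strictly above the cut are foreground.
#' @return logical matrix of the same dimensions (TRUE = specimen).
#' @export
segment <- function(frame, threshold = "auto") {
  px <- if (is.list(frame)) frame$pixels else frame
  stopifnot(is.matrix(px))
  cut <- if (identical(threshold, "auto")) {
    EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  fg <- px > cut
  if (!any(fg)) {
    id <- if (is.list(frame)) {
      paste0(frame$specimen_id, " cam", frame$camera_id,
             " frame", frame$frame_index)
    } else {
      "matrix input"
    }
    abort_invalid("empty foreground after thresholding (", id, ")")
  }
  largest_component(fg)
}

# label 8-connected components and keep the largest
largest_component <- function(fg) {
  lab <- label_components_8(fg)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# 8-connected labelling: 4-connected labelling from EBImage::bwlabel,
# then union of label pairs that touch diagonally
label_components_8 <- function(fg) {
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  n <- max(lab)
  if (n <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

# boundary pixels: foreground with at least one background (or
# out-of-image) pixel in the 8-neighborhood
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  all_nb <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    all_nb <- all_nb & padded[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  }
  which(mask & !all_nb, arr.ind = TRUE)
}
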