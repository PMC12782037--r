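# Plain-file interfaces between pipeline stages. Every table has a
# header row; frames are 8-bit grayscale PNG, one file per frame, under
# frames/{specimen_id}/{camera_id}_{frame_index}.png.

#' Write rendered frames as PNG files
#'
#' @param frames list of frames from [render_frames()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_frames_png <- function(frames, dir) {
  paths <- vapply(frames, function(fr) {
    d <- file.path(dir, fr$specimen_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, sprintf("%d_%03d.png", fr$camera_id, fr$frame_index))
    png::writePNG(fr$pixels, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read frames back from a PNG directory
#'
#' Inverse of [write_frames_png()]. The non-target truth flag is not
#' recoverable from pixels and is set to NA.
#'
#' @param dir directory written by [write_frames_png()].
#' @param px_per_mm calibration to attach to each frame.
#' @return list of frames.
#' @export
read_frames_png <- function(dir, px_per_mm) {
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) abort_invalid("no PNG frames under ", dir)
  lapply(sort(files), function(p) {
    parts <- strsplit(basename(p), "[_.]")[[1]]
    px <- png::readPNG(p)
    if (length(dim(px)) == 3) px <- px[, , 1]
    list(pixels = px, specimen_id = basename(dirname(p)),
         camera_id = as.integer(parts[1]),
         frame_index = as.integer(parts[2]),
         px_per_mm = px_per_mm, nontarget = NA)
  })
}

write_table_csv <- function(df, path, sep = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_csv <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop(structure(class = c("mm_dependency_error", "error", "condition"),
                   list(message = paste0("missing artifact: ", path),
                        call = NULL)))
  }
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
}

write_json_file <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
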