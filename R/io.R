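#' Write a frame sequence to a directory of PNG files
#'
#' Frames are written as zero-padded `frame_000000.png` (0-based indices),
#' with `ground_truth.json` alongside when truth is supplied.
#'
#' @param video list with `frames` (a `frame_sequence`) and optionally
#'   `truth`, as returned by [generate_video()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_video <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(video$frames)
  paths <- character(n)
  for (i in seq_len(n) - 1L) {
    fr <- video$frames$get(i)
    paths[i + 1L] <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(fr / 255, paths[i + 1L])
  }
  if (!is.null(video$truth))
    jsonlite::write_json(video$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  invisible(paths)
}

#' Read a directory of PNG frames as a lazy frame sequence
#'
#' Files are taken in lexical order (zero-padded names sort correctly);
#' each frame is decoded only when requested.
#'
#' @param dir directory containing `*.png` frames.
#' @return a `frame_sequence`.
#' @export
read_video <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames in ", dir, call. = FALSE)
  frame_sequence(function(i) {
    img <- png::readPNG(files[i + 1L])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE] * 255
  }, length(files))
}
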