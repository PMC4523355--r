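#' Check that a video directory contains only supported inputs
#'
#' Scans a directory (non-recursively) and reports every entry that the
#' package cannot process. Accepted inputs are `.avi` files and
#' subdirectories holding numbered PNG/TIFF image sequences. `.cxd`
#' (Hamamatsu) files are recognized as a microscopy video format but are not
#' decodable here (they require the ImageJ BIO-formats route); they are
#' reported as non-conforming, with a note, to aid migration.
#'
#' @param directory path to the folder holding the raw videos.
#' @return character vector of non-conforming file names (empty if all
#'   conform). Recognized-but-unsupported `.cxd` names are additionally
#'   listed in the `"recognized_unsupported"` attribute.
#' @examples
#' d <- tempfile(); dir.create(d)
#' file.create(file.path(d, c("a.avi", "notes.txt")))
#' check_video_file_names(d)
#' @export
check_video_file_names <- function(directory) {
  if (!dir.exists(directory)) {
    stop(sprintf("directory does not exist: '%s'", directory), call. = FALSE)
  }
  entries <- list.files(directory, all.files = FALSE)
  if (!length(entries)) return(character(0))
  full <- file.path(directory, entries)
  is_dir <- dir.exists(full)
  ext <- tolower(tools::file_ext(entries))
  conforming <- is_dir | ext == "avi"
  bad <- entries[!conforming]
  cxd <- bad[tolower(tools::file_ext(bad)) == "cxd"]
  if (length(cxd)) {
    message("recognized but unsupported format (.cxd requires BIO-formats): ",
            paste(cxd, collapse = ", "))
  }
  structure(bad, recognized_unsupported = cxd)
}

seq_file_pattern <- "^(.*)_([0-9]+)\\.(png|tif|tiff)$"

# 8-bit luminance from a decoded png/tiff array in [0,1].
to_grey8 <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      img[, , 1L]
    }
  }
  m <- round(img * 255)
  m[m < 0] <- 0; m[m > 255] <- 255
  m
}

#' Load a video as a frame stack
#'
#' Reads a directory of numbered PNG/TIFF frames (`<stem>_<number>.<ext>`,
#' sorted by the numeric suffix) into a [frame_stack()]. Colour frames are
#' converted to 8-bit grayscale with the standard luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); for monochrome dark-field material the
#' conversion is a pass-through. At least two frames are required because
#' difference segmentation needs an offset partner for every analyzed frame.
#'
#' `.avi` files cannot be decoded by this implementation (no video decoder
#' backend); convert them to a PNG/TIFF sequence first (e.g.
#' `ffmpeg -i in.avi frames/in_%05d.png`).
#'
#' @param path directory containing the numbered image sequence.
#' @param fps frames per second of the recording (Hz).
#' @param scale micrometres per pixel.
#' @return a [frame_stack()] named after the directory (or file stem).
#' @seealso [save_frames()]
#' @export
load_frames <- function(path, fps, scale) {
  stop_if_not_scalar_number(fps, "fps")
  stop_if_not_scalar_number(scale, "scale")
  if (dir.exists(path)) {
    files <- list.files(path)
    hit <- grepl(seq_file_pattern, files, ignore.case = TRUE)
    files <- files[hit]
    if (length(files) < 2L) {
      stop(sprintf(
        "image sequence at '%s' has %d matching frame file(s); at least 2 are required",
        path, length(files)), call. = FALSE)
    }
    idx <- as.integer(sub(seq_file_pattern, "\\2", files, ignore.case = TRUE))
    files <- files[order(idx)]
    frames <- lapply(file.path(path, files), function(f) {
      e <- tolower(tools::file_ext(f))
      img <- if (e == "png") png::readPNG(f) else tiff::readTIFF(f)
      to_grey8(img)
    })
    return(frame_stack(frames, fps = fps, scale = scale,
                       source_name = basename(path)))
  }
  if (!file.exists(path)) {
    stop(sprintf("video source does not exist: '%s'", path), call. = FALSE)
  }
  if (tolower(tools::file_ext(path)) == "avi") {
    stop(sprintf(paste0(
      "'%s': AVI decoding is not available in this implementation; ",
      "convert the video to a numbered PNG/TIFF sequence first ",
      "(e.g. ffmpeg -i video.avi frames/video_%%05d.png)"), path),
      call. = FALSE)
  }
  stop(sprintf("unsupported video source: '%s'", path), call. = FALSE)
}

#' Write a frame stack to disk
#'
#' `png_sequence` writes one 8-bit grayscale PNG per frame, named
#' `<source_name>_<frame>.png` with a zero-padded 0-based frame number, so
#' that [load_frames()] round-trips the stack bit-exactly. AVI output is not
#' supported (no encoder backend); use the PNG sequence.
#'
#' @param stack a [frame_stack()].
#' @param path output directory (created if absent).
#' @param format `"png_sequence"` (the only supported encoder).
#' @return invisibly, the vector of files written.
#' @export
save_frames <- function(stack, path, format = c("png_sequence", "avi")) {
  stopifnot(inherits(stack, "frame_stack"))
  format <- match.arg(format)
  if (format == "avi") {
    stop("AVI encoding is not available; use format = \"png_sequence\"",
         call. = FALSE)
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  }
  nf <- n_frames(stack)
  width <- max(5L, nchar(as.character(nf - 1L)))
  out <- character(nf)
  for (t in seq_len(nf)) {
    out[t] <- file.path(path, sprintf("%s_%0*d.png", stack$source_name,
                                      width, t - 1L))
    png::writePNG(stack$frames[, , t] / 255, out[t])
  }
  invisible(out)
}
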