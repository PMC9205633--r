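#' In-memory miniscope video with named axes
#'
#' A `video_array` is a 3-D non-negative numeric array with axes
#' `(frame, height, width)`, the `Y` of the factorization model
#' `Y = AC + bf' + E`.  Axis coordinates are 0-based integers; the frame
#' coordinate is strictly increasing.  The acquisition rate (`fps`) and the
#' execution chunk plan travel with the array as attributes.
#'
#' @param data 3-D numeric array indexed `(frame, height, width)`; all values
#'   must be non-negative.
#' @param fps frames per second (default 30).
#' @param coords optional list with integer vectors `frame`, `height`,
#'   `width` (0-based axis coordinates).  Defaults to `0:(n-1)` per axis.
#' @param chunks optional integer vector of per-axis chunk sizes used by
#'   chunk-wise stages and by [persist_array()].
#' @return an object of class `video_array`.
#' @export
video_array <- function(data, fps = 30, coords = NULL, chunks = NULL) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (frame, height, width)")
  if (any(data < 0)) stop("video values must be non-negative")
  storage.mode(data) <- "double"
  d <- dim(data)
  if (is.null(coords)) {
    coords <- list(frame = seq_len(d[1]) - 1L,
                   height = seq_len(d[2]) - 1L,
                   width = seq_len(d[3]) - 1L)
  }
  stopifnot(lengths(coords) == d)
  if (is.unsorted(coords$frame, strictly = TRUE))
    stop("frame coordinate must be strictly increasing")
  if (is.null(chunks)) chunks <- d
  structure(data, class = c("video_array", "array"),
            fps = fps, coords = coords, chunks = as.integer(pmin(chunks, d)))
}

#' @export
print.video_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_array> %d frames x %d x %d px, %g fps, chunks [%s]\n",
              d[1], d[2], d[3], attr(x, "fps"),
              paste(attr(x, "chunks"), collapse = ", ")))
  invisible(x)
}

# strip class/attrs -> plain array
va_data <- function(v) {
  attributes(v) <- list(dim = dim(v))
  v
}

# rebuild a video_array reusing metadata from a parent
va_like <- function(data, parent, coords = NULL) {
  video_array(data, fps = attr(parent, "fps"),
              coords = coords %||% attr(parent, "coords"),
              chunks = attr(parent, "chunks"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# video as (frame x pixel) matrix; pixel index runs height-fastest
va_matrix <- function(v) {
  d <- dim(v)
  x <- va_data(v)
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

# frame-block index sets according to the chunk plan
chunk_starts <- function(n, size) {
  if (size >= n) return(list(seq_len(n)))
  lapply(seq(1L, n, by = size), function(s) s:min(s + size - 1L, n))
}

#' Pixel crop mask
#'
#' Half-open row/column pixel intervals `[start, stop)` in 0-based frame
#' coordinates, used to restrict processing to a sub-region.
#'
#' @param rows,cols length-2 integer vectors `c(start, stop)`, half-open,
#'   0-based.
#' @return an object of class `crop_mask`.
#' @export
crop_mask <- function(rows, cols) {
  stopifnot(length(rows) == 2, length(cols) == 2)
  if (rows[2] <= rows[1] || cols[2] <= cols[1])
    stop("bounds error: stop must exceed start")
  if (rows[1] < 0 || cols[1] < 0) stop("bounds error: negative start")
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "crop_mask")
}

#' Subset a video by frame interval and pixel mask
#'
#' Pure slicing: no value changes.  The frame coordinates of the retained
#' frames are preserved, so a subset of frames `[10, 20)` of a video keeps
#' frame coordinates `10..19`.
#'
#' @param video a [video_array()].
#' @param frames length-2 vector `c(start, stop)`: half-open interval in the
#'   0-based frame coordinate, or `NULL` to keep all frames.
#' @param mask a [crop_mask()] or `NULL` to keep the full field of view.
#' @return a `video_array`.
#' @export
subset_video <- function(video, frames = NULL, mask = NULL) {
  d <- dim(video)
  co <- attr(video, "coords")
  fi <- seq_len(d[1])
  if (!is.null(frames)) {
    if (frames[1] < 0 || frames[2] > max(co$frame) + 1 || frames[2] <= frames[1])
      stop("bounds error: frame interval out of range")
    fi <- which(co$frame >= frames[1] & co$frame < frames[2])
    if (length(fi) == 0) stop("bounds error: empty frame selection")
  }
  ri <- seq_len(d[2]); ci <- seq_len(d[3])
  if (!is.null(mask)) {
    if (mask$rows[2] > d[2] || mask$cols[2] > d[3])
      stop("bounds error: mask exceeds frame bounds")
    ri <- (mask$rows[1] + 1L):mask$rows[2]
    ci <- (mask$cols[1] + 1L):mask$cols[2]
  }
  out <- va_data(video)[fi, ri, ci, drop = FALSE]
  video_array(out, fps = attr(video, "fps"),
              coords = list(frame = co$frame[fi], height = co$height[ri],
                            width = co$width[ci]))
}

#' Change the execution chunk plan of an array
#'
#' Only the chunk sizes used by chunk-wise stages (and by the on-disk store)
#' change; values are untouched.  Every pipeline stage is required to return
#' identical results (within 1e-6) under any chunk plan.
#'
#' @param video a [video_array()].
#' @param chunks integer vector of per-axis chunk sizes (length 3), each >= 1.
#' @return the same video with an updated plan.
#' @export
rechunk <- function(video, chunks) {
  stopifnot(length(chunks) == 3, all(chunks >= 1))
  attr(video, "chunks") <- as.integer(pmin(chunks, dim(video)))
  video
}

natural_order <- function(x) {
  # order msCam1, msCam2, ..., msCam10 numerically within text runs
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  nmax <- max(lengths(toks))
  keys <- lapply(seq_len(nmax), function(i) {
    tk <- vapply(toks, function(t) if (i <= length(t)) t[i] else "", "")
    num <- suppressWarnings(as.numeric(tk))
    if (all(!is.na(num) | tk == "")) ifelse(is.na(num), -Inf, num) else tk
  })
  do.call(order, keys)
}

read_stack_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]  # RGB: take channel 0
      p
    })
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  } else {
    stop(sprintf("format error: unsupported container '.%s'", ext))
  }
}

#' Load a session's videos from disk
#'
#' Reads all multi-page TIFF stacks matching `pattern` under `path`, in
#' natural filename order (`msCam1, msCam2, ..., msCam10`), concatenates the
#' frames, and optionally downsamples each axis either by subsetting on a
#' regular interval or by averaging each interval.  Values are promoted to
#' 32/64-bit floating point but kept on the raw 0-255 scale.
#'
#' @param path directory containing the session's files.
#' @param pattern filename glob (default `"*.tif*"`).
#' @param downsample named list of per-axis integer factors, e.g.
#'   `list(frame = 2)`; axes not named are untouched.
#' @param strategy `"subset"` (stride) or `"mean"` (interval average; a
#'   trailing interval shorter than the factor is dropped).
#' @param fps frames per second of the recording after downsampling is
#'   accounted for internally; give the acquisition rate.
#' @return a [video_array()].
#' @export
load_videos <- function(path, pattern = "*.tif*",
                        downsample = list(), strategy = c("subset", "mean"),
                        fps = 30) {
  strategy <- match.arg(strategy)
  files <- Sys.glob(file.path(path, pattern))
  if (length(files) == 0) stop("empty input: no file matches pattern")
  files <- files[natural_order(basename(files))]
  parts <- lapply(files, read_stack_file)
  hw <- lapply(parts, function(p) dim(p)[2:3])
  if (length(unique(hw)) != 1) stop("shape mismatch across files")
  arr <- do.call(abind_frames, parts)
  eff_fps <- fps
  for (ax in names(downsample)) {
    f <- as.integer(downsample[[ax]])
    if (f <= 1) next
    dimi <- match(ax, c("frame", "height", "width"))
    if (is.na(dimi)) stop("unknown downsample axis: ", ax)
    arr <- downsample_axis(arr, dimi, f, strategy)
    if (dimi == 1) eff_fps <- fps / f
  }
  video_array(arr, fps = eff_fps)
}

abind_frames <- function(...) {
  parts <- list(...)
  nf <- vapply(parts, function(p) dim(p)[1], 0)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(nf), d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

downsample_axis <- function(arr, axis, f, strategy) {
  n <- dim(arr)[axis]
  if (strategy == "subset") {
    idx <- seq(1L, n, by = f)
    index_axis(arr, axis, idx)
  } else {
    nblk <- n %/% f  # trailing remainder dropped
    if (nblk == 0) stop("downsample factor exceeds axis length")
    pieces <- lapply(seq_len(f), function(o) {
      index_axis(arr, axis, seq(o, by = f, length.out = nblk))
    })
    Reduce(`+`, pieces) / f
  }
}

index_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
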