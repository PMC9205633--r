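#' Vignetting correction by temporal-minimum subtraction
#'
#' Single-photon miniscope optics make the centre of the field brighter than
#' the periphery.  The static part of that profile is estimated as the
#' per-pixel minimum over time and subtracted from every frame, which keeps
#' the video on its raw linear intensity scale and leaves a per-pixel
#' temporal minimum of exactly zero.  The operation is idempotent.
#'
#' @param video a [video_array()].
#' @return a `video_array` of the same shape.
#' @export
remove_vignette <- function(video) {
  d <- dim(video)
  mat <- va_matrix(video)
  blocks <- chunk_starts(ncol(mat), px_chunk(video))
  for (b in blocks) {
    mn <- .colMins(mat[, b, drop = FALSE], nrow(mat), length(b))
    mat[, b] <- mat[, b, drop = FALSE] - rep(mn, each = nrow(mat))
  }
  dim(mat) <- d
  va_like(mat, video)
}

.colMins <- function(m, nr, nc) apply(m, 2, min)

# pixel-block size implied by the chunk plan (height*width granularity)
px_chunk <- function(video) {
  ch <- attr(video, "chunks")
  max(1L, ch[2] * ch[3])
}

#' Median-filter denoising
#'
#' Removes salt-and-pepper sensor noise by passing each frame through a 2-D
#' median filter (square window, reflected boundaries).  The window side
#' should be about the average cell radius in pixels; larger windows start
#' to blend adjacent cells.
#'
#' @param video a [video_array()].
#' @param method only `"median"` is implemented.
#' @param wnd odd window side in pixels (default 11).
#' @return a `video_array` of the same shape.
#' @export
denoise <- function(video, method = "median", wnd = 11) {
  method <- match.arg(method, "median")
  if (wnd %% 2 == 0) stop("window must be odd")
  d <- dim(video)
  out <- va_data(video)
  if (wnd > 1) {
    for (blk in chunk_starts(d[1], attr(video, "chunks")[1])) {
      for (t in blk) out[t, , ] <- cpp_median_filter(out[t, , ], wnd)
    }
  }
  va_like(out, video)
}

# EBImage grayscale morphology clips intensities to [0, 1]; rescale around
# it (morphological opening commutes with positive scaling)
opening_gray <- function(frame, kern) {
  m <- max(frame)
  if (m <= 0) return(frame)
  EBImage::opening(frame / m, kern) * m
}

dilate_gray <- function(frame, kern) {
  m <- max(abs(frame)) 
  if (m <= 0) return(frame)
  EBImage::dilate(frame / m, kern) * m
}

disc_kernel <- function(wnd) {
  sz <- as.integer(wnd)
  if (sz %% 2 == 0) sz <- sz + 1L  # EBImage disc brushes have odd side
  if (sz < 3L) return(matrix(1, 1, 1))
  EBImage::makeBrush(sz, shape = "disc")
}

#' Morphological background removal
#'
#' Estimates the remaining out-of-focus background of each frame as its
#' grayscale morphological opening (erosion then dilation) with a flat disc
#' whose diameter matches the expected cell diameter, and subtracts it.
#' Because the opening never exceeds the frame, the result is non-negative;
#' this is the white top-hat transform acting as a size filter that keeps
#' cell bodies and removes smooth, larger-scale fluorescence.
#'
#' @param video a [video_array()].
#' @param method only `"tophat"` is implemented.
#' @param wnd structuring-element diameter in pixels (default 20).
#' @return a `video_array` of the same shape.
#' @export
remove_background <- function(video, method = "tophat", wnd = 20) {
  method <- match.arg(method, "tophat")
  stopifnot(wnd >= 1)
  d <- dim(video)
  out <- va_data(video)
  kern <- disc_kernel(wnd)
  if (length(kern) > 1) {
    for (blk in chunk_starts(d[1], attr(video, "chunks")[1])) {
      for (t in blk) {
        fr <- out[t, , ]
        out[t, , ] <- pmax(fr - opening_gray(fr, kern), 0)
      }
    }
  } else {
    out[] <- 0  # opening with a single-pixel element returns the frame
  }
  va_like(out, video)
}

#' Run the full preprocessing stage
#'
#' Applies, in order: vignetting correction, median denoising, and
#' morphological background removal.
#'
#' @param video a [video_array()].
#' @param denoise_wnd odd median window side (px).
#' @param background_wnd structuring-element diameter (px).
#' @return a `video_array`.
#' @export
preprocess_video <- function(video, denoise_wnd = 11, background_wnd = 20) {
  video |>
    remove_vignette() |>
    denoise(wnd = denoise_wnd) |>
    remove_background(wnd = background_wnd)
}
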