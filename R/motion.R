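#' Estimate the integer shift between a frame and a template
#'
#' Exhaustive search over integer displacements in
#' `[-max_shift, max_shift]^2` for the one maximizing the Pearson
#' (normalized) cross-correlation between the shifted frame and the
#' template, computed on the valid overlap.  The returned value is the
#' displacement of the frame *relative to* the template; [apply_shifts()]
#' undoes it.  If the true displacement exceeds `max_shift` the argmax
#' within the search window is returned (clamped search).  Exact
#' correlation ties are broken towards the smallest L-infinity shift, then
#' row before column.
#'
#' @param frame,template numeric matrices of identical shape.
#' @param max_shift maximum displacement searched, in pixels.
#' @param margin exclude this many border pixels of the template from the
#'   correlation (keeps the compared region constant across shifts).
#' @return integer vector `c(shift_row, shift_col)`.
#' @export
match_template_shift <- function(frame, template, max_shift = 10,
                                 margin = 0) {
  stopifnot(max_shift >= 0)
  if (stats::sd(frame) == 0 || stats::sd(template) == 0)
    stop("flat image: normalized cross-correlation undefined")
  cpp_match_template(frame, template, as.integer(max_shift),
                     as.integer(margin))
}

#' Estimate rigid per-frame motion
#'
#' Divide-and-conquer template matching: the movie is split into leaf chunks
#' of at most `chunk_nfm` frames, within which every frame is registered to
#' the chunk's middle frame.  Chunks are then merged three at a time, using
#' the max projection of each (already registered) chunk as its template and
#' the middle chunk as reference, so chunk size grows in powers of three
#' until one chunk covers the movie.  Sparse, non-overlapping activity can
#' make max-projection templates unreliable; whenever the projection-based
#' inter-chunk shift and the shift implied by the two consecutive border
#' frames disagree by more than `fallback_thres` pixels on either axis, the
#' consecutive-frame estimate is used instead.
#'
#' @param video a [video_array()] (preprocessed).
#' @param chunk_nfm frames per leaf chunk (>= 2).
#' @param max_shift maximum displacement searched per match, in pixels.
#' @param fallback_thres disagreement (px, per axis) beyond which the
#'   consecutive-frame fallback is taken.
#' @param mask optional [crop_mask()]: matching is computed on this
#'   sub-region only (shifts still apply to the full frame).
#' @param blur_sigma optional Gaussian pre-blur (px sd) of the frames used
#'   for matching only; off by default (cell-sized features are already
#'   smooth and further blurring flattens the correlation peak).
#' @return a data.frame with columns `frame`, `shift_row`, `shift_col`
#'   (class `motion_shifts`).
#' @export
estimate_motion <- function(video, chunk_nfm = 3, max_shift = 10,
                            fallback_thres = 5, mask = NULL,
                            blur_sigma = 0) {
  d <- dim(video)
  if (d[1] == 0) stop("empty video")
  arr <- va_data(video)
  if (!is.null(mask)) {
    arr <- arr[, (mask$rows[1] + 1L):mask$rows[2],
               (mask$cols[1] + 1L):mask$cols[2], drop = FALSE]
  }
  if (blur_sigma > 0) {
    for (t in seq_len(d[1]))
      arr[t, , ] <- EBImage::gblur(arr[t, , ], sigma = blur_sigma)
  }
  stopifnot(chunk_nfm >= 2)
  res <- est_motion_part(arr, seq_len(d[1]), chunk_nfm, max_shift,
                         fallback_thres)
  sh <- res$shifts
  # the global reference is arbitrary; centre on the median shift so the
  # correction moves the movie as little as possible
  sh <- sweep(sh, 2, round(apply(sh, 2, stats::median)))
  structure(data.frame(frame = attr(video, "coords")$frame,
                       shift_row = sh[, 1], shift_col = sh[, 2]),
            class = c("motion_shifts", "data.frame"))
}

# register frames[idx]; returns per-frame shifts (n x 2) relative to the
# part's internal reference, plus the max projection of the registered part
est_motion_part <- function(arr, idx, chunk_nfm, max_shift, fallback_thres) {
  n <- length(idx)
  if (n <= chunk_nfm) {
    mid <- idx[(n + 1L) %/% 2L]
    templ <- arr[mid, , ]
    sh <- matrix(0L, n, 2)
    reg <- array(0, c(n, dim(templ)))
    for (k in seq_len(n)) {
      if (idx[k] == mid) {
        reg[k, , ] <- arr[idx[k], , ]
        next
      }
      s <- tryCatch(cpp_match_template(arr[idx[k], , ], templ,
                                       as.integer(max_shift),
                                       as.integer(max_shift)),
                    error = function(e) c(0L, 0L))
      sh[k, ] <- s
      reg[k, , ] <- cpp_shift_frame(arr[idx[k], , ], s[1], s[2], 0)
    }
    return(list(shifts = sh, proj = apply(reg, c(2, 3), max),
                first = reg[seq_len(min(3, n)), , , drop = FALSE],
                last = reg[n + 1L - rev(seq_len(min(3, n))), , ,
                           drop = FALSE]))
  }
  # split into three near-equal contiguous parts and recurse
  cut <- round(n * c(1, 2) / 3)
  parts <- list(idx[1:cut[1]], idx[(cut[1] + 1):cut[2]], idx[(cut[2] + 1):n])
  sub <- lapply(parts, est_motion_part, arr = arr, chunk_nfm = chunk_nfm,
                max_shift = max_shift, fallback_thres = fallback_thres)
  # register parts 1 and 3 to the middle part via max-projection templates,
  # with the consecutive-border-frame estimate as fallback
  off <- list(c(0L, 0L), c(0L, 0L), c(0L, 0L))
  for (k in c(1L, 3L)) {
    proj_shift <- tryCatch(
      cpp_match_template(sub[[k]]$proj, sub[[2]]$proj, as.integer(max_shift),
                         as.integer(max_shift)),
      error = function(e) c(0L, 0L))
    cons <- if (k == 1L) {
      border_shift(sub[[1]]$last, sub[[2]]$first, max_shift, proj_shift)
    } else {
      border_shift(sub[[3]]$first, sub[[2]]$last, max_shift, proj_shift)
    }
    off[[k]] <- if (any(abs(proj_shift - cons) > fallback_thres)) cons
                else proj_shift
  }
  sh <- rbind(sweep(sub[[1]]$shifts, 2, -off[[1]]),
              sub[[2]]$shifts,
              sweep(sub[[3]]$shifts, 2, -off[[3]]))
  # rebuild projection / border frames in the common reference
  shift_proj <- function(p, o) cpp_shift_frame(p, o[1], o[2], 0)
  proj <- pmax(pmax(shift_proj(sub[[1]]$proj, off[[1]]), sub[[2]]$proj),
               shift_proj(sub[[3]]$proj, off[[3]]))
  shift_stack <- function(st, o) {
    for (k in seq_len(dim(st)[1])) st[k, , ] <- shift_proj(st[k, , ], o)
    st
  }
  list(shifts = sh, proj = proj,
       first = shift_stack(sub[[1]]$first, off[[1]]),
       last = shift_stack(sub[[3]]$last, off[[3]]))
}

# consecutive-frame shift across a chunk border, made robust by taking the
# per-axis median over the frame pairs within two frames of the boundary
border_shift <- function(last_stack, first_stack, max_shift, fallback) {
  ests <- list()
  nl <- dim(last_stack)[1]; nf <- dim(first_stack)[1]
  for (i in seq_len(nl)) for (j in seq_len(nf)) {
    if ((nl - i) + (j - 1) > 2) next  # frames at most two hops apart
    e <- tryCatch(cpp_match_template(last_stack[i, , ], first_stack[j, , ],
                                     as.integer(max_shift),
                                     as.integer(max_shift)),
                  error = function(e) NULL)
    if (!is.null(e)) ests[[length(ests) + 1]] <- e
  }
  if (length(ests) == 0) return(fallback)
  m <- do.call(rbind, ests)
  as.integer(round(apply(m, 2, stats::median)))
}

#' Apply estimated shifts to a video
#'
#' Each frame is translated by the negative of its estimated shift
#' (integer-pixel translation, no interpolation); vacated borders are filled
#' with `fill`.
#'
#' @param video a [video_array()].
#' @param shifts a `motion_shifts` data.frame from [estimate_motion()].
#' @param fill border fill value (default 0).
#' @return a `video_array`.
#' @export
apply_shifts <- function(video, shifts, fill = 0) {
  d <- dim(video)
  if (nrow(shifts) != d[1]) stop("shifts length must equal frame count")
  out <- va_data(video)
  for (blk in chunk_starts(d[1], attr(video, "chunks")[1])) {
    for (t in blk) {
      if (shifts$shift_row[t] != 0 || shifts$shift_col[t] != 0)
        out[t, , ] <- cpp_shift_frame(out[t, , ], shifts$shift_row[t],
                                      shifts$shift_col[t], fill)
    }
  }
  va_like(out, video)
}
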