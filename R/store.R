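#' Chunked on-disk array store
#'
#' Arrays are persisted as a directory in the Zarr v2 layout (C-order
#' chunks, float64 little-endian, no compression), with axis names and
#' coordinates recorded under the xarray `_ARRAY_DIMENSIONS` convention in
#' `.zattrs`.  This is the package's default intermediate store; stores
#' written here are readable by any Zarr v2 implementation.
#'
#' @param x a numeric array (1-3 dimensions), [video_array()], or matrix.
#' @param store_path directory to create/overwrite.
#' @param chunks per-axis chunk sizes; defaults to the array's chunk plan
#'   (if any) or the full shape.
#' @param dims axis names; defaults for a `video_array` are
#'   `c("frame","height","width")`.
#' @param attrs named list of extra scalar attributes to record.
#' @return `store_path`, invisibly.
#' @export
persist_array <- function(x, store_path, chunks = NULL, dims = NULL,
                          attrs = list()) {
  coords <- attr(x, "coords")
  if (inherits(x, "video_array")) {
    dims <- dims %||% c("frame", "height", "width")
    attrs$fps <- attr(x, "fps")
    chunks <- chunks %||% attr(x, "chunks")
  }
  arr <- x
  attributes(arr) <- list(dim = dim(x) %||% length(x))
  d <- dim(arr)
  nd <- length(d)
  if (is.null(dims)) dims <- paste0("dim_", seq_len(nd) - 1L)
  if (is.null(chunks)) chunks <- d
  chunks <- as.integer(pmin(pmax(chunks, 1L), pmax(d, 1L)))
  ok <- dir.create(store_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(store_path)) stop("I/O error: cannot create store at ", store_path)
  unlink(list.files(store_path, all.files = TRUE, full.names = TRUE,
                    no.. = TRUE), recursive = TRUE)
  zarray <- list(zarr_format = 2L, shape = as.list(d), chunks = as.list(chunks),
                 dtype = "<f8", compressor = NULL, fill_value = 0,
                 filters = NULL, order = "C")
  writeLines(jsonlite::toJSON(zarray, auto_unbox = TRUE, null = "null",
                              digits = NA),
             file.path(store_path, ".zarray"))
  zattrs <- c(list(`_ARRAY_DIMENSIONS` = as.list(dims)), attrs)
  if (!is.null(coords)) zattrs$coords <- coords
  writeLines(jsonlite::toJSON(zattrs, auto_unbox = TRUE, digits = NA),
             file.path(store_path, ".zattrs"))
  ngrid <- ceiling(d / chunks)
  grid <- as.matrix(expand.grid(lapply(ngrid, function(n) seq_len(n) - 1L)))
  for (g in seq_len(nrow(grid))) {
    ci <- grid[g, ]
    idx <- lapply(seq_len(nd), function(k) {
      s <- ci[k] * chunks[k] + 1L
      s:min(s + chunks[k] - 1L, d[k])
    })
    blk <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    # pad edge chunks to full chunk shape with the fill value
    if (any(dim(blk) != chunks)) {
      full <- array(0, chunks)
      do.call(`[<-`, c(list(full), lapply(dim(blk), seq_len), list(blk))) -> full
      blk <- full
    }
    # C order: last axis fastest
    vals <- as.vector(aperm(blk, rev(seq_len(nd))))
    con <- file(file.path(store_path, paste(rev(ci), collapse = ".")), "wb")
    writeBin(vals, con, size = 8, endian = "little")
    close(con)
  }
  invisible(store_path)
}

#' Load an array from a chunked store
#'
#' Round-trips [persist_array()] bit-exactly, including axis names,
#' coordinates and recorded attributes.  If the store carries the
#' `(frame, height, width)` axes of a video, a [video_array()] is returned.
#'
#' @param store_path directory written by [persist_array()].
#' @return array, matrix or `video_array` depending on the stored axes.
#' @export
load_array <- function(store_path) {
  zf <- file.path(store_path, ".zarray")
  if (!file.exists(zf)) stop("I/O error: not a store: ", store_path)
  za <- jsonlite::fromJSON(readLines(zf, warn = FALSE))
  d <- as.integer(za$shape); chunks <- as.integer(za$chunks)
  nd <- length(d)
  stopifnot(za$dtype == "<f8", za$order == "C")
  out <- array(0, pmax(d, 1L))
  ngrid <- ceiling(d / chunks)
  grid <- as.matrix(expand.grid(lapply(ngrid, function(n) seq_len(n) - 1L)))
  if (prod(d) > 0) for (g in seq_len(nrow(grid))) {
    ci <- grid[g, ]
    f <- file.path(store_path, paste(rev(ci), collapse = "."))
    con <- file(f, "rb")
    vals <- readBin(con, "double", n = prod(chunks), size = 8,
                    endian = "little")
    close(con)
    blk <- aperm(array(vals, rev(chunks)), rev(seq_len(nd)))
    idx <- lapply(seq_len(nd), function(k) {
      s <- ci[k] * chunks[k] + 1L
      s:min(s + chunks[k] - 1L, d[k])
    })
    blk <- do.call(`[`, c(list(blk), lapply(lengths(idx), seq_len),
                          list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx, list(blk)))
  }
  if (prod(d) == 0) out <- array(numeric(0), d)
  attrs <- list()
  af <- file.path(store_path, ".zattrs")
  if (file.exists(af)) attrs <- jsonlite::fromJSON(readLines(af, warn = FALSE),
                                                   simplifyVector = TRUE)
  dims <- unlist(attrs$`_ARRAY_DIMENSIONS`)
  if (identical(dims, c("frame", "height", "width"))) {
    co <- NULL
    if (!is.null(attrs$coords))
      co <- lapply(attrs$coords, as.integer)
    return(video_array(out, fps = attrs$fps %||% 30, coords = co,
                       chunks = chunks))
  }
  if (nd == 2) dim(out) <- d
  attr(out, "dims") <- dims
  out
}
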