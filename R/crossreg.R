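#' Align sessions to a template session
#'
#' Estimates one rigid translation per session by template-matching each
#' session's summary image (max projection of the preprocessed video, or
#' summed footprints) against the template session's summary.  The
#' template session gets shift `(0, 0)`.
#'
#' @param templates named list of summary matrices, one per session.
#' @param template_session name or index of the reference session.
#' @param max_shift maximum displacement searched (px).
#' @return data.frame with `session`, `shift_row`, `shift_col`.
#' @export
align_sessions <- function(templates, template_session = 1, max_shift = 20) {
  nm <- names(templates) %||% as.character(seq_along(templates))
  ti <- if (is.numeric(template_session)) as.integer(template_session)
        else match(as.character(template_session), nm)
  ref <- templates[[ti]]
  if (stats::sd(ref) == 0) stop("flat template summary")
  sh <- t(vapply(seq_along(templates), function(i) {
    if (i == ti) return(c(0L, 0L))
    as.integer(match_template_shift(templates[[i]], ref, max_shift))
  }, integer(2)))
  data.frame(session = nm, shift_row = sh[, 1], shift_col = sh[, 2])
}

#' Shift footprints by a session alignment
#'
#' Applies the integer session shift to every unit's footprint (undoing the
#' estimated displacement), so centroids are computed in the aligned frame.
#'
#' @param A footprint array `(height, width, unit)`.
#' @param shift integer `c(shift_row, shift_col)`.
#' @return shifted footprint array.
#' @export
shift_footprints <- function(A, shift) {
  if (all(shift == 0)) return(A)
  out <- A
  for (k in seq_len(dim(A)[3]))
    out[, , k] <- cpp_shift_frame(A[, , k], shift[1], shift[2], 0)
  out
}

#' Mutual-nearest centroid matching between two sessions
#'
#' Distances are evaluated inside moving spatial windows (side `window`,
#' overlapping by half, so pairs straddling a window edge are still seen).
#' A pair `(i, j)` is matched iff their distance is at most `param_dist`,
#' `i` is `j`'s nearest neighbour and `j` is `i`'s nearest.  Exact distance
#' ties are discarded.
#'
#' @param centA,centB centroid data.frames from [calculate_centroids()]
#'   (columns `unit_id`, `row`, `col`) in the aligned frame.
#' @param param_dist maximum matching distance in pixels (default 5).
#' @param window moving-window side in pixels (default 100; use a value
#'   much larger than a cell).
#' @return data.frame with `unit_a`, `unit_b`, `dist`.
#' @export
match_centroid_pairs <- function(centA, centB, param_dist = 5,
                                 window = 100) {
  if (nrow(centA) == 0 || nrow(centB) == 0)
    return(data.frame(unit_a = integer(0), unit_b = integer(0),
                      dist = numeric(0)))
  lim <- ceiling(max(centA$row, centA$col, centB$row, centB$col)) + 1
  starts <- unique(pmax(0, seq(0, lim, by = window / 2)))
  dd <- matrix(Inf, nrow(centA), nrow(centB))
  for (r0 in starts) for (c0 in starts) {
    ia <- which(centA$row >= r0 & centA$row < r0 + window &
                  centA$col >= c0 & centA$col < c0 + window)
    ib <- which(centB$row >= r0 & centB$row < r0 + window &
                  centB$col >= c0 & centB$col < c0 + window)
    if (length(ia) == 0 || length(ib) == 0) next
    d <- sqrt(outer(centA$row[ia], centB$row[ib], `-`)^2 +
                outer(centA$col[ia], centB$col[ib], `-`)^2)
    dd[ia, ib] <- pmin(dd[ia, ib, drop = FALSE], d)
  }
  dd[dd > param_dist] <- Inf
  pick_mutual <- function(dd) {
    out <- NULL
    for (i in seq_len(nrow(dd))) {
      di <- dd[i, ]
      if (all(!is.finite(di))) next
      j <- which(di == min(di))
      if (length(j) > 1) next              # tie: discard
      dj <- dd[, j]
      i2 <- which(dj == min(dj))
      if (length(i2) > 1 || i2 != i) next  # not mutual or tied
      out <- rbind(out, data.frame(i = i, j = j, dist = di[j]))
    }
    out %||% data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  }
  m <- pick_mutual(dd)
  data.frame(unit_a = centA$unit_id[m$i], unit_b = centB$unit_id[m$j],
             dist = m$dist)
}

#' Resolve pairwise matches into a master cross-session mapping
#'
#' Takes the union of all pairwise matches, groups units transitively, and
#' keeps a group only if every pair of sessions represented in it has the
#' corresponding direct pairwise match (and no session appears twice);
#' otherwise the whole group dissolves into singletons.  The master table
#' has one row per putative real cell and one column per session holding
#' that session's unit id or `NA`.
#'
#' @param pairwise named list of match data.frames from
#'   [match_centroid_pairs()]; names are `"<sessionA>|<sessionB>"`.
#' @param sessions character vector of all session names.
#' @return data.frame (class `crossreg_mapping`), one column per session.
#' @export
resolve_mappings <- function(pairwise, sessions) {
  node <- function(s, u) paste0(s, "#", u)
  # collect per-session unit universe from the pairwise tables
  units <- stats::setNames(vector("list", length(sessions)), sessions)
  edges <- character(0)
  for (nm in names(pairwise)) {
    ss <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tab <- pairwise[[nm]]
    units[[ss[1]]] <- union(units[[ss[1]]], tab$unit_a)
    units[[ss[2]]] <- union(units[[ss[2]]], tab$unit_b)
    if (nrow(tab))
      edges <- c(edges, rbind(node(ss[1], tab$unit_a),
                              node(ss[2], tab$unit_b)))
  }
  all_nodes <- unlist(lapply(sessions, function(s)
    if (length(units[[s]])) node(s, units[[s]]) else character(0)))
  if (length(all_nodes) == 0)
    return(empty_mapping(sessions))
  g <- igraph::make_graph(edges = edges, isolates =
                            setdiff(all_nodes, edges), directed = FALSE)
  comp <- igraph::components(g)$membership
  direct <- new.env()
  for (nm in names(pairwise)) {
    ss <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tab <- pairwise[[nm]]
    if (nrow(tab)) for (r in seq_len(nrow(tab))) {
      key <- paste(node(ss[1], tab$unit_a[r]), node(ss[2], tab$unit_b[r]))
      assign(key, TRUE, envir = direct)
      assign(paste(node(ss[2], tab$unit_b[r]), node(ss[1], tab$unit_a[r])),
             TRUE, envir = direct)
    }
  }
  rows <- list()
  for (cid in unique(comp)) {
    mem <- names(comp)[comp == cid]
    ms <- sub("#.*$", "", mem)
    mu <- sub("^.*#", "", mem)
    ok <- !anyDuplicated(ms)
    if (ok && length(mem) > 1) {
      for (a in seq_len(length(mem) - 1)) for (b in (a + 1):length(mem)) {
        if (!isTRUE(mget(paste(mem[a], mem[b]), envir = direct,
                         ifnotfound = FALSE)[[1]])) { ok <- FALSE; break }
      }
    }
    if (ok) {
      row <- stats::setNames(rep(NA_integer_, length(sessions)), sessions)
      row[ms] <- as.integer(mu)
      rows[[length(rows) + 1]] <- row
    } else {
      for (k in seq_along(mem)) {  # conflict: dissolve into singletons
        row <- stats::setNames(rep(NA_integer_, length(sessions)), sessions)
        row[ms[k]] <- as.integer(mu[k])
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- sessions
  ord <- do.call(order, out)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("crossreg_mapping", "data.frame"))
}

empty_mapping <- function(sessions) {
  out <- as.data.frame(stats::setNames(
    rep(list(integer(0)), length(sessions)), sessions))
  structure(out, class = c("crossreg_mapping", "data.frame"))
}

#' Cross-register cells across sessions
#'
#' Full pipeline: align each session's summary image to the template
#' session, shift footprints, compute weighted centroids, run
#' mutual-nearest matching for every session pair, and resolve the
#' pairwise matches into a master mapping.
#'
#' @param footprints named list of footprint arrays, one per session.
#' @param summaries optional named list of summary images for alignment;
#'   default: summed footprints.
#' @param unit_ids optional named list of per-session unit id vectors.
#' @param template_session reference session (name or index).
#' @param param_dist mutual-nearest distance threshold (px).
#' @param max_shift alignment search radius (px).
#' @param window moving-window side (px).
#' @return list with `shifts`, `pairwise`, `mapping`.
#' @export
cross_register <- function(footprints, summaries = NULL, unit_ids = NULL,
                           template_session = 1, param_dist = 5,
                           max_shift = 20, window = 100) {
  sessions <- names(footprints) %||% as.character(seq_along(footprints))
  names(footprints) <- sessions
  if (is.null(summaries))
    summaries <- lapply(footprints, function(A) apply(A, c(1, 2), sum))
  shifts <- align_sessions(summaries, template_session, max_shift)
  cents <- lapply(sessions, function(s) {
    sh <- unlist(shifts[shifts$session == s, c("shift_row", "shift_col")])
    A <- shift_footprints(footprints[[s]], sh)
    calculate_centroids(A, unit_ids = unit_ids[[s]] %||%
                          seq_len(dim(A)[3]))
  })
  names(cents) <- sessions
  pairwise <- list()
  if (length(sessions) > 1) {
    for (a in seq_len(length(sessions) - 1)) for (b in (a + 1):length(sessions)) {
      pairwise[[paste(sessions[a], sessions[b], sep = "|")]] <-
        match_centroid_pairs(cents[[a]], cents[[b]], param_dist, window)
    }
  }
  list(shifts = shifts, centroids = cents, pairwise = pairwise,
       mapping = resolve_mappings(pairwise, sessions))
}
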