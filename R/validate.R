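#' Weighted footprint centroids
#'
#' Intensity-weighted mean pixel coordinate of each unit's footprint,
#' in 0-based `(row, col)` coordinates.
#'
#' @param A footprint array `(height, width, unit)`.
#' @param unit_ids optional labels (default `1:K`).
#' @return data.frame with `unit_id`, `row`, `col`.
#' @export
calculate_centroids <- function(A, unit_ids = NULL) {
  d <- dim(A)
  K <- d[3]
  if (is.null(unit_ids)) unit_ids <- seq_len(K)
  rows <- cols <- numeric(K)
  ri <- seq_len(d[1]) - 1; ci <- seq_len(d[2]) - 1
  for (k in seq_len(K)) {
    w <- A[, , k]
    tot <- sum(w)
    if (tot <= 0) stop("zero footprint has no centroid")
    rows[k] <- sum(rowSums(w) * ri) / tot
    cols[k] <- sum(colSums(w) * ci) / tot
  }
  data.frame(unit_id = unit_ids, row = rows, col = cols)
}

# maximum-cardinality, minimum-total-distance one-to-one matching between
# two centroid sets, restricted to pairs at distance <= max_dist
assign_centroids <- function(centA, centB, max_dist) {
  nA <- nrow(centA); nB <- nrow(centB)
  if (nA == 0 || nB == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  dmat <- outer(centA$row, centB$row, `-`)^2 +
    outer(centA$col, centB$col, `-`)^2
  dmat <- sqrt(dmat)
  pairs <- which(dmat <= max_dist, arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  # maximum weight bipartite matching; big constant enforces cardinality
  big <- max_dist * (min(nA, nB) + 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("a", pairs[, 1]),
               to = paste0("b", pairs[, 2]),
               weight = big - dmat[pairs]),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("a", seq_len(nA)),
                                   paste0("b", seq_len(nB))),
                          type = rep(c(FALSE, TRUE), c(nA, nB))))
  m <- igraph::max_bipartite_match(g)$matching
  i <- seq_len(nA)
  j <- as.integer(sub("^b", "", m[paste0("a", i)]))
  ok <- !is.na(j)
  data.frame(i = i[ok], j = j[ok],
             dist = dmat[cbind(i[ok], j[ok])])
}

#' Match estimated units to ground truth
#'
#' Optimal one-to-one assignment between the centroid sets of two footprint
#' collections: the matching maximizes the number of pairs within
#' `max_dist` pixels and, among those, minimizes the total centroid
#' distance.  Rigid registration fixes footprints only up to a global
#' integer translation (the reference of the motion-correction template),
#' so by default the summed-footprint images are first template-matched
#' and the estimated set is shifted onto the reference set; the alignment
#' shift used is recorded as an attribute.
#'
#' @param A_true,A_est footprint arrays `(height, width, unit)`.
#' @param max_dist maximum centroid distance for a valid pair (px); default
#'   8, about one cell diameter.
#' @param align remove the global translation before matching (default
#'   `TRUE`).
#' @return an object of class `match_result`: data.frame of pairs
#'   (`truth_unit`, `est_unit`, `dist`) with counts `n_true`, `n_est`,
#'   `n_matched` and the alignment shift as attributes.
#' @export
match_neurons <- function(A_true, A_est, max_dist = 8, align = TRUE) {
  shift <- c(0L, 0L)
  if (align && dim(A_true)[3] > 0 && dim(A_est)[3] > 0) {
    s_true <- apply(A_true, c(1, 2), sum)
    s_est <- apply(A_est, c(1, 2), sum)
    shift <- tryCatch(
      match_template_shift(s_est, s_true, max_shift = 2 * max_dist,
                           margin = 2 * max_dist),
      error = function(e) c(0L, 0L))
    A_est <- shift_footprints(A_est, shift)
  }
  ct <- calculate_centroids(A_true)
  ce <- calculate_centroids(A_est)
  asg <- assign_centroids(ct, ce, max_dist)
  res <- data.frame(truth_unit = asg$i, est_unit = asg$j, dist = asg$dist)
  structure(res, class = c("match_result", "data.frame"),
            n_true = nrow(ct), n_est = nrow(ce), n_matched = nrow(res),
            align_shift = shift)
}

#' Shift estimated footprints onto the reference frame of a matching
#'
#' Applies the alignment translation recorded by [match_neurons()] so that
#' per-pixel footprint comparisons use the same gauge as the matching.
#'
#' @param match a `match_result`.
#' @param A_est the estimated footprint array passed to [match_neurons()].
#' @return the shifted footprint array.
#' @export
aligned_footprints <- function(match, A_est) {
  shift_footprints(A_est, attr(match, "align_shift") %||% c(0L, 0L))
}

#' Detection precision, recall and F1
#'
#' `precision = n_matched / n_est`, `recall = n_matched / n_true`,
#' `f1 = 2 P R / (P + R)` (0 when `P + R = 0`).
#'
#' @param match a `match_result` from [match_neurons()].
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
score_f1 <- function(match) {
  n_true <- attr(match, "n_true"); n_est <- attr(match, "n_est")
  if (n_true == 0 && n_est == 0) stop("undefined: no units on either side")
  n_m <- attr(match, "n_matched")
  P <- if (n_est > 0) n_m / n_est else 0
  R <- if (n_true > 0) n_m / n_true else 0
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = f1)
}

#' Median footprint and trace correlations over matched units
#'
#' Per matched pair, the Pearson correlation of the flattened footprints
#' and of the calcium traces; the medians across pairs are returned.
#' Pairs with a zero-variance member are excluded with a warning.
#'
#' @param match a `match_result`.
#' @param A_true,A_est footprint arrays; `C_true`, `C_est` trace matrices
#'   `(frame, unit)`.
#' @return named numeric vector `(footprint, trace)`.
#' @export
median_correlations <- function(match, A_true, A_est, C_true, C_est) {
  stopifnot(nrow(match) >= 1)
  fp <- tr <- numeric(0)
  for (r in seq_len(nrow(match))) {
    a1 <- as.vector(A_true[, , match$truth_unit[r]])
    a2 <- as.vector(A_est[, , match$est_unit[r]])
    c1 <- C_true[, match$truth_unit[r]]
    c2 <- C_est[, match$est_unit[r]]
    if (stats::sd(a1) == 0 || stats::sd(a2) == 0) {
      warning("zero-variance footprint excluded from correlation")
    } else fp <- c(fp, stats::cor(a1, a2))
    if (stats::sd(c1) == 0 || stats::sd(c2) == 0) {
      warning("zero-variance trace excluded from correlation")
    } else tr <- c(tr, stats::cor(c1, c2))
  }
  c(footprint = stats::median(fp), trace = stats::median(tr))
}

#' Spike-signal correlation after temporal binning
#'
#' Both spike series are bin-summed by `factor` frames and the Pearson
#' correlation is computed per matched unit; the mean and sd across units
#' are reported.  Units with a zero-variance binned series are excluded
#' with a warning.
#'
#' @param S_true,S_est spike matrices `(frame, unit)` with equal frame
#'   counts.
#' @param match a `match_result`.
#' @param factor binning factor (default 5).
#' @return list with `per_unit` (numeric vector), `mean`, `sd`.
#' @export
spike_correlation <- function(S_true, S_est, match, factor = 5) {
  stopifnot(nrow(S_true) == nrow(S_est))
  bin <- function(x) {
    n <- (length(x) %/% factor) * factor
    colSums(matrix(x[seq_len(n)], factor))
  }
  per <- numeric(0)
  for (r in seq_len(nrow(match))) {
    s1 <- bin(S_true[, match$truth_unit[r]])
    s2 <- bin(S_est[, match$est_unit[r]])
    if (stats::sd(s1) == 0 || stats::sd(s2) == 0) {
      warning("zero-variance binned spike series excluded")
      next
    }
    per <- c(per, stats::cor(s1, s2))
  }
  list(per_unit = per, mean = mean(per), sd = stats::sd(per))
}
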