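# Likelihood-map labels, local-maxima extraction, and the threshold-sweep
# true/false-positive evaluation.

#' Build a Gaussian likelihood-map label from marker centres
#'
#' Each marker contributes an unnormalised 2-D Gaussian (peak 1) at its
#' centre with SD `sigma = (1,1)` px; the label is the element-wise mean of
#' the per-marker maps, min-max normalised to `[0, 1]`.  With no centres an
#' all-zero map is returned (normalisation skipped).
#'
#' @param centres integer/numeric matrix `n x 2` of (row, col) centres
#'   (1-based), all inside `shape`
#' @param shape `c(rows, cols)`
#' @param sigma Gaussian SD (row, col) in pixels
#' @return matrix in `[0, 1]`
#' @export
buildLabel <- function(centres, shape, sigma = c(1, 1)) {
  out <- matrix(0, shape[1], shape[2])
  centres <- matrix(centres, ncol = 2)
  if (!nrow(centres)) return(out)
  if (any(centres[, 1] < 1) || any(centres[, 1] > shape[1]) ||
      any(centres[, 2] < 1) || any(centres[, 2] > shape[2]))
    stop("marker centre outside the image")
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(nrow(centres)))
    out <- out + exp(-((r - centres[i, 1])^2 / (2 * sigma[1]^2) +
                       (c_ - centres[i, 2])^2 / (2 * sigma[2]^2)))
  out <- out / nrow(centres)
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out
}

#' Extract 8-connected local maxima of a likelihood map
#'
#' A pixel is a candidate when its value is >= all existing 8-neighbours;
#' candidates are grouped into 8-connected equal-valued plateaus, and a
#' plateau is a maximum when all of its outside neighbours are strictly
#' smaller (so it exceeds at least one neighbour; a constant map has no
#' maxima).  Each plateau contributes one candidate at its centroid,
#' rounded to the nearest pixel.
#'
#' @param map numeric matrix (finite values)
#' @param connectivity 8 (the only supported value)
#' @return data.frame(row, col, value), sorted by decreasing value
#' @export
localMaxima <- function(map, connectivity = 8L) {
  stopifnot(connectivity == 8L, all(is.finite(map)))
  H <- nrow(map); W <- ncol(map)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- map
  geq <- matrix(TRUE, H, W)
  anyLess <- matrix(FALSE, H, W)
  anyEqOut <- matrix(FALSE, H, W)   # filled later per plateau
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(H + 1)) + dr, (2:(W + 1)) + dc]
    ex <- is.finite(nb)
    geq <- geq & (!ex | map >= nb)
    anyLess <- anyLess | (ex & nb < map)
  }
  cand <- which(geq)
  if (!length(cand)) return(data.frame(row = integer(), col = integer(),
                                       value = numeric()))
  # 8-connected equal-value components among candidates (union-find)
  parent <- seq_along(cand)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  inCand <- matrix(0L, H, W)
  inCand[cand] <- seq_along(cand)
  rc <- arrayInd(cand, c(H, W))
  for (i in seq_along(cand)) {
    r0 <- rc[i, 1]; c0 <- rc[i, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r1 <- r0 + dr; c1 <- c0 + dc
      if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
      j <- inCand[r1, c1]
      if (j > 0 && map[r1, c1] == map[cand[i]]) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_along(cand), findRoot, integer(1))
  res <- data.frame(row = integer(), col = integer(), value = numeric())
  for (g in unique(comp)) {
    members <- which(comp == g)
    v <- map[cand[members[1]]]
    ok <- TRUE; hasLess <- FALSE
    for (i in members) {
      r0 <- rc[i, 1]; c0 <- rc[i, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r1 <- r0 + dr; c1 <- c0 + dc
        if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
        nv <- map[r1, c1]
        if (nv > v) ok <- FALSE
        else if (nv < v) hasLess <- TRUE
        else {
          j <- inCand[r1, c1]
          if (j == 0 || findRoot(j) != g) ok <- FALSE  # equal plateau leaks out
        }
      }
    }
    if (ok && hasLess)
      res <- rbind(res, data.frame(row = as.integer(round(mean(rc[members, 1]))),
                                   col = as.integer(round(mean(rc[members, 2]))),
                                   value = v))
  }
  res[order(-res$value, res$row, res$col), , drop = FALSE]
}

#' Match detection candidates to annotated marker centres
#'
#' Candidates with value >= `threshold` are matched greedily in descending
#' value order (ties broken by row, then column): a candidate claims the
#' nearest unmatched annotation within Euclidean distance `tolerance`
#' (default 2 voxels).  Matched candidates are true positives; kept but
#' unmatched candidates are false positives; each annotation is matched at
#' most once.
#'
#' @param candidates data.frame(row, col, value) from [localMaxima()]
#' @param annotations matrix `n x 2` of (row, col) ground-truth centres
#' @param threshold minimum candidate value retained
#' @param tolerance maximum match distance (voxels)
#' @return list(tp, fp, matches = data.frame(candidate, annotation))
#' @export
matchDetections <- function(candidates, annotations, threshold,
                            tolerance = 2) {
  annotations <- matrix(annotations, ncol = 2)
  keep <- candidates[candidates$value >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$value, keep$row, keep$col), , drop = FALSE]
  matched <- logical(nrow(annotations))
  tp <- 0L; fp <- 0L
  pairs <- data.frame(candidate = integer(), annotation = integer())
  for (i in seq_len(nrow(keep))) {
    if (nrow(annotations) && any(!matched)) {
      d <- sqrt((annotations[, 1] - keep$row[i])^2 +
                (annotations[, 2] - keep$col[i])^2)
      d[matched] <- Inf
      j <- which.min(d)
      if (d[j] <= tolerance) {
        matched[j] <- TRUE
        tp <- tp + 1L
        pairs <- rbind(pairs, data.frame(candidate = i, annotation = j))
        next
      }
    }
    fp <- fp + 1L
  }
  list(tp = tp, fp = fp, matches = pairs)
}

#' Threshold-sweep detection evaluation
#'
#' Predicts a likelihood map per evaluation frame (or uses precomputed
#' maps), extracts 8-connected local maxima once per frame, and counts true
#' and false positives at every likelihood threshold.  The dataset summary
#' is the median and IQR of the counts over all (frame, threshold) pairs.
#'
#' @param model a [DetectorModel-class], or NULL if `maps` are supplied
#' @param evalSeries a [MarkerSeries-class], or a `rows x cols x n` array
#' @param annotations ground-truth centres: one `n x 2` matrix, or a list
#'   with one matrix per frame; default: the series' [markerCentresPx()]
#' @param config a [DetectionConfig-class] (thresholds, tolerance)
#' @param maps optional list of precomputed likelihood maps per frame
#' @return a [DetectionMetrics-class]
#' @export
sweepEvaluate <- function(model, evalSeries, annotations = NULL,
                          config = detectionConfig(), maps = NULL) {
  imgs <- if (is(evalSeries, "MarkerSeries")) frames(evalSeries) else evalSeries
  n <- dim(imgs)[3]
  if (is.null(annotations) && is(evalSeries, "MarkerSeries"))
    annotations <- markerCentresPx(evalSeries)
  if (!is.list(annotations)) annotations <- rep(list(annotations), n)
  perFrame <- NULL
  for (i in seq_len(n)) {
    map <- if (is.null(maps)) predictLikelihood(model, imgs[, , i]) else maps[[i]]
    cand <- localMaxima(map, config@connectivity)
    ann <- matrix(annotations[[i]], ncol = 2)
    for (th in config@thresholds) {
      m <- matchDetections(cand, ann, th, config@matchTolerance)
      perFrame <- rbind(perFrame,
                        data.frame(frame = i, threshold = th, tp = m$tp,
                                   fp = m$fp, n_annotated = nrow(ann)))
    }
  }
  tpq <- .safeIQR(perFrame$tp)
  fpq <- .safeIQR(perFrame$fp)
  new("DetectionMetrics", perFrame = perFrame,
      summary = list(tp_median = tpq[["median"]], tp_q1 = tpq[["q1"]],
                     tp_q3 = tpq[["q3"]], fp_median = fpq[["median"]],
                     fp_q1 = fpq[["q1"]], fp_q3 = fpq[["q3"]]),
      thresholds = config@thresholds)
}
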