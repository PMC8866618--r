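# Shared fixtures: tiny geometries and cached simulated series so the
# expensive renders happen once per test run.

# a small acquisition for fast unit tests (divisible by 4 for the detector)
smallAcq <- function(...) {
  AcquisitionParams(matrixSize = c(48L, 48L), ...)
}

# phantom scaled to the small field of view
smallPhantom <- function(...) {
  PhantomSpec(tubeCentre = 40, airMargin = 18, ...)
}

smallWire <- function(...) {
  GuidewireSpec(intermarkerGaps = c(15, 10), tipPosition = c(20, 40), ...)
}

smallRois <- function() {
  ROISet(blood = c(36L, 24L, 8L, 2L), agar = c(8L, 30L, 20L, 5L),
         noise = c(2L, 1L, 44L, 9L))
}

# memoised baseline series shared across tests
.fixtureCache <- new.env(parent = emptyenv())

cachedSeries <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

baselineRef <- function() cachedSeries("ref", simulateSeries(
  PhantomSpec(), NULL, acquisitionPreset("a"), 30, seed = 11))

baselineMarker <- function() cachedSeries("mark", simulateSeries(
  PhantomSpec(), GuidewireSpec(), acquisitionPreset("a"), 30, seed = 12))

# brute-force mean-width oracle: per wire-axis line, count x spacing
oracleWidth <- function(mask, wireAxis, spacing, countEmpty = FALSE) {
  lines <- if (wireAxis == "rows") seq_len(nrow(mask)) else seq_len(ncol(mask))
  perp <- if (wireAxis == "rows") spacing[2] else spacing[1]
  w <- numeric(0)
  for (l in lines) {
    cnt <- if (wireAxis == "rows") sum(mask[l, ]) else sum(mask[, l])
    if (cnt > 0 || countEmpty) w <- c(w, cnt * perp)
  }
  if (!length(w) || all(w == 0)) 0 else mean(w)
}

# exhaustive 8-neighbour local-maxima oracle implementing the documented
# plateau rule by explicit scanning
oracleMaxima <- function(map) {
  H <- nrow(map); W <- ncol(map)
  geq <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r1 <- r + dr; c1 <- c + dc
      if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
      if (map[r1, c1] > map[r, c]) ok <- FALSE
    }
    geq[r, c] <- ok
  }
  # flood-fill equal-valued candidate plateaus
  seen <- matrix(FALSE, H, W)
  out <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!geq[r, c] || seen[r, c]) next
    v <- map[r, c]
    stack <- list(c(r, c)); members <- NULL
    seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      members <- rbind(members, p)
      for (dr in -1:1) for (dc in -1:1) {
        r1 <- p[1] + dr; c1 <- p[2] + dc
        if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
        if (!seen[r1, c1] && geq[r1, c1] && map[r1, c1] == v) {
          seen[r1, c1] <- TRUE
          stack[[length(stack) + 1]] <- c(r1, c1)
        }
      }
    }
    isMax <- TRUE; hasLess <- FALSE
    for (i in seq_len(nrow(members))) {
      for (dr in -1:1) for (dc in -1:1) {
        r1 <- members[i, 1] + dr; c1 <- members[i, 2] + dc
        if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
        inComp <- any(members[, 1] == r1 & members[, 2] == c1)
        if (inComp) next
        if (map[r1, c1] < v) hasLess <- TRUE else isMax <- FALSE
      }
    }
    if (isMax && hasLess)
      out <- rbind(out, data.frame(row = as.integer(round(mean(members[, 1]))),
                                   col = as.integer(round(mean(members[, 2]))),
                                   value = v))
  }
  if (is.null(out)) data.frame(row = integer(), col = integer(),
                               value = numeric())
  else out[order(-out$value, out$row, out$col), , drop = FALSE]
}

# exhaustive optimal-assignment TP count for small candidate sets
oracleAssignment <- function(cand, ann, tolerance) {
  nc <- nrow(cand); na <- nrow(ann)
  if (nc == 0 || na == 0) return(0L)
  d <- outer(seq_len(nc), seq_len(na), function(i, j)
    sqrt((cand$row[i] - ann[j, 1])^2 + (cand$col[i] - ann[j, 2])^2))
  best <- 0L
  assign <- function(i, used, tp) {
    if (i > nc) { best <<- max(best, tp); return(invisible()) }
    assign(i + 1L, used, tp)                      # candidate i unmatched
    for (j in seq_len(na)) {
      if (!used[j] && d[i, j] <= tolerance) {
        used[j] <- TRUE
        assign(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign(1L, logical(na), 0L)
  best
}

# literal 2^n sign-flip enumeration of the two-tailed signed-rank p
oracleWilcoxon <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- apply(expand.grid(rep(list(c(FALSE, TRUE)), n)), 1,
              function(sgn) sum(r[sgn]))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
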