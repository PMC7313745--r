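# Brute-force oracles, independent of the package's C++ kernels:
# morphology and medians by direct exhaustive max/min/median over the disc
# footprint, minima prominence by threshold-sweep connected components
# (igraph), regression by dense grid search.

padRep <- function(m, k) {
  m[c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k)),
    c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
}

discOffsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, ]
}

# one clipped-window max/min pass over a matrix (no padding of its own)
bruteMorphPass <- function(m, r, fun) {
  n <- nrow(m); mm <- ncol(m)
  acc <- matrix(if (identical(fun, pmax)) -Inf else Inf, n, mm)
  offs <- discOffsets(r)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    rT <- max(1, 1 - dy):min(n, n - dy)
    cT <- max(1, 1 - dx):min(mm, mm - dx)
    acc[rT, cT] <- fun(acc[rT, cT], m[rT + dy, cT + dx])
  }
  acc
}

# closing/opening with edge replication: pad by 2r, two passes, crop center
bruteMorph <- function(px, r, type = c("close", "open", "dilate", "erode")) {
  type <- match.arg(type)
  P <- padRep(px, 2L * r)
  out <- switch(type,
    dilate = bruteMorphPass(P, r, pmax),
    erode  = bruteMorphPass(P, r, pmin),
    close  = bruteMorphPass(bruteMorphPass(P, r, pmax), r, pmin),
    open   = bruteMorphPass(bruteMorphPass(P, r, pmin), r, pmax))
  n <- nrow(px); m <- ncol(px)
  out[2L * r + seq_len(n), 2L * r + seq_len(m), drop = FALSE]
}

bruteSubtractBackground <- function(px, r, light = TRUE) {
  if (light) out <- px - bruteMorph(px, r, "close") + 255
  else out <- px - bruteMorph(px, r, "open")
  out[out < 0] <- 0; out[out > 255] <- 255
  matrix(as.integer(out), nrow(px), ncol(px))
}

bruteMedianDisc <- function(px, r) {
  n <- nrow(px); m <- ncol(px)
  offs <- discOffsets(r)
  out <- px
  for (y in seq_len(n)) for (x in seq_len(m)) {
    yy <- pmin(pmax(y + offs$dy, 1L), n)
    xx <- pmin(pmax(x + offs$dx, 1L), m)
    out[y, x] <- as.integer(median(px[cbind(yy, xx)]))
  }
  out
}

# exhaustive regional-minima-with-prominence oracle over small grids.
# Returns a data.frame(row, col, prominence) sorted by (row, col).
bruteFindMinima <- function(px, minProm, mask = NULL) {
  n <- nrow(px); m <- ncol(px)
  if (is.null(mask)) mask <- matrix(TRUE, n, m)
  ids <- which(mask)
  if (!length(ids)) return(data.frame(row = integer(0), col = integer(0),
                                      prominence = integer(0)))
  # 8-neighbor adjacency among in-mask pixels
  co <- arrayInd(ids, c(n, m))
  pos <- match(seq_len(n * m), ids)  # linear index -> vertex id (or NA)
  dirs <- expand.grid(dy = -1:1, dx = -1:1)
  dirs <- dirs[!(dirs$dy == 0 & dirs$dx == 0), ]
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    rr <- co[, 1] + dirs$dy[k]; cc <- co[, 2] + dirs$dx[k]
    okn <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
    nb <- pos[(cc[okn] - 1L) * n + rr[okn]]
    src <- seq_along(ids)[okn]
    keep <- !is.na(nb) & nb > src       # each pair once
    ea <- c(ea, src[keep]); eb <- c(eb, nb[keep])
  }
  vals <- px[ids]
  # plateaus: components of the equal-value subgraph
  eq <- vals[ea] == vals[eb]
  gEq <- igraph::graph_from_data_frame(
    data.frame(from = ea[eq], to = eb[eq]),
    directed = FALSE, vertices = data.frame(name = seq_along(ids)))
  compEq <- igraph::components(gEq)$membership[as.character(seq_along(ids))]
  plateaus <- list()
  for (pc in unique(compEq)) {
    members <- which(compEq == pc)
    v <- vals[members[1]]
    if (v == 255) next
    # neighbors outside the plateau must all be strictly brighter,
    # and at least one such neighbor must exist
    touching <- c(eb[ea %in% members], ea[eb %in% members])
    outside <- setdiff(touching, members)
    if (!length(outside)) next
    if (any(vals[outside] <= v)) next
    mr <- mean(co[members, 1]); mc <- mean(co[members, 2])
    d2 <- (co[members, 1] - mr)^2 + (co[members, 2] - mc)^2
    best <- members[order(d2, co[members, 1], co[members, 2])][1]
    plateaus[[length(plateaus) + 1L]] <- list(
      v = v, members = members, repR = co[best, 1], repC = co[best, 2])
  }
  if (!length(plateaus)) return(data.frame(row = integer(0),
    col = integer(0), prominence = integer(0)))
  # dominance: deeper wins; equal depth -> lexicographically smaller rep
  nP <- length(plateaus)
  pv <- vapply(plateaus, `[[`, 0, "v")
  pr <- vapply(plateaus, `[[`, 0, "repR")
  pc <- vapply(plateaus, `[[`, 0, "repC")
  reps <- vapply(plateaus, function(p) p$members[1], 0)
  domMat <- outer(seq_len(nP), seq_len(nP), function(j, i)
    pv[j] < pv[i] | (pv[j] == pv[i] &
      (pr[j] < pr[i] | (pr[j] == pr[i] & pc[j] < pc[i]))))
  prom <- rep(NA_integer_, nP)
  for (t in sort(unique(vals))) {
    open <- which(is.na(prom) & pv < t)
    if (!length(open)) next
    keepV <- which(vals <= t)
    sel <- ea %in% keepV & eb %in% keepV
    gT <- igraph::graph_from_data_frame(
      data.frame(from = ea[sel], to = eb[sel]),
      directed = FALSE, vertices = data.frame(name = keepV))
    memb <- igraph::components(gT)$membership
    compAll <- unname(memb[as.character(reps)])
    for (i in open) {
      doms <- which(domMat[, i])
      if (any(compAll[doms] == compAll[i], na.rm = TRUE))
        prom[i] <- t - pv[i]
    }
  }
  prom[is.na(prom)] <- 255L - pv[is.na(prom)]
  keep <- which(prom >= minProm)
  out <- data.frame(row = pr[keep], col = pc[keep],
                    prominence = as.numeric(prom[keep]))
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# dense grid-search minimizer of the effective-variance chi-square
gridSlope <- function(x, y, cvX, cvY) {
  f <- function(b) sum((y - b * x)^2 / ((b * cvX * x)^2 + (cvY * y)^2))
  b0 <- NULL
  bs <- seq(1e-3, 4 * max(y / x) + 1, length.out = 4001)
  b0 <- bs[which.min(vapply(bs, f, 0))]
  for (w in c(2e-3, 2e-4, 2e-5)) {
    bs <- seq(max(1e-6, b0 - w), b0 + w, length.out = 401)
    b0 <- bs[which.min(vapply(bs, f, 0))]
  }
  b0
}

# small random test images
randImage <- function(n, m = n, levels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- if (is.null(levels)) sample.int(256, n * m, replace = TRUE) - 1L
       else sample(levels, n * m, replace = TRUE)
  grayImage(matrix(as.integer(v), n, m))
}

# 90 deg counter-clockwise rotation of a matrix
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# a small plate layout used across counter tests
testLayout <- function(n = 1200, segments = 1, ...) {
  plateLayout((n + 1) / 2, (n + 1) / 2, dishRadiusPx = n / 2 - 40,
              imageNrow = n, imageNcol = n, nSegments = segments, ...)
}

# place a radially darkening blob into an integer matrix (for minima tests)
addBlob <- function(px, r0, c0, radius, depth) {
  n <- nrow(px); m <- ncol(px)
  for (y in seq_len(n)) for (x in seq_len(m)) {
    d <- sqrt((y - r0)^2 + (x - c0)^2)
    if (d <= radius)
      px[y, x] <- min(px[y, x],
        as.integer(round(255 - depth * (1 - (d / radius)^2))))
  }
  px
}
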