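# Independent pure-R oracles used to validate the package's compiled
# primitives, plus small digitized-shape builders. Deliberately written
# from scratch, sharing no code with the package internals.

# ---- flood-fill connected-component labelling (BFS) -------------------------

oracleLabel2d <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (connectivity == 8) {
    dy <- c(-1, -1, -1, 0, 0, 1, 1, 1); dx <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dy <- c(-1, 1, 0, 0); dx <- c(0, 0, -1, 1)
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      qy <- integer(nr * nc); qx <- integer(nr * nc)
      qy[1] <- i; qx[1] <- j; head <- 1L; tail <- 1L
      lab[i, j] <- cur
      while (head <= tail) {
        y <- qy[head]; x <- qx[head]; head <- head + 1L
        for (k in seq_along(dy)) {
          yy <- y + dy[k]; xx <- x + dx[k]
          if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
              mask[yy, xx] && lab[yy, xx] == 0L) {
            lab[yy, xx] <- cur
            tail <- tail + 1L
            qy[tail] <- yy; qx[tail] <- xx
          }
        }
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

# ---- Moore boundary walk / chain-code perimeter -----------------------------

# Total boundary-walk length of one connected pixel region (single pixel -> 0).
# Independent re-derivation: walks the Moore boundary clockwise and detects
# the closed cycle by recurrence of the (pixel, entry-direction) state.
oracleMooreWalk <- function(region) {
  pts <- which(region, arr.ind = TRUE)
  if (nrow(pts) == 1) return(0)
  nr <- nrow(region); nc <- ncol(region)
  inR <- function(y, x) y >= 1 && y <= nr && x >= 1 && x <= nc && region[y, x]
  # clockwise ring in image coordinates (y down): W NW N NE E SE S SW
  ry <- c(0, -1, -1, -1, 0, 1, 1, 1)
  rx <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  rlen <- sqrt(ry^2 + rx^2)
  start <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE][1, ]
  cy <- start[1]; cx <- start[2]
  bdir <- 1L # backtrack direction: W of the topmost-leftmost pixel is outside
  seen <- new.env(hash = TRUE)
  total <- 0
  acc <- numeric(0) # cumulative length at each state visit
  repeat {
    key <- paste(cy, cx, bdir)
    if (!is.null(prev <- seen[[key]]))
      return(total - prev)
    seen[[key]] <- total
    moved <- FALSE
    for (s in 1:8) {
      d <- ((bdir - 1L + s) %% 8L) + 1L # scan clockwise from the backtrack
      yy <- cy + ry[d]; xx <- cx + rx[d]
      if (inR(yy, xx)) {
        total <- total + rlen[d]
        # new backtrack: the last empty cell checked, relative to (yy, xx)
        pdir <- ((d - 2L) %% 8L) + 1L
        by <- cy + ry[pdir]; bx <- cx + rx[pdir]
        cy <- yy; cx <- xx
        bdir <- which(ry == by - cy & rx == bx - cx)
        moved <- TRUE
        break
      }
    }
    if (!moved) return(0) # isolated pixel (shouldn't reach here)
  }
}

# Corner-counting perimeters of every 8-connected component of a mask, by the
# package's normative rule: Moore chain-code step sum (straight 1, diagonal
# sqrt(2)) + 4 per closed contour; enclosed solid islands ("holes" of the
# pore) add their own contour to the enclosing component.
oraclePerimeters <- function(mask, includeHoles = TRUE) {
  lab <- oracleLabel2d(mask, 8)
  n <- attr(lab, "n")
  if (n == 0) return(numeric(0))
  per <- vapply(seq_len(n), function(L) oracleMooreWalk(lab == L) + 4,
                numeric(1))
  if (includeHoles) {
    bg <- oracleLabel2d(!mask, 4)
    for (H in seq_len(attr(bg, "n"))) {
      hole <- bg == H
      idx <- which(hole, arr.ind = TRUE)
      if (any(idx[, 1] == 1L | idx[, 1] == nrow(mask) |
              idx[, 2] == 1L | idx[, 2] == ncol(mask))) next
      top <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      owner <- lab[top[1] - 1L, top[2]]
      per[owner] <- per[owner] + oracleMooreWalk(hole) + 4
    }
  }
  per
}

# ---- brute-force threshold objective scans ----------------------------------

# All fixed points of the IsoData map t -> floor((mu_low + mu_high) / 2).
oracleIsodataFixedPoints <- function(counts) {
  bins <- 0:255
  out <- integer(0)
  for (t in 0:254) {
    nl <- sum(counts[1:(t + 1)]); nh <- sum(counts) - nl
    if (nl == 0 || nh == 0) next
    ml <- sum(counts[1:(t + 1)] * bins[1:(t + 1)]) / nl
    mh <- sum(counts[(t + 2):256] * bins[(t + 2):256]) / nh
    if (floor((ml + mh) / 2) == t) out <- c(out, t)
  }
  out
}

# Residual of the IsoData fixed-point equation at each candidate bin.
oracleIsodataResidual <- function(counts, t) {
  bins <- 0:255
  nl <- sum(counts[1:(t + 1)]); nh <- sum(counts) - nl
  if (nl == 0 || nh == 0) return(Inf)
  ml <- sum(counts[1:(t + 1)] * bins[1:(t + 1)]) / nl
  mh <- sum(counts[(t + 2):256] * bins[(t + 2):256]) / nh
  abs((ml + mh) / 2 - t)
}

# Exhaustive minimum-cross-entropy threshold (Li objective) on 1-offset bin
# values; returns the 0-based bin below which lies the background class.
oracleLiScan <- function(counts) {
  v <- 1:256
  best <- Inf; bt <- NA_integer_
  for (t in 1:255) {
    nb <- sum(counts[1:t]); nf <- sum(counts) - nb
    if (nb == 0 || nf == 0) next
    sb <- sum(counts[1:t] * v[1:t])
    sf <- sum(counts * v) - sb
    obj <- -(sb * log(sb / nb) + sf * log(sf / nf))
    if (obj < best - 1e-12) { best <- obj; bt <- t }
  }
  bt - 1L
}

# Exhaustive Kapur maximum-entropy threshold; ties toward the lower bin.
oracleMaxEntropyScan <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p[1:(t + 1)][p[1:(t + 1)] > 0] / P0
    q1 <- p[(t + 2):256][p[(t + 2):256] > 0] / P1
    H <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (H > best + 1e-12) { best <- H; bt <- t }
  }
  bt
}

# Seeded bimodal test histogram: a two-Gaussian intensity mixture on 0..255.
randomBimodalCounts <- function(seed) {
  set.seed(seed)
  mu <- sort(sample(30:220, 2))
  while (diff(mu) < 40) mu <- sort(sample(30:220, 2))
  sdv <- runif(2, 5, 25)
  w <- runif(1, 0.2, 0.8)
  n <- 5000
  vals <- c(rnorm(round(w * n), mu[1], sdv[1]),
            rnorm(n - round(w * n), mu[2], sdv[2]))
  vals <- pmin(pmax(round(vals), 0), 255)
  structure(tabulate(vals + 1L, nbins = 256L), modes = mu)
}

# ---- digitized shape builders ----------------------------------------------

digitDisc <- function(r, n = 2 * r + 5, cy = (n + 1) / 2, cx = cy) {
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

digitBall <- function(r, n = 2 * r + 5, c0 = (n + 1) / 2) {
  a <- array(FALSE, c(n, n, n))
  for (z in seq_len(n)) {
    rz2 <- r^2 - (z - c0)^2
    if (rz2 >= 0) a[z, , ] <- digitDisc(sqrt(rz2), n, c0, c0)
  }
  a
}

# seeded random blob: thresholded smoothed noise, guaranteed non-empty
randomBlob <- function(seed, n = 24) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  k <- matrix(1, 5, 5) / 25
  sm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ys <- max(1, i - 2):min(n, i + 2)
    xs <- max(1, j - 2):min(n, j + 2)
    sm[i, j] <- mean(m[ys, xs])
  }
  blob <- sm > quantile(sm, 0.7)
  if (!any(blob)) blob[n %/% 2, n %/% 2] <- TRUE
  blob
}
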