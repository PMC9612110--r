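# Independent oracles used to verify the implementation paths.

# Brute-force moment ellipse: search the major-axis direction on a fine
# angle grid by maximizing the projection variance, independent of the
# closed-form eigendecomposition used by fit_ellipse(). Axis lengths follow
# the same regionprops convention (pixel variance 1/12 added).
oracle_ellipse <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  x <- rc[, 2] - mean(rc[, 2])
  y <- -(rc[, 1] - mean(rc[, 1]))
  angles <- seq(0, 179.75, by = 0.25)
  va <- vapply(angles, function(a) {
    th <- a * pi / 180
    p <- x * cos(th) + y * sin(th)
    sum(p^2) / length(p)
  }, numeric(1))
  i <- which.max(va)
  th <- angles[i] * pi / 180
  perp <- -x * sin(th) + y * cos(th)
  v2 <- sum(perp^2) / length(perp)
  list(major_px = 4 * sqrt(va[i] + 1 / 12),
       minor_px = 4 * sqrt(v2 + 1 / 12),
       angle_deg = angles[i])
}

# Brute-force flood fill from all edge pixels of the pore phase: the set of
# pore pixels connected to the image border (8-connectivity).
oracle_border_connected <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  queue <- which(mask & (row(mask) %in% c(1, H) | col(mask) %in% c(1, W)))
  seen[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      q <- (cc - 1) * H + rr
      if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  seen
}

# Brute-force nearest-marker region growth on the distance map: regions
# start at the marker pixels; at every step the unassigned pore pixel that
# is 8-adjacent to an assigned pixel and has the highest distance-map value
# is claimed by the region of its highest-valued assigned neighbour. A
# naive O(n^2) re-derivation of basin growth, independent of the
# priority-flood implementation.
oracle_nearest_marker <- function(markers, mask, dist) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[markers > 0 & mask] <- markers[markers > 0 & mask]
  nbr <- function(p) {
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    rr <- r + c(-1, 1, 0, 0, -1, -1, 1, 1)
    cc <- c + c(0, 0, -1, 1, -1, 1, -1, 1)
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    (cc[ok] - 1) * H + rr[ok]
  }
  frontier <- integer(0)
  for (p in which(lab > 0)) {
    q <- nbr(p)
    frontier <- union(frontier, q[mask[q] & lab[q] == 0])
  }
  while (length(frontier)) {
    i <- which.max(dist[frontier])   # highest pixel next; ties: first found
    p <- frontier[i]
    frontier <- frontier[-i]
    if (lab[p] > 0) next
    q <- nbr(p)
    qa <- q[lab[q] > 0]
    lab[p] <- lab[qa[which.max(dist[qa])]]
    fresh <- q[mask[q] & lab[q] == 0]
    frontier <- union(frontier, fresh)
  }
  lab
}

# Union of discs, a convenience for segmentation fixtures.
make_discs <- function(centers, radius, canvas) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  for (i in seq_len(nrow(centers)))
    m <- m | rasterize_ellipse(centers[i, ], c(radius, radius), 0, canvas)
  m
}

# Random blob masks (union of random ellipses) for property-style checks.
random_blob_mask <- function(canvas, n_blobs, seed) {
  set.seed(seed)
  m <- matrix(FALSE, canvas[1], canvas[2])
  for (i in seq_len(n_blobs)) {
    a <- runif(1, 4, 10)
    b <- runif(1, 3, a)
    ctr <- c(runif(1, 8, canvas[1] - 8), runif(1, 8, canvas[2] - 8))
    m <- m | rasterize_ellipse(ctr, c(a, b), runif(1, 0, 180), canvas)
  }
  m
}
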