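# Independent oracles, coded naively on purpose: they must share no code
# path with the package implementation they check.

# Exhaustive best-first region growing: a flat neighbour list scanned in
# full at every iteration, differences re-evaluated against the current
# region mean, strict < tolerance admission, lexicographic (i,j,k)
# tie-break.  O(n^2); only for small volumes.
grow_oracle <- function(vol, brain, seed, tolerance) {
  dm <- dim(vol)
  tol <- tolerance * 255
  lexkey <- function(p) ((p[1] - 1) * dm[2] + (p[2] - 1)) * dm[3] + (p[3] - 1)
  region <- array(FALSE, dm)
  queued <- array(FALSE, dm)
  cap <- prod(dm)
  nb <- matrix(0L, cap, 3)
  nn <- 0L
  push_neighbours <- function(p) {
    for (d in list(c(-1L,0L,0L), c(1L,0L,0L), c(0L,-1L,0L),
                   c(0L,1L,0L), c(0L,0L,-1L), c(0L,0L,1L))) {
      q <- p + d
      if (any(q < 1L) || any(q > dm)) next
      if (!brain[q[1], q[2], q[3]] || region[q[1], q[2], q[3]] ||
          queued[q[1], q[2], q[3]]) next
      queued[q[1], q[2], q[3]] <<- TRUE
      nn <<- nn + 1L
      nb[nn, ] <<- q
    }
  }
  p <- as.integer(seed)
  region[p[1], p[2], p[3]] <- TRUE
  total <- vol[p[1], p[2], p[3]]
  count <- 1L
  push_neighbours(p)
  while (nn > 0L) {
    m <- total / count
    act <- nb[seq_len(nn), , drop = FALSE]
    diffs <- abs(vol[act] - m)
    best <- which(diffs == min(diffs))
    if (length(best) > 1L)
      best <- best[which.min(apply(act[best, , drop = FALSE], 1, lexkey))]
    if (!(diffs[best] < tol)) break
    p <- act[best, ]
    nb[best, ] <- nb[nn, ]          # remove by swapping with the last entry
    nn <- nn - 1L
    queued[p[1], p[2], p[3]] <- FALSE
    region[p[1], p[2], p[3]] <- TRUE
    total <- total + vol[p[1], p[2], p[3]]
    count <- count + 1L
    push_neighbours(p)
  }
  region
}

# Dense 3D Gaussian convolution: full product kernel applied voxel by voxel
# over a zero-padded copy (no separability shortcut).
conv_oracle <- function(x, sigma) {
  r <- ceiling(4 * sigma)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(outer(k1, k1), k1)
  dm <- dim(x)
  xp <- array(0, dm + 2 * r)
  xp[r + seq_len(dm[1]), r + seq_len(dm[2]), r + seq_len(dm[3])] <- x
  out <- array(0, dm)
  for (a in seq_len(dm[1])) for (b in seq_len(dm[2])) for (cc in seq_len(dm[3]))
    out[a, b, cc] <- sum(K * xp[a:(a + 2 * r), b:(b + 2 * r), cc:(cc + 2 * r)])
  out
}

# is a voxel set one 6-connected component containing `seed`? (BFS)
is_connected6 <- function(mask, seed) {
  if (!mask[seed[1], seed[2], seed[3]]) return(FALSE)
  dm <- dim(mask)
  seen <- array(FALSE, dm)
  queue <- matrix(as.integer(seed), 1)
  seen[seed[1], seed[2], seed[3]] <- TRUE
  while (nrow(queue)) {
    p <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1L,0L,0L), c(1L,0L,0L), c(0L,-1L,0L),
                   c(0L,1L,0L), c(0L,0L,-1L), c(0L,0L,1L))) {
      q <- p + d
      if (any(q < 1L) || any(q > dm)) next
      if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
        seen[q[1], q[2], q[3]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  identical(seen, mask & TRUE)
}
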