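# Shared fixtures and independent oracles.

# independent Bellman-Ford shortest paths on the 8-connected grid with
# edge cost |P(q) - P(p)| + eps * steplen; written with its own
# neighbour enumeration, no shared code with geodesicDistance()
bellmanFordGeodesic <- function(P, seedMask, eps = 1e-4) {
  H <- nrow(P); W <- ncol(P)
  d <- matrix(Inf, H, W)
  d[seedMask != 0] <- 0
  nbr <- rbind(
    c(-1, -1, sqrt(2)), c(-1, 0, 1), c(-1, 1, sqrt(2)),
    c(0, -1, 1), c(0, 1, 1),
    c(1, -1, sqrt(2)), c(1, 0, 1), c(1, 1, sqrt(2))
  )
  repeat {
    changed <- FALSE
    for (i in seq_len(H)) for (j in seq_len(W)) {
      for (k in seq_len(nrow(nbr))) {
        pi <- i + nbr[k, 1]; pj <- j + nbr[k, 2]
        if (pi < 1 || pi > H || pj < 1 || pj > W) next
        cand <- d[pi, pj] + abs(P[i, j] - P[pi, pj]) + eps * nbr[k, 3]
        if (cand < d[i, j] - 1e-15) { d[i, j] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d
}

# a grayscale step-edge image: left half `lo`, right half `hi`
stepImage <- function(H = 32, W = 32, lo = 50, hi = 200) {
  m <- matrix(lo, H, W)
  m[, (W %/% 2 + 1):W] <- hi
  m
}

# cone-shaped level-set field: negative inside a disk of radius r,
# |grad phi| = 1 away from the centre
conePhi <- function(H, W, centre, r) {
  rr <- matrix(seq_len(H), H, W) - centre[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - centre[2]
  sqrt(rr^2 + cc^2) - r
}

quietPipeline <- function(...) suppressWarnings(runPipeline(...))
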