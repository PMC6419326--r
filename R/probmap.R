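# Foreground probability: Gaussian color models fitted on two sampling
# patches, combined per pixel into a likelihood ratio, then tempered by
# geodesic distances so that spatial connectivity (how much probability
# change a path must cross) decides ambiguous pixels.

# extract the pixels of one patch as an n x C matrix (C = 1 or 3)
.patchPixels <- function(image, patch) {
  stopifnot(is(patch, "PatchSpec"))
  H <- nrow(image); W <- ncol(image)
  r <- patch@row0 + seq_len(patch@height)       # 1-based rows
  c <- patch@col0 + seq_len(patch@width)
  if (min(r) < 1L || max(r) > H || min(c) < 1L || max(c) > W)
    stop(sprintf("%s patch out of image bounds", patch@label))
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    sapply(seq_len(nc), function(k) as.numeric(image[r, c, k]))
  } else {
    matrix(as.numeric(image[r, c]), ncol = 1)
  }
}

#' Fit per-channel Gaussian color models on the two patches
#'
#' Estimates, for each color channel, the sample mean and population
#' standard deviation of the pixel intensities inside the foreground
#' (lesion) and background (healthy skin) patches.  These parameterize
#' the Gaussian densities \code{p(x) = exp(-(x - mu)^2 / (2 sigma^2)) /
#' (sqrt(2 pi) sigma)} used by [pixelLikelihood()].  Standard deviations
#' of degenerate (constant) patches are floored at 1e-3.
#'
#' @param image H x W x C array or H x W matrix in [0, 255].
#' @param fg,bg [PatchSpec-class] rectangles; each must contain at least
#'   100 pixels.
#' @return A [GaussianChannelModel-class].
#' @export
fitGaussianModels <- function(image, fg, bg) {
  if (fg@label != "foreground" || bg@label != "background")
    stop("fg must be a foreground patch and bg a background patch")
  pf <- .patchPixels(image, fg)
  pb <- .patchPixels(image, bg)
  if (nrow(pf) < 100L || nrow(pb) < 100L)
    stop("each patch must contain at least 100 pixels")
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  nc <- ncol(pf)
  mu <- rbind(foreground = colMeans(pf), background = colMeans(pb))
  sd <- rbind(foreground = pmax(apply(pf, 2, popSd), 1e-3),
              background = pmax(apply(pb, 2, popSd), 1e-3))
  colnames(mu) <- colnames(sd) <- paste0("ch", seq_len(nc))
  new("GaussianChannelModel", mean = mu, sd = sd)
}

#' Gaussian density used by the color models
#'
#' @param x intensities.
#' @param mu,sigma mean and standard deviation.
#' @return Density values \code{exp(-(x - mu)^2 / (2 sigma^2)) /
#'   (sqrt(2 pi) sigma)}.
#' @keywords internal
.gaussDensity <- function(x, mu, sigma) {
  stats::dnorm(x, mean = mu, sd = sigma)
}

#' Per-pixel foreground likelihood from the color models
#'
#' For each channel i the normalized likelihood
#' \code{P_i = p_fg(C_i(x)) / (p_fg(C_i(x)) + p_bg(C_i(x)))} is computed
#' (both densities floored at 1e-12), and the channels are combined with
#' non-negative weights summing to 1:
#' \code{P_F = sum_i w_i P_i}.  By construction the background likelihood
#' is its complement, \code{P_B = 1 - P_F}.
#'
#' @param image H x W x C array or H x W matrix in [0, 255].
#' @param model a [GaussianChannelModel-class] with matching channel
#'   count.
#' @param weights per-channel weights, non-negative, summing to 1
#'   (default uniform).
#' @return H x W matrix \code{P_F} with values in [0, 1].
#' @export
pixelLikelihood <- function(image, model, weights = NULL) {
  nc <- if (length(dim(image)) == 3L) dim(image)[3] else 1L
  if (ncol(model@mean) != nc)
    stop(sprintf("model has %d channel(s) but image has %d", ncol(model@mean), nc))
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (length(weights) != nc)
    stop(sprintf("weights must have length %d", nc))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1")
  H <- nrow(image); W <- ncol(image)
  PF <- matrix(0, H, W)
  for (k in seq_len(nc)) {
    ch <- if (nc > 1L || length(dim(image)) == 3L) image[, , k] else image
    df <- pmax(.gaussDensity(ch, model@mean["foreground", k],
                             model@sd["foreground", k]), 1e-12)
    db <- pmax(.gaussDensity(ch, model@mean["background", k],
                             model@sd["background", k]), 1e-12)
    PF <- PF + weights[k] * df / (df + db)
  }
  PF
}

# edge list of the 8-connected grid graph with costs
# |P(q) - P(p)| + eps * steplen; nodes are column-major pixel indices
.gridEdges <- function(P, eps) {
  H <- nrow(P); W <- ncol(P)
  idx <- matrix(seq_len(H * W), H, W)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  step <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (s in step) {
    di <- s[[1]]; dj <- s[[2]]; len <- s[[3]]
    ri <- seq_len(H); ci <- seq_len(W)
    rs <- ri[ri + di >= 1L & ri + di <= H]
    cs <- ci[ci + dj >= 1L & ci + dj <= W]
    a <- idx[rs, cs, drop = FALSE]
    b <- idx[rs + di, cs + dj, drop = FALSE]
    from <- c(from, as.integer(a))
    to <- c(to, as.integer(b))
    wt <- c(wt, abs(P[a] - P[b]) + eps * len)
  }
  list(from = from, to = to, weight = wt)
}

#' Geodesic distance to a seed patch over a probability field
#'
#' Exact shortest-path distance on the 8-connected pixel graph from the
#' set of seed-patch pixels, where each grid step p -> q costs
#' \code{|P_F(q) - P_F(p)| + eps * steplen} (step length 1 axis-aligned,
#' sqrt(2) diagonal).  The first term is the discrete line integral of
#' the probability change along the path -- crossing a region border is
#' expensive -- and the epsilon term is a spatial regularizer and
#' tie-break.  Distances are computed with Dijkstra's algorithm on a
#' graph with a virtual zero-cost source attached to every seed pixel.
#'
#' @param P H x W probability field in [0, 1].
#' @param seed a [PatchSpec-class] (all its pixels are sources) or an
#'   H x W logical/binary matrix of seed pixels.
#' @param eps step-length regularizer weight (default 1e-4).
#' @return H x W non-negative distance field; 0 on the seed pixels.
#' @export
geodesicDistance <- function(P, seed, eps = 1e-4) {
  if (any(P < 0 | P > 1)) stop("P must lie within [0, 1]")
  H <- nrow(P); W <- ncol(P)
  if (is(seed, "PatchSpec")) {
    r <- seed@row0 + seq_len(seed@height)
    c <- seed@col0 + seq_len(seed@width)
    if (min(r) < 1L || max(r) > H || min(c) < 1L || max(c) > W)
      stop("seed patch out of image bounds")
    seedIdx <- as.integer(outer(r, (c - 1L) * H, `+`))
  } else {
    if (!identical(dim(seed), dim(P))) stop("seed mask shape mismatch")
    seedIdx <- which(seed != 0)
    if (length(seedIdx) == 0L) stop("seed set is empty")
  }
  ed <- .gridEdges(P, eps)
  n <- H * W
  src <- n + 1L
  g <- igraph::make_graph(
    edges = rbind(c(ed$from, rep(src, length(seedIdx))),
                  c(ed$to, seedIdx)),
    n = n + 1L, directed = FALSE
  )
  wts <- c(ed$weight, rep(0, length(seedIdx)))
  d <- igraph::distances(g, v = src, weights = wts, algorithm = "dijkstra")
  matrix(as.numeric(d)[seq_len(n)], H, W)
}

#' Combine color likelihood and geodesic distances into a foreground
#' probability
#'
#' Continuous form of the geodesic labeling rule (a pixel is foreground
#' when its geodesic distance to the foreground patch is smaller than to
#' the background patch): \code{s = D_B / (D_F + D_B)}, so \code{s > 0.5}
#' exactly when \code{D_F < D_B}.  Where both distances vanish the color
#' likelihood \code{P_F} is used directly.
#'
#' @param PF H x W color-model likelihood in [0, 1].
#' @param DF,DB H x W non-negative geodesic distances to the foreground
#'   and background patches.
#' @return H x W field \code{s} in [0, 1].
#' @export
combineProbability <- function(PF, DF, DB) {
  if (!identical(dim(PF), dim(DF)) || !identical(dim(PF), dim(DB)))
    stop("field shapes must match")
  if (any(DF < 0) || any(DB < 0)) stop("distances must be non-negative")
  den <- DF + DB
  s <- ifelse(den > 0, DB / den, PF)
  pmin(pmax(s, 0), 1)
}

#' Minimize the probability matrix at the edges
#'
#' Quadratic minimization \code{prob(s) = 2 (s - center)^2}: the field
#' vanishes exactly where the foreground probability equals
#' \code{center}, i.e. along the probabilistic boundary band, and grows
#' toward confident foreground/background.  Multiplying the edge-stop
#' function by this field drives it to zero on the lesion border.  The
#' default center 0.7 places the zero set slightly on the foreground side
#' of the 50/50 line, which suits dermoscopy lesions; 0.5 reproduces the
#' symmetric baseline.
#'
#' @param s H x W foreground probability field in [0, 1].
#' @param center value of s at which prob vanishes, inside (0, 1)
#'   (default 0.7).
#' @return H x W field \code{2 (s - center)^2}, in [0, 2].
#' @examples
#' minimizeProb(matrix(c(0.7, 0.2, 0), 1))  # 0, 0.5, 0.98
#' @export
minimizeProb <- function(s, center = 0.7) {
  if (!is.numeric(center) || length(center) != 1L ||
      center <= 0 || center >= 1)
    stop("'center' must lie inside (0, 1)")
  if (any(s < 0 | s > 1)) stop("s must lie within [0, 1]")
  2 * (s - center)^2
}

#' Fuse the edge indicator with the minimized probability field
#'
#' The robust edge-stop function \code{g_new = g * prob}: it inherits the
#' small values of g at strong intensity edges and additionally vanishes
#' along the probabilistic boundary (where \code{prob = 0}), so the
#' contour stops at fuzzy borders that g alone would leak through.
#' Optionally, values below \code{edgeThreshold} are floored to exactly 0
#' to make weak fused edges fully stopping.
#'
#' @param g H x W edge indicator in (0, 1] (see [edgeIndicator()]).
#' @param prob H x W non-negative minimized probability field (see
#'   [minimizeProb()]).
#' @param edgeThreshold optional absolute threshold; fused values below
#'   it become 0.  Use \code{NULL} (default) for no thresholding, or
#'   \code{TRUE} for the default of 5 percent of the maximum fused value.
#' @return H x W non-negative field \code{g_new}.
#' @export
fuseEdgeIndicator <- function(g, prob, edgeThreshold = NULL) {
  if (!identical(dim(g), dim(prob))) stop("field shapes must match")
  if (any(prob < 0)) stop("prob must be non-negative")
  gnew <- g * prob
  if (!is.null(edgeThreshold)) {
    thr <- if (isTRUE(edgeThreshold)) 0.05 * max(gnew) else edgeThreshold
    gnew[gnew < thr] <- 0
  }
  gnew
}
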