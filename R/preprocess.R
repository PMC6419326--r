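#' Intermeans (Ridler-Calvard) iterative thresholding
#'
#' Computes the global intensity threshold as the fixed point of the
#' intermeans iteration: starting from the global mean, the threshold is
#' repeatedly replaced by the average of the means of the two classes it
#' induces, \code{T <- (mean(x[x <= T]) + mean(x[x > T])) / 2}, until it
#' moves by less than 0.5 intensity units.  On dermoscopy images this
#' coarsely separates the pigmented lesion from the surrounding skin.
#'
#' @param image grayscale H x W matrix in [0, 255].  Convert color input
#'   with [toGrayscale()] first.
#' @param invert by default the darker class is labelled lesion
#'   (pigmented lesions are darker than the surrounding skin); set
#'   \code{TRUE} for bright-on-dark targets.
#' @return A list with \code{threshold} (numeric) and \code{mask}
#'   (integer H x W matrix of {0, 1}, 1 = lesion side).
#' @examples
#' img <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
#' intermeansThreshold(img)$threshold
#' @export
intermeansThreshold <- function(image, invert = FALSE) {
  if (length(dim(image)) != 2L)
    stop("intermeansThreshold expects a grayscale matrix; use toGrayscale()")
  assertRaster(image)
  x <- as.numeric(image)
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    stop("constant image: no bimodal structure to threshold")
  Tk <- mean(x)
  repeat {
    lo <- x[x <= Tk]
    hi <- x[x > Tk]
    # all mass on one side can only happen transiently; nudge back inside
    if (length(lo) == 0L) { Tk <- min(hi); next }
    if (length(hi) == 0L) { Tk <- max(lo) - 0.25; next }
    Tn <- (mean(lo) + mean(hi)) / 2
    if (abs(Tn - Tk) < 0.5) { Tk <- Tn; break }
    Tk <- Tn
  }
  dark <- matrix(as.integer(image <= Tk), nrow(image))
  list(
    threshold = Tk,
    mask = if (invert) 1L - dark else dark
  )
}

#' Automatic foreground/background patch placement
#'
#' Places one rectangular sampling patch on the lesion and one on the
#' healthy skin, given a coarse binary localization mask (typically from
#' [intermeansThreshold()]).  The foreground patch is anchored at the
#' centroid of the largest foreground connected component; among all
#' window positions fully covered by that component (computed exactly
#' with summed-area tables) the one closest to the centroid is chosen,
#' falling back to the maximally covered window when the component
#' cannot contain the patch.  The background patch is anchored at the
#' background pixel farthest from any foreground pixel (Euclidean
#' distance transform, row-major tie-break) and selected the same way
#' among fully background windows, excluding positions that would
#' overlap the foreground patch.  Keeping the patches inside their
#' regions matters: stray opposite-class pixels in a patch contaminate
#' the color models and, worse, act as misplaced geodesic seeds.
#'
#' @param mask integer H x W matrix of {0, 1}; 1 = coarse lesion.
#' @param patchHeight,patchWidth patch extent in pixels (defaults 70 x 90,
#'   the average box size used for dermoscopy color sampling).
#' @return A list with \code{fg} and \code{bg}, both [PatchSpec-class].
#' @export
selectPatches <- function(mask, patchHeight = 70L, patchWidth = 90L) {
  patchHeight <- as.integer(patchHeight); patchWidth <- as.integer(patchWidth)
  H <- nrow(mask); W <- ncol(mask)
  if (patchHeight > H || patchWidth > W)
    stop("patch does not fit inside the image")
  area <- patchHeight * patchWidth
  nfg <- sum(mask != 0); nbg <- sum(mask == 0)
  if (nfg < area)
    stop(sprintf("foreground too small to host a %dx%d patch (%d px)",
                 patchHeight, patchWidth, nfg))
  if (nbg < area)
    stop(sprintf("background too small to host a %dx%d patch (%d px)",
                 patchHeight, patchWidth, nbg))

  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), H))
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  idx <- which(comp, arr.ind = TRUE)
  cen <- colMeans(idx)                      # (row, col), 1-based

  fg <- .bestWindow(comp, patchHeight, patchWidth, cen, exclude = NULL)

  # background anchor: the pixel farthest from any foreground pixel
  dt <- EBImage::distmap(matrix(as.numeric(mask == 0), H))
  far <- which(dt == max(dt))[1]            # row-major tie-break
  anchor <- c((far - 1L) %% H + 1L, (far - 1L) %/% H + 1L)
  bg <- .bestWindow(mask == 0, patchHeight, patchWidth, anchor, exclude = fg)
  if (is.null(bg))
    stop("background too constrained: cannot place a non-overlapping patch")

  list(
    fg = patchSpec(fg[1] - 1L, fg[2] - 1L, patchHeight, patchWidth, "foreground"),
    bg = patchSpec(bg[1] - 1L, bg[2] - 1L, patchHeight, patchWidth, "background")
  )
}

# choose the ph x pw window top-left corner (1-based) maximizing region
# coverage, preferring fully covered windows nearest `target`; windows
# overlapping the `exclude` corner (same size) are skipped
.bestWindow <- function(region, ph, pw, target, exclude = NULL) {
  H <- nrow(region); W <- ncol(region)
  # summed-area table: S[i+1, j+1] = sum(region[1:i, 1:j])
  S <- matrix(0, H + 1L, W + 1L)
  S[-1, -1] <- apply(apply(region + 0, 2, cumsum), 1, cumsum) |> t()
  nr <- H - ph + 1L; nc <- W - pw + 1L
  r <- seq_len(nr); c <- seq_len(nc)
  cnt <- S[r + ph, c + pw, drop = FALSE] - S[r, c + pw, drop = FALSE] -
         S[r + ph, c, drop = FALSE] + S[r, c, drop = FALSE]
  if (!is.null(exclude)) {
    bad_r <- abs(r - exclude[1]) < ph
    bad_c <- abs(c - exclude[2]) < pw
    cnt[bad_r, bad_c] <- -Inf
    if (all(!is.finite(cnt))) return(NULL)
  }
  full <- cnt == ph * pw
  pool <- if (any(full)) which(full) else which(cnt == max(cnt))
  pr <- (pool - 1L) %% nr + 1L
  pc <- (pool - 1L) %/% nr + 1L
  # window center closest to the anchor point
  d2 <- (pr + (ph - 1) / 2 - target[1])^2 + (pc + (pw - 1) / 2 - target[2])^2
  k <- which.min(d2)
  c(pr[k], pc[k])
}

#' Perona-Malik anisotropic diffusion denoising
#'
#' Edge-preserving smoothing: an explicit diffusion scheme whose
#' conduction coefficient decays with the local gradient magnitude, so
#' flat regions are smoothed while strong edges (gradient much larger
#' than \code{gamma}) are left nearly untouched.  Color images are
#' filtered per channel.
#'
#' Two conduction coefficients are available through \code{variant}:
#' \describe{
#'   \item{\code{"as_printed"}}{\code{c = 1 / (1 + sqrt(1 + |grad|^2 / gamma^2))},
#'     bounded above by 1/2; the default.}
#'   \item{\code{"classic"}}{\code{c = 1 / (1 + |grad|^2 / gamma^2)}, the
#'     canonical Perona-Malik rational coefficient.}
#' }
#'
#' @param image H x W matrix or H x W x C array in [0, 255].
#' @param gamma gradient-sensitivity constant on the 8-bit intensity
#'   scale; diffusion stalls where the gradient magnitude greatly
#'   exceeds it.  Default 15.
#' @param nIter number of explicit iterations (default 20).
#' @param dt time step, must be <= 0.25 for 2-D explicit stability
#'   (default 0.2).
#' @param variant conduction coefficient, see Details.
#' @return Filtered image, same shape, clipped to [0, 255].
#' @examples
#' img <- matrix(128, 32, 32)
#' identical(peronaMalik(img), img)
#' @export
peronaMalik <- function(image, gamma = 15, nIter = 20L, dt = 0.2,
                        variant = c("as_printed", "classic")) {
  variant <- match.arg(variant)
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (dt > 0.25) stop("'dt' must be <= 0.25 for explicit-scheme stability")
  if (nIter < 1L) stop("'nIter' must be >= 1")
  assertRaster(image)
  if (length(dim(image)) == 3L) {
    out <- image
    for (k in seq_len(dim(image)[3]))
      out[, , k] <- .pmChannel(image[, , k], gamma, nIter, dt, variant)
    return(out)
  }
  .pmChannel(image, gamma, nIter, dt, variant)
}

# one grayscale channel; 4-neighbour forward differences with replicated
# borders (zero flux across the frame)
.pmChannel <- function(u, gamma, nIter, dt, variant) {
  H <- nrow(u); W <- ncol(u)
  cfun <- if (variant == "as_printed") {
    function(d2) 1 / (1 + sqrt(1 + d2 / gamma^2))
  } else {
    function(d2) 1 / (1 + d2 / gamma^2)
  }
  for (it in seq_len(nIter)) {
    dN <- rbind(u[1, , drop = FALSE], u[-H, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[H, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -W, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, W, drop = FALSE]) - u
    u <- u + dt * (cfun(dN^2) * dN + cfun(dS^2) * dS +
                   cfun(dW^2) * dW + cfun(dE^2) * dE)
  }
  pmin(pmax(u, 0), 255)
}
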