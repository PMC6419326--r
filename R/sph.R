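# SPH over the pixel grid: every pixel is a particle whose mass is its
# (denoised, grayscale) intensity.  A compact-support polynomial kernel
# interpolates the intensity field and its gradient; the gradient
# magnitude plays the role of an edge map.

# radial polynomial exponent: cubic poly6 by default, squared variant
# available for the alternative printed form
.kernExponent <- function(spec) if (spec@exponentAsPrinted) 2L else 3L

# integer stencil offsets (pixel units) whose physical radius is < h
.kernOffsets <- function(spec) {
  hw <- max(1L, as.integer(ceiling(spec@h / spec@spacing)) - 1L)
  d <- expand.grid(di = -hw:hw, dj = -hw:hw)
  r <- spec@spacing * sqrt(d$di^2 + d$dj^2)
  keep <- r < spec@h
  data.frame(di = d$di[keep], dj = d$dj[keep], r = r[keep])
}

# normalization constant
.kernConst <- function(spec) {
  h <- spec@h; n <- .kernExponent(spec)
  if (spec@normalization == "as_printed_3d") {
    315 / (64 * pi * h^9)
  } else {
    off <- .kernOffsets(spec)
    1 / sum((h^2 - off$r^2)^n)
  }
}

#' SPH kernel weight
#'
#' Evaluates the compact-support polynomial kernel
#' \code{W(r) = C (h^2 - r^2)^n} for \code{|r| < h} and 0 otherwise
#' (n = 3 for the default poly6 form).  The kernel satisfies the SPH
#' feasibility conditions: non-negative, even in r, compactly supported,
#' and (under \code{"renormalized_2d"}) unit discrete sum over the
#' support grid.
#'
#' @param r displacement magnitude(s), physical units, >= 0.
#' @param spec an [SPHKernel-class] from [sphKernel()].
#' @return Numeric vector of kernel weights.
#' @examples
#' k <- sphKernel(h = 1, normalization = "as_printed_3d")
#' kernelWeight(0, k)   # 315 / (64 * pi)
#' kernelWeight(1, k)   # 0: support boundary
#' @export
kernelWeight <- function(r, spec) {
  stopifnot(is(spec, "SPHKernel"))
  if (any(r < 0)) stop("'r' must be non-negative")
  h <- spec@h; n <- .kernExponent(spec); C <- .kernConst(spec)
  ifelse(r < h, C * (h^2 - r^2)^n, 0)
}

#' SPH kernel gradient
#'
#' Analytic gradient of [kernelWeight()] with respect to the displacement
#' vector: \code{-2 n C r_vec (h^2 - |r|^2)^(n-1)} inside the support,
#' the zero vector outside.  For the default cubic poly6 form with the
#' 3-D constant this is \code{-(945 / (32 pi h^9)) r_vec (h^2 - |r|^2)^2}.
#' The gradient is antisymmetric: \code{grad(-r) = -grad(r)}.
#'
#' @param rVec numeric length-2 displacement vector, or an n x 2 matrix
#'   of displacement vectors (physical units).
#' @param spec an [SPHKernel-class].
#' @return Gradient vector(s), same shape as \code{rVec}.
#' @export
kernelGradient <- function(rVec, spec) {
  stopifnot(is(spec, "SPHKernel"))
  vec <- is.null(dim(rVec))
  if (vec) rVec <- matrix(rVec, ncol = 2)
  if (ncol(rVec) != 2L) stop("'rVec' must be a 2-vector or n x 2 matrix")
  h <- spec@h; n <- .kernExponent(spec); C <- .kernConst(spec)
  r2 <- rowSums(rVec^2)
  fac <- ifelse(r2 < h^2, -2 * n * C * (h^2 - r2)^(n - 1), 0)
  out <- rVec * fac
  dimnames(out) <- NULL
  if (vec) drop(out) else out
}

# shift matrix by (di, dj) with replicate ("replicate") or zero ("zero")
# handling of the exposed border
.shiftMat <- function(M, di, dj, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  H <- nrow(M); W <- ncol(M)
  ri <- seq_len(H) + di
  cj <- seq_len(W) + dj
  if (pad == "replicate") {
    ri <- pmin(pmax(ri, 1L), H)
    cj <- pmin(pmax(cj, 1L), W)
    M[ri, cj, drop = FALSE]
  } else {
    out <- matrix(0, H, W)
    rok <- ri >= 1L & ri <= H
    cok <- cj >= 1L & cj <= W
    out[rok, cok] <- M[ri[rok], cj[cok], drop = FALSE]
    out
  }
}

#' SPH density field
#'
#' Discrete SPH density: \code{rho(i) = sum_j m_j W(|r_i - r_j|, h)},
#' with each pixel j acting as a particle of mass equal to its intensity
#' and the sum restricted to the kernel's compact support.  Pixels near
#' the image border use truncated neighbourhoods (missing particles
#' contribute nothing).
#'
#' @param image grayscale H x W matrix.
#' @param spec an [SPHKernel-class]; under \code{"renormalized_2d"} a
#'   constant image reproduces its own value at interior pixels.
#' @return H x W numeric density field.
#' @export
sphDensity <- function(image, spec = sphKernel()) {
  if (length(dim(image)) != 2L)
    stop("sphDensity expects a grayscale matrix; use toGrayscale()")
  stopifnot(is(spec, "SPHKernel"))
  off <- .kernOffsets(spec)
  w <- kernelWeight(off$r, spec)
  out <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(off)))
    out <- out + w[k] * .shiftMat(image, off$di[k], off$dj[k], pad = "zero")
  out
}

#' SPH surface-normal (intensity gradient) field
#'
#' Interpolated intensity gradient
#' \code{grad A(r_i) = sum_j m_j grad W(r_i - r_j, h)} over the kernel
#' support, with particle masses equal to pixel intensities.  The border
#' is handled by replicating edge pixels so that constant images yield an
#' exactly zero field and the image frame casts no spurious edge.
#'
#' @param image grayscale H x W matrix (typically the denoised image).
#' @param spec an [SPHKernel-class].
#' @return A list with \code{dr}, \code{dc} (H x W gradient components
#'   along rows and columns) and \code{magnitude} (H x W field,
#'   \code{sqrt(dr^2 + dc^2)}).
#' @export
sphNormalField <- function(image, spec = sphKernel()) {
  if (length(dim(image)) != 2L)
    stop("sphNormalField expects a grayscale matrix; use toGrayscale()")
  stopifnot(is(spec, "SPHKernel"))
  off <- .kernOffsets(spec)
  h <- spec@h; n <- .kernExponent(spec); C <- .kernConst(spec)
  # grad W(r_i - r_j) at r_j = r_i + spacing * d equals
  # +2 n C spacing d (h^2 - r^2)^(n-1)
  fac <- 2 * n * C * spec@spacing * (h^2 - off$r^2)^(n - 1)
  dr <- matrix(0, nrow(image), ncol(image))
  dc <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(off))) {
    if (off$di[k] == 0L && off$dj[k] == 0L) next
    nb <- .shiftMat(image, off$di[k], off$dj[k], pad = "replicate")
    dr <- dr + fac[k] * off$di[k] * nb
    dc <- dc + fac[k] * off$dj[k] * nb
  }
  list(dr = dr, dc = dc, magnitude = sqrt(dr^2 + dc^2))
}

#' Edge indicator function from a gradient-magnitude field
#'
#' Maps a non-negative edge-strength field to the edge-stop function
#' \code{g = 1 / (1 + m^p)}, which equals 1 in flat regions and
#' approaches 0 at strong edges.  By default the magnitude field is first
#' rescaled to [0, scaleMax] by dividing by its 99th percentile (values
#' above it are capped), which makes g insensitive to the kernel
#' normalization convention; set \code{rescale = FALSE} to apply the raw
#' formula.
#'
#' @param magnitude H x W non-negative field (or any numeric array).
#' @param p exponent, 1 or 2 (default 2).
#' @param rescale rescale the magnitudes before applying the formula
#'   (default TRUE).
#' @param scaleMax upper end of the rescaled magnitude range (default 10).
#' @return Field of the same shape with values in (0, 1]; equals 1
#'   exactly where the magnitude is 0.
#' @examples
#' edgeIndicator(matrix(c(0, 1), 1), p = 1, rescale = FALSE)  # 1, 0.5
#' @export
edgeIndicator <- function(magnitude, p = 2, rescale = TRUE, scaleMax = 10) {
  if (!p %in% c(1, 2)) stop("'p' must be 1 or 2")
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("magnitudes must be finite and non-negative")
  m <- magnitude
  if (rescale) {
    q <- stats::quantile(m, 0.99, names = FALSE)
    m <- if (q > 0) pmin(m / q, 1) * scaleMax else m * 0
  }
  1 / (1 + m^p)
}
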