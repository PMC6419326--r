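# Seeded generator of dermoscopy-like images with known ground truth:
# a roughly elliptical darker lesion on lighter skin, with controllable
# boundary fuzziness, contrast, background noise, and hair strokes.
# Exercises the failure modes border detection must survive -- fuzzy
# borders, low lesion/skin contrast, and curvilinear artifacts.

#' Construct a synthetic lesion specification
#'
#' @param height,width image size (default 224 x 224, the smallest
#'   square canvas on which a centered lesion leaves room for two
#'   non-overlapping 70 x 90 sampling patches).
#' @param center lesion center (row, col); default the image center.
#' @param semiAxes ellipse semi-axes (row, col) in pixels (default
#'   c(58, 70), sized so a 70 x 90 sampling window fits fully inside the
#'   lesion even at the default boundary irregularity).
#' @param irregularity relative amplitude of the smooth radial boundary
#'   perturbation (default 0.08).
#' @param blurSigma boundary blur in pixels; 0 gives a hard color step
#'   (default 0).
#' @param lesionColor,bgColor mean RGB colors (defaults mimic a
#'   pigmented lesion, c(110, 70, 60), on light skin, c(200, 160, 140)).
#' @param noiseSd per-channel i.i.d. Gaussian noise sd (default 8).
#' @param hairCount number of dark curvilinear hair strokes (default 0).
#' @param hairDarkness intensity subtracted along hairs (default 70).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return A [LesionSpec-class].
#' @export
lesionSpec <- function(height = 224L, width = 224L,
                       center = c(height / 2, width / 2),
                       semiAxes = c(58, 70), irregularity = 0.08,
                       blurSigma = 0,
                       lesionColor = c(110, 70, 60),
                       bgColor = c(200, 160, 140),
                       noiseSd = 8, hairCount = 0L, hairDarkness = 70,
                       seed = 1L) {
  new("LesionSpec",
    height = as.integer(height), width = as.integer(width),
    center = as.numeric(center), semiAxes = as.numeric(semiAxes),
    irregularity = as.numeric(irregularity),
    blurSigma = as.numeric(blurSigma),
    lesionColor = as.numeric(lesionColor), bgColor = as.numeric(bgColor),
    noiseSd = as.numeric(noiseSd), hairCount = as.integer(hairCount),
    hairDarkness = as.numeric(hairDarkness), seed = as.integer(seed)
  )
}

# run expr with a private RNG stream seeded at `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# separable Gaussian blur with replicate padding
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (k in -r:r) {
    ri <- pmin(pmax(seq_len(H) + k, 1L), H)
    out <- out + w[k + r + 1L] * m[ri, , drop = FALSE]
  }
  m <- out
  out <- matrix(0, H, W)
  for (k in -r:r) {
    cj <- pmin(pmax(seq_len(W) + k, 1L), W)
    out <- out + w[k + r + 1L] * m[, cj, drop = FALSE]
  }
  out
}

#' Generate a synthetic dermoscopy image with ground truth
#'
#' The ground truth is the set of pixels inside the radially perturbed
#' ellipse.  The image is built per channel as
#' \code{background + (lesion - background) * softMask + noise}, where
#' the soft mask is the truth mask blurred with a Gaussian of sd
#' \code{blurSigma} (boundary fuzziness), plus dark hair strokes drawn
#' as random cubic Bezier arcs of width 1-3 px.  Output is fully
#' determined by the spec, including its seed.
#'
#' @param spec a [LesionSpec-class].
#' @return List with \code{image} (H x W x 3 array in [0, 255]) and
#'   \code{truth} (integer H x W mask).
#' @export
generateLesion <- function(spec) {
  stopifnot(is(spec, "LesionSpec"))
  validObject(spec)
  .withSeed(spec@seed, {
    H <- spec@height; W <- spec@width
    rr <- matrix(seq_len(H), H, W) - spec@center[1]
    cc <- matrix(seq_len(W), H, W, byrow = TRUE) - spec@center[2]
    u <- rr / spec@semiAxes[1]
    v <- cc / spec@semiAxes[2]
    rho <- sqrt(u^2 + v^2)
    # smooth radial perturbation: low-order random harmonics, scaled so
    # the relative boundary excursion never exceeds `irregularity`
    theta <- atan2(v, u)
    pert <- matrix(0, H, W)
    if (spec@irregularity > 0) {
      amp <- stats::rnorm(4)
      phs <- stats::runif(4, 0, 2 * pi)
      raw <- matrix(0, H, W)
      for (k in seq_along(amp))
        raw <- raw + amp[k] * cos((k + 1) * theta + phs[k])
      pert <- spec@irregularity * raw / max(abs(raw))
    }
    truth <- matrix(as.integer(rho <= 1 + pert), H, W)
    soft <- .gaussBlur(truth + 0, spec@blurSigma)

    hair <- if (spec@hairCount > 0L) .hairMask(H, W, spec@hairCount) else NULL
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- spec@bgColor[ch] +
        (spec@lesionColor[ch] - spec@bgColor[ch]) * soft
      if (spec@noiseSd > 0)
        plane <- plane + matrix(stats::rnorm(H * W, sd = spec@noiseSd), H, W)
      if (!is.null(hair)) plane <- plane - spec@hairDarkness * hair
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(image = img, truth = truth)
  })
}

# binary mask of `n` random cubic Bezier arcs of width 1-3 px
.hairMask <- function(H, W, n) {
  mask <- matrix(0, H, W)
  for (i in seq_len(n)) {
    P <- cbind(stats::runif(4, 1, H), stats::runif(4, 1, W))
    t <- seq(0, 1, length.out = 4L * (H + W))
    b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t
    b2 <- 3 * (1 - t) * t^2; b3 <- t^3
    pr <- b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1]
    pc <- b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2]
    wdt <- sample(1:3, 1L)
    off <- expand.grid(dr = -1:1, dc = -1:1)
    off <- off[sqrt(off$dr^2 + off$dc^2) <= wdt / 2, , drop = FALSE]
    for (k in seq_len(nrow(off))) {
      r <- round(pr) + off$dr[k]
      c <- round(pc) + off$dc[k]
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      mask[cbind(r[ok], c[ok])] <- 1
    }
  }
  mask
}

#' Fixed battery of synthetic test fixtures
#'
#' Generates twelve images -- six difficulty classes by two seeds --
#' spanning the challenge cases for border detection: a sharp
#' high-contrast lesion, fuzzy boundaries (blur 4, 8, and 12 px, the
#' heavier blurs combined with reduced contrast), a low-contrast lesion
#' (channel difference <= 30), and a heavily haired fuzzy lesion.  The
#' heavy-blur and low-contrast classes carry a few hair strokes, the
#' artifact load under which a plain gradient edge-stop function loses
#' its scale and the contour leaks through the fuzzy border.
#'
#' @param seed integer; fixture seeds are derived from it.
#' @return A list of twelve elements, each with \code{image},
#'   \code{truth}, \code{tag}, and \code{spec}.
#' @export
fixtureSuite <- function(seed = 1L) {
  classes <- list(
    sharp      = list(blurSigma = 0,  lesionColor = c(110, 70, 60),  hairCount = 0L),
    fuzzy_s4   = list(blurSigma = 4,  lesionColor = c(160, 120, 100), hairCount = 0L),
    fuzzy_s8   = list(blurSigma = 8,  lesionColor = c(170, 130, 110), hairCount = 3L),
    fuzzy_s12  = list(blurSigma = 12, lesionColor = c(170, 130, 110), hairCount = 3L),
    lowcontrast = list(blurSigma = 4, lesionColor = c(175, 135, 115), hairCount = 3L),
    fuzzy_hairy = list(blurSigma = 8, lesionColor = c(160, 120, 100), hairCount = 6L)
  )
  out <- list()
  i <- 0L
  for (tag in names(classes)) {
    for (rep in 1:2) {
      i <- i + 1L
      cl <- classes[[tag]]
      sp <- lesionSpec(
        blurSigma = cl$blurSigma, lesionColor = cl$lesionColor,
        hairCount = cl$hairCount,
        seed = (as.integer(seed) * 131L + i) %% .Machine$integer.max
      )
      gen <- generateLesion(sp)
      out[[i]] <- list(image = gen$image, truth = gen$truth,
                       tag = tag, spec = sp)
    }
  }
  out
}
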