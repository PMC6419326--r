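# End-to-end orchestration: threshold -> patches -> denoise -> SPH edge
# features -> probability map -> fused edge-stop function -> level set.

#' Default pipeline configuration
#'
#' Nested configuration for all pipeline stages.  Every value can be
#' overridden by passing a nested list, e.g.
#' \code{pipelineConfig(list(prob = list(center = 0.5)))}; unknown keys
#' are rejected with their full path named.
#'
#' @param overrides nested list of values to override.
#' @return A nested list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(overrides = list()) {
  cfg <- list(
    preprocess = list(
      gamma = 15, nIter = 20L, dt = 0.2, variant = "as_printed",
      invert = FALSE, patchHeight = 70L, patchWidth = 90L
    ),
    sph = list(
      h = 1, normalization = "renormalized_2d", exponentAsPrinted = FALSE,
      spacing = 0.5, p = 2L, rescale = TRUE, scaleMax = 10
    ),
    prob = list(
      center = 0.7, channelWeights = c(1, 1, 1) / 3,
      edgeThreshold = 0, connectivity = 8L, eps = 1e-4,
      useGeodesic = TRUE
    ),
    levelSet = list(
      tau1 = 0.3, tau2 = 0.01, v = 0.7, mu = 0.5, lambda = 5,
      beta = 1.5, epsDirac = 2.5, c0 = 2, maxIter = 500L,
      areaTol = 10, areaWindow = 10L, initSmooth = 8L, reaction = "merged"
    ),
    output = list(esf = "fused")
  )
  cfg <- .mergeConfig(cfg, overrides, path = "")
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

.mergeConfig <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  if (is.null(names(over)) || any(names(over) == ""))
    stop(sprintf("config overrides at '%s' must be a named list",
                 if (nzchar(path)) path else "<root>"))
  for (k in names(over)) {
    p <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop(sprintf("unknown config key: '%s'", p))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- .mergeConfig(base[[k]], over[[k]], p)
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' @param cfg a \code{PipelineConfig}.
#' @return \code{cfg}, invisibly, or an error naming the offending key.
#' @export
validatePipelineConfig <- function(cfg) {
  with(cfg$preprocess, {
    if (gamma <= 0) stop("preprocess.gamma must be positive")
    if (dt <= 0 || dt > 0.25) stop("preprocess.dt must be in (0, 0.25]")
    if (!variant %in% c("as_printed", "classic"))
      stop("preprocess.variant must be 'as_printed' or 'classic'")
  })
  with(cfg$sph, {
    if (h <= 0) stop("sph.h must be positive")
    if (!p %in% c(1, 2)) stop("sph.p must be 1 or 2")
    if (!normalization %in% c("renormalized_2d", "as_printed_3d"))
      stop("sph.normalization invalid")
  })
  with(cfg$prob, {
    if (center <= 0 || center >= 1) stop("prob.center must lie inside (0, 1)")
    if (abs(sum(channelWeights) - 1) > 1e-6 || any(channelWeights < 0))
      stop("prob.channelWeights must be non-negative and sum to 1")
    if (connectivity != 8L) stop("only 8-connectivity is implemented")
  })
  with(cfg$levelSet, {
    if (tau1 <= 0 || tau2 <= 0) stop("levelSet time steps must be positive")
    if (tau2 > 0.1) stop("levelSet.tau2 must be <= 0.1")
    if (!reaction %in% c("merged", "as_printed"))
      stop("levelSet.reaction must be 'merged' or 'as_printed'")
  })
  if (!cfg$output$esf %in% c("fused", "plain"))
    stop("output.esf must be 'fused' or 'plain'")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The file stores only nested key-value pairs; reading merges them onto
#' the defaults and rejects unknown keys with their path named, so a
#' written config reads back to an identical object.
#'
#' @param path YAML file path.
#' @return For \code{readPipelineConfig}, a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param cfg a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
}

# bounding box of the largest foreground component, dilated and clipped;
# returned as c(row0, col0, height, width), 0-based
.initRectangle <- function(mask, dilate = 10L) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask)))
  sizes <- tabulate(lab[lab > 0])
  idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - dilate); r1 <- min(nrow(mask), max(idx[, 1]) + dilate)
  c0 <- max(1L, min(idx[, 2]) - dilate); c1 <- min(ncol(mask), max(idx[, 2]) + dilate)
  # keep at least one exterior pixel so the initial contour exists
  if (r0 == 1L && c0 == 1L && r1 == nrow(mask) && c1 == ncol(mask)) {
    r0 <- 2L; c0 <- 2L; r1 <- nrow(mask) - 1L; c1 <- ncol(mask) - 1L
  }
  c(r0 - 1L, c0 - 1L, r1 - r0 + 1L, c1 - c0 + 1L)
}

#' Run the full border-detection pipeline
#'
#' Executes the stages in order: intermeans coarse localization,
#' foreground/background patch placement (unless patches are supplied),
#' Perona-Malik denoising, SPH surface-normal edge extraction and the
#' edge indicator g, Gaussian color models and the geodesic probability
#' map, probability minimization and fusion into the robust edge-stop
#' function g_new, and reaction-diffusion level-set evolution from the
#' dilated coarse-lesion bounding box.
#'
#' @param image H x W x 3 array or H x W matrix in [0, 255], at least
#'   64 x 64.
#' @param cfg a [pipelineConfig()].
#' @param fg,bg optional [PatchSpec-class] rectangles; when omitted they
#'   are placed automatically from the coarse mask.
#' @param verbose log per-iteration contour area.
#' @param saveIntermediate optional directory; when given, the
#'   intermediate fields (g, P_F, s, prob, g_new) are written there as
#'   32-bit float TIFF together with the initialization rectangle.
#' @return A [SegmentationResult-class] whose diagnostics record the
#'   threshold, patch specs and origin, ESF mode, iteration count, final
#'   area, and convergence flag.
#' @examples
#' \donttest{
#' fx <- generateLesion(lesionSpec(seed = 7L))
#' res <- runPipeline(fx$image)
#' diceCoefficient(maskOf(res), fx$truth)
#' }
#' @export
runPipeline <- function(image, cfg = pipelineConfig(), fg = NULL, bg = NULL,
                        verbose = FALSE, saveIntermediate = NULL) {
  .stage("input", assertRaster(image, minSize = 64L))
  pp <- cfg$preprocess
  gray <- toGrayscale(image)
  thr <- .stage("intermeans", intermeansThreshold(gray, invert = pp$invert))

  # thin dark artifacts (hairs) survive thresholding and would inflate
  # the coarse lesion footprint; a small morphological opening removes
  # them from the localization mask only (the segmentation itself never
  # sees this mask)
  coarse <- EBImage::opening(matrix(as.numeric(thr$mask), nrow(thr$mask)),
                             EBImage::makeBrush(5, "disc"))
  coarse <- matrix(as.integer(coarse > 0), nrow(thr$mask))
  if (sum(coarse) == 0L) coarse <- thr$mask

  userPatches <- !is.null(fg) && !is.null(bg)
  if (!userPatches) {
    # small coarse lesions cannot host the full-size sampling patch;
    # shrink the window (keeping its aspect) until placement succeeds
    ph <- pp$patchHeight; pw <- pp$patchWidth
    pat <- NULL
    while (is.null(pat)) {
      pat <- tryCatch(selectPatches(coarse, ph, pw), error = function(e) NULL)
      if (is.null(pat)) {
        ph <- as.integer(floor(ph * 0.8)); pw <- as.integer(floor(pw * 0.8))
        if (ph < 12L || pw < 12L)
          .stage("patches", selectPatches(coarse, pp$patchHeight,
                                          pp$patchWidth))  # raise original
      }
    }
    fg <- pat$fg; bg <- pat$bg
  }

  den <- .stage("denoise",
    peronaMalik(image, gamma = pp$gamma, nIter = pp$nIter, dt = pp$dt,
                variant = pp$variant))

  kern <- sphKernel(h = cfg$sph$h, normalization = cfg$sph$normalization,
                    exponentAsPrinted = cfg$sph$exponentAsPrinted,
                    spacing = cfg$sph$spacing)
  nf <- .stage("sph", sphNormalField(toGrayscale(den), kern))
  g <- .stage("sph", edgeIndicator(nf$magnitude, p = cfg$sph$p,
                                   rescale = cfg$sph$rescale,
                                   scaleMax = cfg$sph$scaleMax))

  nchan <- if (length(dim(den)) == 3L) dim(den)[3] else 1L
  wts <- cfg$prob$channelWeights
  if (length(wts) != nchan) wts <- rep(1 / nchan, nchan)
  model <- .stage("probmap", fitGaussianModels(den, fg, bg))
  PF <- .stage("probmap", pixelLikelihood(den, model, wts))
  DF <- .stage("probmap", geodesicDistance(PF, fg, eps = cfg$prob$eps))
  DB <- .stage("probmap", geodesicDistance(PF, bg, eps = cfg$prob$eps))
  s <- .stage("probmap", combineProbability(PF, DF, DB))
  probSrc <- if (isTRUE(cfg$prob$useGeodesic)) s else PF
  prob <- .stage("probmap", minimizeProb(probSrc, center = cfg$prob$center))

  esf <- cfg$output$esf
  gnew <- if (esf == "fused") {
    thrE <- cfg$prob$edgeThreshold
    .stage("fuse", fuseEdgeIndicator(g, prob,
      edgeThreshold = if (thrE > 0) thrE else NULL))
  } else g

  rect <- .initRectangle(coarse)
  ls <- cfg$levelSet
  lsCfg <- evolutionConfig(
    tau1 = ls$tau1, tau2 = ls$tau2, v = ls$v, mu = ls$mu,
    lambda = ls$lambda, beta = ls$beta, epsDirac = ls$epsDirac,
    c0 = ls$c0, maxIter = ls$maxIter, areaTol = ls$areaTol,
    areaWindow = ls$areaWindow, initSmooth = ls$initSmooth,
    reaction = ls$reaction
  )
  phi0 <- .stage("levelset", initializePhi(dim(gray), rect, c0 = ls$c0))
  res <- .stage("levelset",
    evolveContour(phi0, gnew, lsCfg, initRect = rect, verbose = verbose))

  if (!is.null(saveIntermediate)) {
    dir.create(saveIntermediate, showWarnings = FALSE, recursive = TRUE)
    writeFloatTiff(g, file.path(saveIntermediate, "g.tif"))
    writeFloatTiff(PF, file.path(saveIntermediate, "pf.tif"))
    writeFloatTiff(s, file.path(saveIntermediate, "s.tif"))
    writeFloatTiff(prob, file.path(saveIntermediate, "prob.tif"))
    writeFloatTiff(gnew, file.path(saveIntermediate, "g_new.tif"))
    jsonlite::write_json(
      list(initRect = rect, c0 = ls$c0),
      file.path(saveIntermediate, "levelset_input.json"),
      auto_unbox = TRUE
    )
  }

  res@diagnostics <- list(
    threshold = thr$threshold,
    fg = patchToList(fg), bg = patchToList(bg),
    patches = if (userPatches) "user" else "auto",
    esf = esf,
    initRect = rect,
    iterations = res@iterations,
    finalArea = sum(res@mask),
    converged = res@converged
  )
  res
}

#' Serialize a PatchSpec to a plain list / JSON
#'
#' @param patch a [PatchSpec-class].
#' @return Named list with \code{label}, \code{row0}, \code{col0},
#'   \code{height}, \code{width} (0-based, end-exclusive).
#' @export
patchToList <- function(patch) {
  list(label = patch@label, row0 = patch@row0, col0 = patch@col0,
       height = patch@height, width = patch@width)
}

#' @rdname patchToList
#' @param x a named list as produced by \code{patchToList} (or parsed
#'   from JSON).
#' @return For \code{patchFromList}, a [PatchSpec-class].
#' @export
patchFromList <- function(x) {
  patchSpec(x$row0, x$col0, x$height, x$width, x$label)
}
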