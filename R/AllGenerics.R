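#' Binary mask accessor
#'
#' @param object an object carrying a segmentation mask.
#' @return An integer H x W matrix of {0, 1}.
#' @export
setGeneric("maskOf", function(object) standardGeneric("maskOf"))

#' Enclosed-area history accessor
#'
#' @param object a [SegmentationResult-class].
#' @return Numeric vector of the contour's enclosed area (pixels with
#'   phi < 0) at each iteration.
#' @export
setGeneric("areaHistory", function(object) standardGeneric("areaHistory"))

#' Stage diagnostics accessor
#'
#' @param object a [SegmentationResult-class].
#' @return Named list of pipeline diagnostics.
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname maskOf
#' @export
setMethod("maskOf", "SegmentationResult", function(object) object@mask)

#' @rdname areaHistory
#' @export
setMethod("areaHistory", "SegmentationResult", function(object) object@areaHistory)

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "SegmentationResult", function(object) object@diagnostics)

#' @describeIn PatchSpec-class compact one-line display.
#' @param object a \code{PatchSpec}.
#' @export
setMethod("show", "PatchSpec", function(object) {
  cat(sprintf(
    "PatchSpec <%s> rows %d..%d, cols %d..%d (%dx%d)\n",
    object@label, object@row0, object@row0 + object@height - 1L,
    object@col0, object@col0 + object@width - 1L,
    object@height, object@width
  ))
})

#' @describeIn SPHKernel-class compact display.
#' @param object an \code{SPHKernel}.
#' @export
setMethod("show", "SPHKernel", function(object) {
  cat(sprintf(
    "SPHKernel poly6: h = %g, normalization = %s, exponent = %s, spacing = %g\n",
    object@h, object@normalization,
    if (object@exponentAsPrinted) "squared (as printed)" else "cubic",
    object@spacing
  ))
})

#' @describeIn GaussianChannelModel-class per-channel summary table.
#' @param object a \code{GaussianChannelModel}.
#' @export
setMethod("show", "GaussianChannelModel", function(object) {
  cat("GaussianChannelModel (", ncol(object@mean), " channel",
      if (ncol(object@mean) > 1L) "s", ")\n", sep = "")
  cat("  means:\n"); print(round(object@mean, 2))
  cat("  sds:\n"); print(round(object@sd, 2))
})

#' @describeIn SegmentationResult-class summary of the evolution outcome.
#' @param object a \code{SegmentationResult}.
#' @export
setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %dx%d mask, lesion area %d px, %d iteration%s, %s\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    object@iterations, if (object@iterations == 1L) "" else "s",
    if (object@converged) "converged (area-change rule)" else "stopped at maxIter"
  ))
})

#' @describeIn LesionSpec-class compact display.
#' @param object a \code{LesionSpec}.
#' @export
setMethod("show", "LesionSpec", function(object) {
  cat(sprintf(
    "LesionSpec %dx%d: center (%g, %g), semi-axes (%g, %g), blur %g px, %d hair(s), seed %d\n",
    object@height, object@width, object@center[1], object@center[2],
    object@semiAxes[1], object@semiAxes[2], object@blurSigma,
    object@hairCount, object@seed
  ))
})
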