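#' @import methods
NULL

#' Axis-aligned rectangular patch
#'
#' A \code{PatchSpec} is an axis-aligned rectangle on the pixel grid,
#' 0-based and end-exclusive (a patch with \code{row0 = 0, height = 70}
#' covers rows 0..69), tagged as sampling the lesion (\code{"foreground"})
#' or the healthy skin (\code{"background"}).  Patches feed the Gaussian
#' color models and seed the geodesic distance transforms.
#'
#' @slot row0 integer(1), top row (0-based).
#' @slot col0 integer(1), left column (0-based).
#' @slot height integer(1), vertical extent in pixels.
#' @slot width integer(1), horizontal extent in pixels.
#' @slot label character(1), \code{"foreground"} or \code{"background"}.
#'
#' @seealso [patchSpec()], [selectPatches()]
#' @exportClass PatchSpec
setClass("PatchSpec",
  slots = c(
    row0 = "integer", col0 = "integer",
    height = "integer", width = "integer",
    label = "character"
  )
)

setValidity("PatchSpec", function(object) {
  msg <- character()
  if (length(object@label) != 1L ||
      !object@label %in% c("foreground", "background"))
    msg <- c(msg, "label must be 'foreground' or 'background'")
  for (s in c("row0", "col0", "height", "width")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, sprintf("%s must be a single integer", s))
  }
  if (length(msg) == 0L) {
    if (object@row0 < 0L || object@col0 < 0L)
      msg <- c(msg, "row0 and col0 must be non-negative")
    if (object@height < 1L || object@width < 1L)
      msg <- c(msg, "height and width must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatchSpec
#'
#' @param row0,col0 top-left pixel of the rectangle, 0-based.
#' @param height,width rectangle extent in pixels (end-exclusive).
#' @param label \code{"foreground"} (lesion) or \code{"background"}
#'   (healthy tissue).
#' @return A [PatchSpec-class] object.
#' @examples
#' patchSpec(10, 20, 70, 90, "foreground")
#' @export
patchSpec <- function(row0, col0, height, width,
                      label = c("foreground", "background")) {
  label <- match.arg(label)
  new("PatchSpec",
    row0 = as.integer(row0), col0 = as.integer(col0),
    height = as.integer(height), width = as.integer(width),
    label = label
  )
}

#' SPH interpolation kernel
#'
#' Specification of the compact-support polynomial ("poly6") smoothing
#' kernel used for particle interpolation over the pixel grid.  The kernel
#' is radially symmetric, non-negative, even, and identically zero for
#' radii at or beyond the smoothing length \code{h} -- the feasibility
#' conditions for an SPH kernel.
#'
#' Two normalizations are available: \code{"as_printed_3d"} keeps the
#' three-dimensional closed-form constant 315 / (64 pi h^9), while
#' \code{"renormalized_2d"} (the default for density interpretation)
#' divides by the discrete sum of kernel weights over the support grid so
#' that interpolating a constant field reproduces the constant.
#'
#' \code{exponentAsPrinted = TRUE} switches the radial polynomial from the
#' cubic \code{(h^2 - r^2)^3} (the poly6 form the normalization constant
#' belongs to) to the squared variant \code{(h^2 - r^2)^2}.
#'
#' @slot h numeric(1), smoothing length in physical units (positive).
#' @slot family character(1), currently \code{"poly6"}.
#' @slot normalization character(1), \code{"renormalized_2d"} or
#'   \code{"as_printed_3d"}.
#' @slot exponentAsPrinted logical(1), use the squared radial polynomial.
#' @slot spacing numeric(1), physical distance between adjacent pixels
#'   (grid pitch) used when the kernel is sampled on the image lattice.
#'
#' @seealso [sphKernel()], [kernelWeight()], [sphNormalField()]
#' @exportClass SPHKernel
setClass("SPHKernel",
  slots = c(
    h = "numeric", family = "character", normalization = "character",
    exponentAsPrinted = "logical", spacing = "numeric"
  )
)

setValidity("SPHKernel", function(object) {
  msg <- character()
  if (length(object@h) != 1L || !is.finite(object@h) || object@h <= 0)
    msg <- c(msg, "h must be a single positive number")
  if (!identical(object@family, "poly6"))
    msg <- c(msg, "only the 'poly6' kernel family is implemented")
  if (!object@normalization %in% c("renormalized_2d", "as_printed_3d"))
    msg <- c(msg, "normalization must be 'renormalized_2d' or 'as_printed_3d'")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an SPH kernel specification
#'
#' @param h smoothing length (support radius) in physical units; the
#'   kernel vanishes for radii \code{>= h}.  Default 1.
#' @param normalization \code{"renormalized_2d"} (discrete unit sum over
#'   the support grid; default) or \code{"as_printed_3d"} (closed-form 3-D
#'   constant 315 / (64 pi h^9)).
#' @param exponentAsPrinted logical; use the squared radial polynomial
#'   \code{(h^2 - r^2)^2} instead of the default cubic poly6 form.
#' @param spacing physical distance between adjacent pixels.  The default
#'   0.5 places first-order pixel neighbours inside the unit support, so
#'   \code{h = 1} yields a 3x3 interpolation stencil.
#' @return An [SPHKernel-class] object.
#' @examples
#' k <- sphKernel(h = 1)
#' kernelWeight(0, k)
#' @export
sphKernel <- function(h = 1,
                      normalization = c("renormalized_2d", "as_printed_3d"),
                      exponentAsPrinted = FALSE, spacing = 0.5) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive number")
  normalization <- match.arg(normalization)
  new("SPHKernel",
    h = as.numeric(h), family = "poly6", normalization = normalization,
    exponentAsPrinted = isTRUE(exponentAsPrinted),
    spacing = as.numeric(spacing)
  )
}

#' Per-channel Gaussian color models of lesion and skin
#'
#' Sample mean and (population) standard deviation of the pixel
#' intensities inside the foreground and background patches, one pair per
#' color channel.  Standard deviations are floored at 1e-3 so degenerate
#' (constant) patches still yield a proper density.
#'
#' @slot mean numeric matrix, 2 x C, rows \code{foreground} /
#'   \code{background}, one column per channel.
#' @slot sd numeric matrix, same shape, strictly positive.
#'
#' @seealso [fitGaussianModels()], [pixelLikelihood()]
#' @exportClass GaussianChannelModel
setClass("GaussianChannelModel",
  slots = c(mean = "matrix", sd = "matrix")
)

setValidity("GaussianChannelModel", function(object) {
  msg <- character()
  if (!identical(dim(object@mean), dim(object@sd)))
    msg <- c(msg, "mean and sd must have the same shape")
  if (nrow(object@mean) != 2L ||
      !identical(rownames(object@mean), c("foreground", "background")))
    msg <- c(msg, "rows must be named 'foreground', 'background'")
  if (any(!is.finite(object@sd)) || any(object@sd <= 0))
    msg <- c(msg, "all standard deviations must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Synthetic dermoscopy lesion specification
#'
#' Parameters of the seeded generator: a roughly elliptical darker lesion
#' on a lighter skin-toned background, with a smooth radial boundary
#' perturbation, controllable boundary blur (fuzziness), per-channel
#' Gaussian noise, and dark curvilinear hair strokes.
#'
#' @slot height,width integer(1), image size in pixels.
#' @slot center numeric(2), lesion center (row, col).
#' @slot semiAxes numeric(2), ellipse semi-axes (row, col) in pixels.
#' @slot irregularity numeric(1), relative amplitude of the smooth radial
#'   boundary perturbation (0 = perfect ellipse).
#' @slot blurSigma numeric(1), Gaussian blur of the lesion/skin transition
#'   in pixels (boundary fuzziness).
#' @slot lesionColor,bgColor numeric(3), mean RGB colors in [0, 255].
#' @slot noiseSd numeric(1), per-channel i.i.d. Gaussian noise sd.
#' @slot hairCount integer(1), number of hair strokes.
#' @slot hairDarkness numeric(1), intensity subtracted along hairs.
#' @slot seed integer(1), RNG seed; the generator is a pure function of
#'   the spec including this seed.
#'
#' @seealso [lesionSpec()], [generateLesion()], [fixtureSuite()]
#' @exportClass LesionSpec
setClass("LesionSpec",
  slots = c(
    height = "integer", width = "integer",
    center = "numeric", semiAxes = "numeric",
    irregularity = "numeric", blurSigma = "numeric",
    lesionColor = "numeric", bgColor = "numeric",
    noiseSd = "numeric", hairCount = "integer",
    hairDarkness = "numeric", seed = "integer"
  )
)

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (object@height < 64L || object@width < 64L)
    msg <- c(msg, "image must be at least 64x64")
  if (length(object@center) != 2L || length(object@semiAxes) != 2L)
    msg <- c(msg, "center and semiAxes must have length 2")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@lesionColor) != 3L || length(object@bgColor) != 3L ||
      any(object@lesionColor < 0 | object@lesionColor > 255) ||
      any(object@bgColor < 0 | object@bgColor > 255))
    msg <- c(msg, "colors must be RGB triples within [0, 255]")
  if (length(msg) == 0L) {
    # the perturbed ellipse must stay >= 10 px inside the frame
    reach <- object@semiAxes * (1 + object@irregularity)
    if (object@center[1] - reach[1] < 10 ||
        object@center[1] + reach[1] > object@height - 10 ||
        object@center[2] - reach[2] < 10 ||
        object@center[2] + reach[2] > object@width - 10)
      msg <- c(msg, "lesion must lie fully inside the image with a 10 px margin")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a level-set segmentation
#'
#' Holds the final binary lesion mask together with the evolution
#' diagnostics: the per-iteration enclosed-area history, the iteration
#' count, and whether the area-change stopping rule fired before the
#' iteration cap.
#'
#' @slot mask integer matrix of {0, 1}; 1 = lesion.
#' @slot phi numeric matrix, the final level-set field.
#' @slot areaHistory numeric vector, pixels with phi < 0 at each iteration.
#' @slot iterations integer(1), iterations performed.
#' @slot converged logical(1), TRUE when the area-change rule stopped the
#'   evolution before \code{maxIter}.
#' @slot diagnostics list of stage diagnostics (threshold, patches, ...).
#'
#' @seealso [evolveContour()], [runPipeline()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  slots = c(
    mask = "matrix", phi = "matrix", areaHistory = "numeric",
    iterations = "integer", converged = "logical", diagnostics = "list"
  )
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask must be binary {0, 1}")
  if (!identical(dim(object@mask), dim(object@phi)))
    msg <- c(msg, "mask and phi must have the same shape")
  if (length(msg)) msg else TRUE
})
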