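# Overlap metrics between a segmentation O and a ground-truth mask G.

.checkMasks <- function(O, G) {
  if (!identical(dim(O), dim(G))) stop("mask shapes must match")
  list(O = O != 0, G = G != 0)
}

#' Dice coefficient
#'
#' \code{2 |O intersect G| / (|O| + |G|)}.
#'
#' @param O segmentation mask (H x W, nonzero = foreground).
#' @param G ground-truth mask, same shape.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(O, G) {
  m <- .checkMasks(O, G)
  no <- sum(m$O); ng <- sum(m$G)
  if (no + ng == 0L) stop("both masks are empty: Dice undefined")
  2 * sum(m$O & m$G) / (no + ng)
}

#' Jaccard index
#'
#' \code{|O intersect G| / |O union G|}.
#'
#' @inheritParams diceCoefficient
#' @return Jaccard index in [0, 1].
#' @export
jaccardIndex <- function(O, G) {
  m <- .checkMasks(O, G)
  un <- sum(m$O | m$G)
  if (un == 0L) stop("both masks are empty: Jaccard undefined")
  sum(m$O & m$G) / un
}

#' Border error
#'
#' \code{(FN + FP) / (TN + TP)}: misclassified pixels over correctly
#' classified pixels.  Note the denominator is the number of correct
#' pixels, not the ground-truth area; see [xorOverTruth()] for the
#' alternative normalization.
#'
#' @inheritParams diceCoefficient
#' @return Non-negative border error.
#' @export
borderError <- function(O, G) {
  m <- .checkMasks(O, G)
  tp <- sum(m$O & m$G); tn <- sum(!m$O & !m$G)
  fp <- sum(m$O & !m$G); fn <- sum(!m$O & m$G)
  if (tp + tn == 0L) stop("no correctly classified pixels: border error undefined")
  (fn + fp) / (tn + tp)
}

#' Alternative border metric: XOR area over ground-truth area
#'
#' \code{(FN + FP) / |G|}, the common normalization of the boundary
#' disagreement.  Provided alongside [borderError()]; never substituted
#' for it.
#'
#' @inheritParams diceCoefficient
#' @return Non-negative error.
#' @export
xorOverTruth <- function(O, G) {
  m <- .checkMasks(O, G)
  ng <- sum(m$G)
  if (ng == 0L) stop("empty ground truth")
  sum(xor(m$O, m$G)) / ng
}

#' All segmentation scores at once
#'
#' @inheritParams diceCoefficient
#' @return Named list: \code{dice}, \code{jaccard}, \code{borderError},
#'   \code{xorOverTruth}, and the confusion counts \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}.
#' @export
evalScores <- function(O, G) {
  m <- .checkMasks(O, G)
  tp <- sum(m$O & m$G); tn <- sum(!m$O & !m$G)
  fp <- sum(m$O & !m$G); fn <- sum(!m$O & m$G)
  list(
    dice = diceCoefficient(O, G),
    jaccard = jaccardIndex(O, G),
    borderError = borderError(O, G),
    xorOverTruth = xorOverTruth(O, G),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
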