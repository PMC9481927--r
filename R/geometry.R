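# Cell-shape morphometrics from manually segmented polygon contours,
# division timing from annotated frames, and qPCR relative expression.
#
# Shape metrics operate on the polygon as drawn: surface protrusions
# that were included in a contour are measured, never smoothed away.

.closeIdx <- function(n) c(seq_len(n)[-1L], 1L)

# Simplicity (non-self-intersection) test. Fast path: if the vertex
# angles about the centroid wind strictly monotonically through one
# full turn, the polygon is star-shaped about that point and hence
# simple. Otherwise fall back to an exhaustive segment-pair
# intersection test (chunked to bound memory).
.isSimple <- function(v) {
  n <- nrow(v)
  ctr <- colMeans(v)
  ang <- atan2(v[, 2L] - ctr[2L], v[, 1L] - ctr[1L])
  d <- diff(c(ang, ang[1L])) %% (2 * pi)
  for (dd in list(d, (-diff(c(ang, ang[1L]))) %% (2 * pi))) {
    if (all(dd > 0) && abs(sum(dd) - 2 * pi) < 1e-9) return(TRUE)
  }
  .noSegmentCrossings(v)
}

.noSegmentCrossings <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[.closeIdx(n), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]  # edge n is adjacent to edge 1
    if (!length(j)) next
    d1 <- cross(p1[i, 1L], p1[i, 2L], p2[i, 1L], p2[i, 2L],
                p1[j, 1L], p1[j, 2L])
    d2 <- cross(p1[i, 1L], p1[i, 2L], p2[i, 1L], p2[i, 2L],
                p2[j, 1L], p2[j, 2L])
    d3 <- cross(p1[j, 1L], p1[j, 2L], p2[j, 1L], p2[j, 2L],
                rep(p1[i, 1L], length(j)), rep(p1[i, 2L], length(j)))
    d4 <- cross(p1[j, 1L], p1[j, 2L], p2[j, 1L], p2[j, 2L],
                rep(p2[i, 1L], length(j)), rep(p2[i, 2L], length(j)))
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))))
      return(FALSE)
  }
  TRUE
}

.assertSimple <- function(x) {
  v <- vertices(x)
  if (nrow(v) < 3L) degenerateError("a contour needs at least 3 vertices")
  if (!.isSimple(v))
    degenerateError("contour is self-intersecting; check the segmentation")
  v
}

.signedArea <- function(v) {
  j <- .closeIdx(nrow(v))
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

#' @describeIn CellContour-class enclosed area (µm²) by the shoelace
#'   formula; orientation-independent. Errors on self-intersecting
#'   contours.
#' @export
setMethod("polygonArea", "CellContour", function(x) {
  abs(.signedArea(.assertSimple(x)))
})

#' @describeIn CellContour-class closed-loop perimeter (µm).
#' @export
setMethod("polygonPerimeter", "CellContour", function(x) {
  v <- vertices(x)
  if (nrow(v) < 3L) degenerateError("a contour needs at least 3 vertices")
  d <- v[.closeIdx(nrow(v)), , drop = FALSE] - v
  sum(sqrt(rowSums(d^2)))
})

#' @describeIn CellContour-class circularity \eqn{4\pi A / P^2}: 1 for
#'   a circle, decreasing with irregularity. By the isoperimetric
#'   inequality it cannot exceed 1 for a simple polygon, so a value
#'   above 1 signals an invalid contour and raises an error rather than
#'   being clamped.
#' @export
setMethod("circularity", "CellContour", function(x) {
  a <- polygonArea(x)
  p <- polygonPerimeter(x)
  if (p <= 0) degenerateError("zero-perimeter contour")
  val <- 4 * pi * a / p^2
  if (val > 1 + 1e-12)
    degenerateError(sprintf(
      "circularity %.6f > 1 is geometrically impossible for a simple contour",
      val))
  val
})

# Second central moments of the polygon interior (Green's theorem),
# normalised by area: the covariance matrix of the uniform distribution
# over the polygon. Signed terms cancel orientation.
.polygonCovariance <- function(v) {
  j <- .closeIdx(nrow(v))
  x0 <- v[, 1L]; y0 <- v[, 2L]
  x1 <- v[j, 1L]; y1 <- v[j, 2L]
  cr <- x0 * y1 - x1 * y0
  A <- sum(cr) / 2
  cx <- sum((x0 + x1) * cr) / (6 * A)
  cy <- sum((y0 + y1) * cr) / (6 * A)
  x0 <- x0 - cx; x1 <- x1 - cx
  y0 <- y0 - cy; y1 <- y1 - cy
  cr <- x0 * y1 - x1 * y0
  mxx <- sum((x0^2 + x0 * x1 + x1^2) * cr) / (12 * A)
  myy <- sum((y0^2 + y0 * y1 + y1^2) * cr) / (12 * A)
  mxy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cr) / (24 * A)
  matrix(c(mxx, mxy, mxy, myy), 2L)
}

#' @describeIn CellContour-class aspect ratio (>= 1): major/minor axis
#'   ratio of the area-moment-equivalent ellipse, computed from the
#'   second central moments of the polygon interior. Invariant under
#'   rotation, translation and uniform scaling.
#' @export
setMethod("aspectRatio", "CellContour", function(x) {
  v <- .assertSimple(x)
  ev <- eigen(.polygonCovariance(v), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2L] <= 0 || ev[2L] < 1e-12 * ev[1L])
    degenerateError("degenerate contour: zero minor axis")
  sqrt(ev[1L] / ev[2L])
})

#' @describeIn DivisionEvents-class rounding time in minutes: frames
#'   from the onset of edge retraction to the first fully round frame
#'   (set to the end of metaphase when rounding continues throughout
#'   metaphase), times the frame interval.
#' @param x a `DivisionEvents`.
#' @export
setMethod("roundingTime", "DivisionEvents", function(x) {
  (x@roundingCompleteFrame - x@roundingOnsetFrame) * x@frameIntervalMin
})

#' @describeIn DivisionEvents-class ingression time in minutes: frames
#'   from the last frame with aligned chromosomes to the end of furrow
#'   ingression, times the frame interval.
#' @export
setMethod("ingressionTime", "DivisionEvents", function(x) {
  (x@ingressionEndFrame - x@metaphaseEndFrame) * x@frameIntervalMin
})

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Per sample, \eqn{\Delta CT} is the target CT minus the arithmetic
#' mean of the endogenous-control CTs (typically ACTB and GAPDH;
#' averaging CTs equals the geometric mean on the expression scale).
#' Then \eqn{\Delta\Delta CT = \Delta CT_{treated} - \Delta
#' CT_{control}} and the relative quantity is \eqn{RQ =
#' 2^{-\Delta\Delta CT}}.
#'
#' @param ctTargetTreated,ctTargetControl target-gene CT in the treated
#'   (e.g. siRNA) and control samples.
#' @param ctRefsTreated,ctRefsControl numeric vectors of
#'   endogenous-control CTs per sample (>= 1 value each).
#' @return The relative expression RQ (1 = unchanged).
#' @examples
#' relativeExpression(26, 25, c(20, 21), c(20, 21))  # ddCT 1 -> 0.5
#' @export
relativeExpression <- function(ctTargetTreated, ctRefsTreated,
                               ctTargetControl, ctRefsControl) {
  vals <- c(ctTargetTreated, ctRefsTreated, ctTargetControl, ctRefsControl)
  if (!length(ctRefsTreated) || !length(ctRefsControl))
    formatError("at least one reference CT per sample is required")
  if (any(!is.finite(vals)) || any(vals <= 0))
    formatError("CT values must be finite and positive")
  dctT <- ctTargetTreated - mean(ctRefsTreated)
  dctC <- ctTargetControl - mean(ctRefsControl)
  2^(-(dctT - dctC))
}

#' Relative expression from a long-format CT table
#'
#' Convenience wrapper over [relativeExpression()] for tables read with
#' [readCtTable()]: CTs within each sample x gene are averaged
#' (technical replicates) before the delta-delta-Ct calculation.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`.
#' @param targetGene gene to quantify.
#' @param treatedSample,controlSample sample identifiers.
#' @param refGenes endogenous-control genes
#'   (default `c("ACTB", "GAPDH")`).
#' @return The relative expression RQ.
#' @export
rqFromCtTable <- function(ct, targetGene, treatedSample, controlSample,
                          refGenes = c("ACTB", "GAPDH")) {
  getCt <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v))
      formatError(sprintf("no CT for sample '%s', gene '%s'", s, g))
    mean(v)
  }
  relativeExpression(
    getCt(treatedSample, targetGene),
    vapply(refGenes, getCt, 0, s = treatedSample),
    getCt(controlSample, targetGene),
    vapply(refGenes, getCt, 0, s = controlSample))
}
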