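## Reconstruction and registration quality measures: normalised grayscale
## similarity D, degree of spectral overlap C, and the directed Hausdorff
## distance set with its distribution statistics.

#' Normalised grayscale similarity coefficient D
#'
#' \deqn{D = 1 - \sum |M(i,j) - F(i,j)| / (m n \cdot 255)}
#'
#' Intensities are expected on the 8-bit [0, 255] scale; identical images give
#' D = 1, maximally different images give D = 0. By default D is evaluated
#' over the full common frame; pass \code{region} to restrict it to a crop
#' (e.g. the plant ROI bounding box), applied identically to both images.
#'
#' @param F,M numeric matrices of identical shape, intensities in [0, 255].
#' @param region optional integer(4) crop \code{c(row1, row2, col1, col2)}.
#' @return D in [0, 1].
#' @export
grayscaleSimilarity <- function(F, M, region = NULL) {
  .assertImage(F, "F", minDim = 1L); .assertImage(M, "M", minDim = 1L)
  .assertSameShape(F, M)
  if (!is.null(region)) {
    F <- F[region[1]:region[2], region[3]:region[4], drop = FALSE]
    M <- M[region[1]:region[2], region[3]:region[4], drop = FALSE]
  }
  1 - sum(abs(M - F)) / (length(F) * 255)
}

#' Degree of spectral overlap C
#'
#' Percentage of the reference (depth-sensor) binary ROI covered by the
#' registered spectral binary ROI:
#' \deqn{C = 100 \cdot |F_2 \wedge M_2| / |F_2|}
#'
#' @param F2 reference binary mask (0/1 or logical): depth-sensor ROI.
#' @param M2 registered spectral binary mask, same shape.
#' @return C in [0, 100] (percent).
#' @export
spectralOverlap <- function(F2, M2) {
  .assertSameShape(F2, M2)
  F2 <- F2 != 0; M2 <- M2 != 0
  nf <- sum(F2)
  if (nf == 0) .mspStop("msp_degenerate_error",
                        "reference mask is empty: overlap undefined")
  100 * sum(F2 & M2) / nf
}

#' Directed nearest-neighbour (Hausdorff) distance set
#'
#' For every point in \code{RP} (the reconstructed cloud) the Euclidean
#' distance to its nearest neighbour in \code{MP} (the reference cloud).
#' This is the directed distance set RP -> MP: it is not symmetric, and its
#' maximum is the classical directed Hausdorff distance. Computed with a
#' k-d tree (exact), identical to the brute-force all-pairs minimum.
#'
#' @param RP,MP N x 3 (or N x d) coordinate matrices, same d.
#' @return numeric vector of length \code{nrow(RP)}: distances in the
#'   coordinate units of the inputs.
#' @export
hausdorffSet <- function(RP, MP) {
  RP <- as.matrix(RP); MP <- as.matrix(MP)
  if (nrow(RP) == 0 || nrow(MP) == 0)
    .mspStop("msp_degenerate_error", "both clouds must be non-empty")
  if (ncol(RP) != ncol(MP))
    .mspStop("msp_dimension_error", "clouds must share one dimensionality")
  as.numeric(RANN::nn2(MP, RP, k = 1, eps = 0)$nn.dists)
}

## Segment edges for the HD distribution (cm).
.hdBreaks <- c(0, 0.1, 0.3, 0.6, 1.0, Inf)

#' Distribution statistics of a Hausdorff distance set
#'
#' Mean, population (divide-by-N) standard deviation and maximum of the
#' distance set, plus the percentage of distances in the segments
#' (0, 0.1], (0.1, 0.3], (0.3, 0.6], (0.6, 1.0] and > 1.0 cm. Exact zeros are
#' counted in the first segment.
#'
#' @param distances non-empty numeric vector of distances in cm, >= 0.
#' @return An [HDStats-class] object.
#' @export
hdStats <- function(distances) {
  if (!length(distances))
    .mspStop("msp_degenerate_error", "empty distance set")
  if (any(!is.finite(distances)) || any(distances < 0))
    .mspStop("msp_value_error", "distances must be finite and >= 0")
  bins <- cut(distances, breaks = .hdBreaks, include.lowest = TRUE)
  props <- 100 * as.numeric(table(bins)) / length(distances)
  new("HDStats", distances = distances, hdAvg = mean(distances),
      hdStd = sqrt(mean((distances - mean(distances))^2)),
      hdMax = max(distances), segmentProps = props)
}

#' Least-squares rigid alignment from point correspondences (Kabsch)
#'
#' Finds the rotation R and translation t minimising
#' \eqn{\sum_i \| R a_i + t - b_i \|^2} over paired landmarks.
#'
#' @param A,B n x 3 matrices of corresponding points (n >= 3, non-collinear).
#' @return list with \code{R} (3 x 3), \code{t} (length 3) and \code{rmse}.
#' @export
kabschAlign <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || nrow(A) < 3L)
    .mspStop("msp_alignment_error", "need >= 3 correspondence pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    .mspStop("msp_alignment_error", "landmarks are collinear or degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.numeric(R %*% ca)
  res <- sweep(A %*% t(R), 2, t, "+") - B
  list(R = R, t = t, rmse = sqrt(mean(rowSums(res^2))))
}

#' Evaluate a reconstruction against a reference cloud
#'
#' If the reference was captured in a different coordinate frame (e.g. a
#' handheld scanner), at least three non-collinear manually selected landmark
#' pairs must be supplied; a least-squares rigid (Kabsch) alignment maps the
#' reference into the reconstruction frame. The directed distance set
#' reconstruction -> reference is then computed (in cm) and summarised.
#'
#' @param recon,reference [MultispectralPointCloud-class] objects or N x 3
#'   coordinate matrices, metres.
#' @param pairs optional list with matrices \code{recon} and \code{reference}
#'   (n >= 3 corresponding landmarks, metres) when the frames differ.
#' @return An [HDStats-class] (distances in cm).
#' @export
evaluateReconstruction <- function(recon, reference, pairs = NULL) {
  rp <- if (is(recon, "MultispectralPointCloud")) coords(recon) else as.matrix(recon)
  mp <- if (is(reference, "MultispectralPointCloud")) coords(reference) else as.matrix(reference)
  if (!is.null(pairs)) {
    al <- kabschAlign(pairs$reference, pairs$recon)
    mp <- sweep(mp %*% t(al$R), 2, al$t, "+")
  }
  hdStats(100 * hausdorffSet(rp, mp))   # m -> cm
}
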