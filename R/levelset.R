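# Localized region-based (Chan-Vese) level-set refinement of coarse masks on
# single 2D slices, with an Otsu-derived intensity gate. The contour is the
# zero level of a signed embedding phi (negative inside); forces are the
# localized counterparts of the Chan-Vese interior/exterior fitting terms,
# computed per boundary point over a disk of radius r, plus mu times the
# curve-length (curvature) regularization.

#' Initialize the level-set embedding from a binary mask
#'
#' phi is the signed exact Euclidean distance to the mask boundary (taken to
#' lie halfway between foreground and background pixel centers), negative
#' inside, so the zero level reproduces the input mask boundary exactly under
#' the sign test phi < 0.
#'
#' @param mask 2D binary matrix (nonempty).
#' @return a [LevelSetState-class].
#' @export
initPhi <- function(mask) {
  m <- asPixelMatrix(mask)
  if (sum(m != 0) == 0)
    stopWithClass("nothing to refine: empty mask", "hepasegNothingToRefine")
  im <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  phi <- cpp_signed_edt(array(im, dim = c(dim(im), 1L)),
                        c(1, 1, 1))[, , 1]
  new("LevelSetState", phi = phi, iteration = 0L, energy = NA_real_)
}

#' Otsu threshold of a 2D image
#'
#' Maximizes the between-class variance over a 256-bin histogram; ties are
#' broken toward the lowest threshold. Used to derive the intensity gate
#' that concentrates the level set on the liver (or tumor) intensity range.
#'
#' @param img 2D intensities with at least two distinct values.
#' @param nbins histogram resolution.
#' @return scalar threshold on the intensity scale of `img`; class 0 is
#'   `img <= threshold`.
#' @export
otsuThreshold <- function(img, nbins = 256L) {
  v <- as.numeric(asPixelMatrix(img))
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo)
    stopWithClass("constant image has no threshold",
                  "hepasegDegenerateInput")
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nbins]
  w1 <- 1 - w0
  sb <- (muT * w0 - mu)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)  # which.max takes the first (lowest) maximizer
  lo + k * (hi - lo) / nbins
}

#' Local interior/exterior statistics at a boundary point
#'
#' The localized counterparts of the Chan-Vese means c1 and c2: means of the
#' image over ball(x, r) intersected with \{phi < 0\} and \{phi >= 0\}. An
#' empty side is flagged undefined and the point's force is 0.
#'
#' @param img 2D intensities.
#' @param state a [LevelSetState-class].
#' @param x point as (row, col), on the narrow band (|phi| <= r).
#' @param r localization ball radius in px.
#' @return list with `u` (interior mean), `v` (exterior mean), `uDefined`,
#'   `vDefined`, and `force` ((I - u)^2 - (I - v)^2, or 0).
#' @export
localRegionStats <- function(img, state, x, r) {
  m <- asPixelMatrix(img)
  phi <- state@phi
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- floor(r)
  ii <- max(1, x[1] - ri):min(nr, x[1] + ri)
  jj <- max(1, x[2] - ri):min(nc, x[2] + ri)
  g <- expand.grid(i = ii, j = jj)
  g <- g[(g$i - x[1])^2 + (g$j - x[2])^2 <= r^2, ]
  vals <- m[cbind(g$i, g$j)]
  inside <- phi[cbind(g$i, g$j)] < 0
  u <- if (any(inside)) mean(vals[inside]) else NA_real_
  v <- if (any(!inside)) mean(vals[!inside]) else NA_real_
  force <- if (is.na(u) || is.na(v)) 0 else
    (m[x[1], x[2]] - u)^2 - (m[x[1], x[2]] - v)^2
  list(u = u, v = v, uDefined = !is.na(u), vDefined = !is.na(v),
       force = force)
}

#' Global Chan-Vese energy of a contour
#'
#' mu times the contour length (smoothed-Dirac estimate of the zero-level
#' length) plus the interior and exterior squared residuals around the
#' global means c1 and c2. Used for diagnostics and descent monitoring.
#'
#' @param img 2D intensities.
#' @param state a [LevelSetState-class] (or matrix phi).
#' @param mu curve-length weight.
#' @param epsilon Dirac smoothing half-width in px.
#' @return scalar energy.
#' @export
chanVeseEnergy <- function(img, state, mu = 0, epsilon = 1.5) {
  m <- asPixelMatrix(img)
  phi <- if (is(state, "LevelSetState")) state@phi else state
  inside <- phi < 0
  c1 <- if (any(inside)) mean(m[inside]) else 0
  c2 <- if (any(!inside)) mean(m[!inside]) else 0
  fit <- sum((m[inside] - c1)^2) + sum((m[!inside] - c2)^2)
  len <- 0
  if (mu > 0) {
    delta <- ifelse(abs(phi) <= epsilon,
                    0.5 / epsilon * (1 + cos(pi * phi / epsilon)), 0)
    nr <- nrow(phi)
    nc <- ncol(phi)
    px <- (phi[, c(2:nc, nc)] - phi[, c(1, 1:(nc - 1))]) / 2
    py <- (phi[c(2:nr, nr), ] - phi[c(1, 1:(nr - 1)), ]) / 2
    len <- sum(delta * sqrt(px^2 + py^2))
  }
  mu * len + fit
}

#' Evolve a coarse mask to the image boundary
#'
#' Localized region-based level-set evolution: at every narrow-band point
#' the force compares the pixel with the local interior and exterior means
#' within a disk of radius `p@radius`; the curve-length term weighted by
#' `p@mu` regularizes the front. The data force is normalized by its band
#' maximum and the step scaled so the largest per-iteration update of phi is
#' `p@dt` pixels; phi is reinitialized to a signed distance every
#' `p@reinitEvery` iterations; evolution stops at `p@maxIters`, when the
#' mean |dphi| over the band drops below `p@tol`, or when the sign mask has
#' been stable for 10 iterations. Components whose local interior and
#' exterior means are indistinguishable carry no data force and are shrunk
#' by the curvature term until they vanish, which removes small spurious
#' (non-tumor) objects from network predictions.
#'
#' @param img 2D intensities (finite).
#' @param initMask nonempty 2D binary matrix: the coarse (network) mask.
#' @param p a [LevelSetParams-class].
#' @param gate optional intensity interval c(lo, hi) (Otsu-derived in the
#'   pipeline); pixels outside it contribute to the exterior statistics
#'   only.
#' @return binary matrix of the converged contour interior, with attributes
#'   `iterations` and `phi`.
#' @export
evolveContour <- function(img, initMask, p = levelSetParams(), gate = NULL) {
  m <- asPixelMatrix(img)
  init <- asPixelMatrix(initMask)
  if (sum(init != 0) == 0)
    stopWithClass("nothing to refine: empty mask", "hepasegNothingToRefine")
  if (any(!is.finite(m)))
    stopWithClass("image intensities must be finite", "hepasegContractError")
  useGate <- !is.null(gate)
  glo <- if (useGate) gate[1] else -Inf
  ghi <- if (useGate) gate[2] else Inf
  res <- cpp_evolve(m, matrix(as.integer(init != 0), nrow(init), ncol(init)),
                    p@radius, p@mu, p@dt, p@maxIters, p@reinitEvery, p@tol,
                    p@epsilon, glo, ghi, useGate)
  out <- res$mask
  attr(out, "iterations") <- res$iterations
  attr(out, "phi") <- res$phi
  out
}
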