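## Feature pooling: Heaviside hashing of the stage-2 maps into integer
## "word" images, min-max rescale, spatial-pyramid word histograms, high
## dispersal (fixed-norm rescale) and local response normalization across
## filter maps, then concatenation into the final feature vector.

#' Binarise a stage-2 map with the Heaviside step
#'
#' Pixels strictly greater than the threshold become 1, all others 0
#' (strict inequality: an exact 0 maps to 0). The default source,
#' \code{"pre_nt"}, thresholds the tanh convolution map at zero — the maps
#' after the nonlinear transform are strictly positive, so thresholding
#' them directly would set every bit. The alternative,
#' \code{"nt_centered"}, thresholds the post-transform map at its own mean.
#'
#' @param stageOut one per-image element of \code{\link{forwardCascade}}'s
#'   value, or a plain numeric matrix (then thresholded at 0).
#' @param k,j stage-1 branch and stage-2 filter index (when
#'   \code{stageOut} is a forward-pass element).
#' @param source \code{"pre_nt"} or \code{"nt_centered"}.
#' @return integer 0/1 matrix.
#' @export
binarize <- function(stageOut, k = NULL, j = NULL, source = "pre_nt") {
  if (!source %in% c("pre_nt", "nt_centered"))
    stop("unknown binarisation source: ", source)
  if (is.matrix(stageOut)) {
    map <- stageOut
    thr <- if (source == "nt_centered") mean(map) else 0
  } else {
    map <- if (source == "pre_nt") stageOut$C2[[k]][[j]]
           else stageOut$T2[[k]][[j]]
    thr <- if (source == "nt_centered") mean(map) else 0
  }
  (map > thr) + 0L
}

#' Hash a group of binary maps into one word image
#'
#' The V1 binary maps that share a stage-2 filter are combined pixelwise as
#' sum over k of 2^((k-1) mod 256) * B_k, with k the stage-1 branch index.
#' For V1 = 8 every word is an integer in [0, 255].
#'
#' @param binaryMaps list of V1 binary matrices of identical shape, ordered
#'   by stage-1 filter index.
#' @return integer matrix of hashed words.
#' @export
hashGroup <- function(binaryMaps) {
  d <- dim(binaryMaps[[1L]])
  H <- matrix(0, d[1L], d[2L])
  for (k in seq_along(binaryMaps)) {
    B <- binaryMaps[[k]]
    if (!identical(dim(B), d)) stop("binary maps differ in shape")
    H <- H + 2^((k - 1L) %% 256L) * B
  }
  H
}

#' Min-max rescale a hashed word image to [0, 255]
#'
#' Per-map rescale (H - min)/(max - min) * 255, rounded half away from
#' zero to integers. A constant map (max = min) becomes all zeros.
#'
#' @param hm numeric/integer matrix of hashed words.
#' @return integer-valued matrix with min 0 and max 255 (unless constant).
#' @export
rescaleHash <- function(hm) {
  lo <- min(hm); hi <- max(hm)
  if (hi == lo) return(hm * 0)
  x <- (hm - lo) / (hi - lo) * 255
  floor(x + 0.5)  # values are >= 0, so this is round-half-away-from-zero
}

#' Spatial-pyramid word histograms of a hashed map
#'
#' For each level l in 0..L the map is partitioned into a 2^l x 2^l cell
#' grid (cell boundaries at floor(m * r / 2^l)) and each cell contributes a
#' 256-bin count histogram of its integer words. Cells are ordered level
#' ascending, then row-major within a level, giving G = sum(4^l) rows
#' (21 at L = 2).
#'
#' @param hm integer-valued matrix with entries in [0, 255].
#' @param L pyramid depth (>= 0); \code{2^L} must not exceed either map
#'   dimension.
#' @param nBins word alphabet size (256 for V1 = 8).
#' @return numeric G x nBins matrix of counts.
#' @export
pyramidHistogram <- function(hm, L, nBins = 256L) {
  if (L < 0) stop("'L' must be >= 0")
  m <- nrow(hm); n <- ncol(hm)
  if (2^L > min(m, n)) stop("2^L exceeds the map dimension")
  G <- sum(4^(0:L))
  out <- matrix(0, G, nBins)
  row <- 0L
  for (l in 0:L) {
    g <- 2^l
    rb <- floor(m * (0:g) / g); cb <- floor(n * (0:g) / g)
    for (i in seq_len(g)) for (j in seq_len(g)) {
      row <- row + 1L
      cell <- hm[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      out[row, ] <- tabulate(as.integer(cell) + 1L, nbins = nBins)
    }
  }
  out
}

#' High dispersal: rescale a feature map to a fixed Euclidean norm
#'
#' Divides the multiscale feature map by its Frobenius norm over all
#' G x 256 entries and multiplies by sigma, so every non-zero map ends up
#' with norm exactly sigma; an all-zero map is returned unchanged. With
#' \code{useSqrt = FALSE} the divisor is the plain sum of squares instead
#' of its square root (no fixed-norm property then).
#'
#' @param pf numeric matrix (a pyramid feature).
#' @param sigma target norm (> 0).
#' @param useSqrt divide by the Euclidean norm (TRUE, default) or the bare
#'   sum of squares (FALSE).
#' @return numeric matrix of the same shape.
#' @export
highDispersal <- function(pf, sigma, useSqrt = TRUE) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  ss <- sum(pf^2)
  if (ss == 0) return(pf)
  sigma * pf / (if (useSqrt) sqrt(ss) else ss)
}

#' Local response normalization across filter maps
#'
#' At every (cell, bin) position, feature j is divided by
#' (gamma + alpha * sum of squares of features j' in the window
#' max(1, j - floor(n/2)) .. min(V2, j + floor(n/2)))^beta, the window
#' running over the stage-2 filter order.
#'
#' @param pfs list of V2 numeric matrices of identical shape (dispersed
#'   pyramid features, ordered by stage-2 filter).
#' @param gamma,alpha,beta LRN constants.
#' @param nLrn window size n (>= 1).
#' @return list of V2 matrices.
#' @export
localResponseNormalize <- function(pfs, gamma, alpha, beta, nLrn) {
  V2 <- length(pfs)
  d <- dim(pfs[[1L]])
  if (!all(vapply(pfs, function(x) identical(dim(x), d), logical(1L))))
    stop("pyramid features differ in shape")
  half <- nLrn %/% 2L
  sq <- lapply(pfs, function(x) x^2)
  lapply(seq_len(V2), function(j) {
    lo <- max(1L, j - half); hi <- min(V2, j + half)
    s <- Reduce(`+`, sq[lo:hi])
    pfs[[j]] / (gamma + alpha * s)^beta
  })
}

#' Concatenate per-filter pyramid features into the final vector
#'
#' Features are concatenated in stage-2 filter order; within each feature
#' the order is level ascending, cell row-major, bin ascending. At the
#' defaults (V2 = 8, L = 2, 256 words) the length is 8 * 21 * 256 = 43008.
#'
#' @param pfs list of V2 numeric G x 256 matrices.
#' @return numeric vector of length V2 * G * 256.
#' @export
vectorizeFeatures <- function(pfs) {
  d <- dim(pfs[[1L]])
  if (!all(vapply(pfs, function(x) identical(dim(x), d), logical(1L))))
    stop("pyramid features differ in shape")
  unlist(lapply(pfs, function(x) as.vector(t(x))), use.names = FALSE)
}

#' Extract the full feature vector of each image
#'
#' Composition of the forward cascade, Heaviside hashing, per-map min-max
#' rescale, spatial-pyramid histograms, high dispersal and local response
#' normalization, concatenated across the V2 stage-2 filters. The ablation
#' switches in \code{params} drop individual components: \code{useMFA} off
#' replaces the pyramid with the single level-0 histogram, \code{useHD} and
#' \code{useLRN} off skip their normalizations, \code{useNT} off skips the
#' nonlinear transform in the cascade. With all four off the output is the
#' PCANet-style baseline of plain hashed histograms (length V2 * 256).
#'
#' @param imgs list of numeric matrices (or a single matrix).
#' @param bank1,bank2 the learned filter banks.
#' @param params a \code{\linkS4class{NetParams}}.
#' @return numeric matrix, one row per image, V2 * G * 256 columns.
#' @export
extractFeatures <- function(imgs, bank1, bank2, params) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  outs <- forwardCascade(imgs, bank1, bank2, params)
  V1 <- nFilters(bank1); V2 <- nFilters(bank2)
  Luse <- if (params@useMFA) params@L else 0L
  feats <- lapply(outs, function(so) {
    pfs <- lapply(seq_len(V2), function(j) {
      bmaps <- lapply(seq_len(V1), function(k)
        binarize(so, k, j, source = params@binarizeSource))
      hm <- rescaleHash(hashGroup(bmaps))
      pf <- pyramidHistogram(hm, L = Luse)
      if (params@useHD)
        pf <- highDispersal(pf, params@sigma, useSqrt = params@hdSqrt)
      pf
    })
    if (params@useLRN)
      pfs <- localResponseNormalize(pfs, params@gamma, params@alpha,
                                    params@beta, params@nLrn)
    vectorizeFeatures(pfs)
  })
  do.call(rbind, feats)
}
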