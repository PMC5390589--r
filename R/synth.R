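## Seeded generator of two-class tongue-like images: an elliptical bright
## foreground on a dark background, a smooth spatially correlated texture
## on both classes, and (class 1 only) high-frequency coating-like spots
## whose density and amplitude scale with the contrast parameter.

# separable Gaussian blur; borders renormalised by the blurred all-ones
# mask so edge pixels are unbiased
blurGaussian <- function(img, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  conv1 <- function(M, kern) {
    n <- ncol(M); r2 <- (length(kern) - 1L) %/% 2L
    P <- cbind(matrix(0, nrow(M), r2), M, matrix(0, nrow(M), r2))
    out <- matrix(0, nrow(M), n)
    for (i in seq_along(kern))
      out <- out + kern[i] * P[, (i - 1L) + seq_len(n), drop = FALSE]
    out
  }
  num <- t(conv1(t(conv1(img, k)), k))
  den <- t(conv1(t(conv1(img * 0 + 1, k)), k))
  num / den
}

#' Generate one synthetic tongue-like image
#'
#' Draws an elliptical bright foreground (jittered centre, axes and
#' rotation) on a dark background, adds a smooth Gaussian-correlated
#' texture and pixel noise to both classes and, for class 1 only,
#' superimposes high-frequency coating-like spots. Spot density and
#' amplitude scale linearly with \code{contrast}; at \code{contrast = 0}
#' the two class-conditional distributions coincide. Identical seed and
#' class give a bit-identical image.
#'
#' This appearance model exists to plant class-discriminative texture of
#' the kind a coated tongue shows, not to mimic clinical photographs.
#'
#' @param classLabel 0 (normal, smooth) or 1 (abnormal, spotted).
#' @param seed integer RNG seed for this image.
#' @param size image side length in pixels.
#' @param config a \code{\linkS4class{SynthConfig}} supplying contrast,
#'   texture correlation length, spot density and noise level.
#' @return numeric \code{size x size} matrix with intensities in [0, 255].
#' @export
generateImage <- function(classLabel, seed, size = NULL, config = synthConfig()) {
  if (is.null(size)) size <- config@size
  size <- as.integer(size)
  if (size < 4L) stop("invalid image size")
  if (!classLabel %in% c(0L, 1L)) stop("'classLabel' must be 0 or 1")
  withSeed(seed, {
    s <- size
    cx <- s / 2 + stats::runif(1, -0.01, 0.01) * s
    cy <- s / 2 + stats::runif(1, -0.01, 0.01) * s
    # the body fills most of the frame, as a segmented bounding-box crop does
    ax <- s * stats::runif(1, 0.46, 0.48)   # semi-axes
    ay <- s * stats::runif(1, 0.38, 0.40)
    th <- stats::runif(1, -0.05, 0.05)
    X <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    Y <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    U <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    W <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    inside <- (U / ax)^2 + (W / ay)^2 <= 1
    img <- matrix(30, s, s)
    img[inside] <- 150
    # class 1 carries a finer-grained base texture; the correlation length
    # shrinks with contrast and coincides with class 0 at contrast 0
    corLen <- if (classLabel == 1L)
      config@corLen / (1 + config@contrast) else config@corLen
    tex <- blurGaussian(matrix(stats::rnorm(s * s), s, s), corLen)
    tex <- tex / max(stats::sd(tex), 1e-12) * 30
    img[inside] <- img[inside] + tex[inside]
    # noise only on the tongue body: the background plays the role of the
    # flat region outside a segmentation mask
    noise <- matrix(stats::rnorm(s * s, sd = config@noiseSD), s, s)
    img[inside] <- img[inside] + noise[inside]
    # spots last, so at contrast 0 the class-1 stream matches class 0
    if (classLabel == 1L && config@contrast > 0) {
      fg <- which(inside)
      nSpots <- stats::rpois(1, config@spotDensity * config@contrast *
                                  length(fg))
      if (nSpots > 0) {
        at <- sample(fg, min(nSpots, length(fg)))
        amp <- min(60 * config@contrast, 100) *
          sample(c(-1, 1), length(at), replace = TRUE)
        # 3x3 blobs (centre full, ring half amplitude) so the spots
        # survive downscaling to the working size
        rs <- (at - 1L) %% s + 1L; cs <- (at - 1L) %/% s + 1L
        for (dy in -1:1) for (dx in -1:1) {
          rr2 <- rs + dy; cc2 <- cs + dx
          ok <- rr2 >= 1L & rr2 <= s & cc2 >= 1L & cc2 <= s
          sc <- if (dy == 0L && dx == 0L) 1 else 0.5
          ii <- (cc2[ok] - 1L) * s + rr2[ok]
          img[ii] <- img[ii] + sc * amp[ok]
        }
      }
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Generate a labelled synthetic dataset
#'
#' \code{nNormal} class-0 images followed by \code{nAbnormal} class-1
#' images; per-image seeds are drawn from the master seed, so the whole
#' dataset is a deterministic function of the configuration.
#'
#' @param config a \code{\linkS4class{SynthConfig}}.
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (integer 0/1 vector) and \code{ids} (character).
#' @export
#' @examples
#' ds <- generateDataset(synthConfig(nNormal = 3, nAbnormal = 5, size = 32))
#' table(ds$labels)
generateDataset <- function(config = synthConfig()) {
  n <- config@nNormal + config@nAbnormal
  if (n == 0L) stop("at least one image must be requested")
  labels <- c(rep(0L, config@nNormal), rep(1L, config@nAbnormal))
  seeds <- withSeed(config@seed, sample.int(.Machine$integer.max - 1L, n))
  images <- lapply(seq_len(n), function(i)
    generateImage(labels[i], seed = seeds[i], size = config@size,
                  config = config))
  list(images = images, labels = labels,
       ids = sprintf("img%04d", seq_len(n)))
}

#' Write a dataset as PNG files plus a labels CSV
#'
#' @param dataset value of \code{\link{generateDataset}}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$images))
    png::writePNG(dataset$images[[i]] / 255,
                  file.path(dir, paste0(dataset$ids[i], ".png")))
  utils::write.csv(data.frame(id = dataset$ids, label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by \code{\link{writeDataset}}
#'
#' @param dir directory holding the PNG files and \code{labels.csv}.
#' @return list with \code{images}, \code{labels}, \code{ids}.
#' @export
readDataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  images <- lapply(lab$id, function(id)
    loadImage(file.path(dir, paste0(id, ".png"))))
  list(images = images, labels = as.integer(lab$label),
       ids = as.character(lab$id))
}
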