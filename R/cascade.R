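## The two-stage forward pass: zero-padded tanh convolution of mean-removed
## patches with the eigenfilters, plus the elementwise nonlinear transform.

#' Convolve an image with an eigenfilter through tanh
#'
#' The image is zero-padded by floor(s1/2), floor(s2/2); each output pixel
#' is tanh of the inner product between the kernel and the mean-removed
#' patch centred there (correlation convention, no kernel flip). Padding
#' pixels take part in the patch mean like any other pixel. The output has
#' the input's shape and all entries lie in (-1, 1).
#'
#' @param img numeric matrix.
#' @param filt numeric kernel matrix with odd dimensions.
#' @return numeric matrix of \code{dim(img)}.
#' @export
convolveTanh <- function(img, filt) {
  convolveTanhBank(img, array(filt, dim = c(dim(filt), 1L)))[[1L]]
}

# shared path: convolve one image with every kernel of an s1 x s2 x V
# array at once (one im2col, one matrix product); returns a list of maps
convolveTanhBank <- function(img, farr) {
  s1 <- dim(farr)[1L]; s2 <- dim(farr)[2L]; V <- dim(farr)[3L]
  if (s1 %% 2L == 0L || s2 %% 2L == 0L)
    stop("filter dimensions must be odd (centre undefined otherwise)")
  m <- nrow(img); n <- ncol(img)
  pm <- removePatchMeans(extractPatches(padImage(img, s1, s2), s1, s2))
  FM <- apply(farr, 3L, function(k) as.vector(t(k)))  # (s1*s2) x V, row-major
  if (!is.matrix(FM)) FM <- matrix(FM, ncol = V)
  resp <- tanh(crossprod(pm, FM))                      # p x V
  lapply(seq_len(V), function(j)
    matrix(resp[, j], nrow = m, ncol = n, byrow = TRUE))
}

#' Elementwise nonlinear transformation
#'
#' With selector \code{a = 1} the smoothed absolute value
#' \code{sqrt(eps + C^2)}; with \code{a = 0} the softplus
#' \code{log(1 + exp(C))}, evaluated in its numerically stable form.
#' Either branch maps any real input to a strictly positive value.
#'
#' @param map numeric matrix (a convolution map).
#' @param eps small positive smoothing constant.
#' @param a branch selector, 0 or 1.
#' @return numeric matrix of the same shape, entries > 0.
#' @export
nonlinearTransform <- function(map, eps, a) {
  if (eps <= 0) stop("'eps' must be > 0")
  if (!a %in% c(0, 1)) stop("'a' must be 0 or 1")
  if (a == 1) sqrt(eps + map^2) else pmax(map, 0) + log1p(exp(-abs(map)))
}

#' Two-stage forward pass of the cascade
#'
#' Stage 1 convolves each image with the V1 stage-1 eigenfilters and (when
#' \code{useNT} is on) applies the nonlinear transform; stage 2 convolves
#' every stage-1 output map with all V2 stage-2 filters, giving V1*V2 maps
#' per image, each of the input's shape. With \code{useNT} off the
#' transform is skipped and the tanh maps feed forward unchanged
#' (the PCANet-style ablation).
#'
#' @param imgs a list of numeric matrices (images at the working size), or
#'   a single matrix.
#' @param bank1,bank2 stage-1 and stage-2 \code{\linkS4class{PCAFilterBank}}.
#' @param params a \code{\linkS4class{NetParams}}.
#' @return a list with one element per image; each element is a list with
#'   \code{C2} and \code{T2}, themselves lists indexed \code{[[k]][[j]]}
#'   (stage-1 branch k, stage-2 filter j) of pre- and post-transform maps.
#' @export
forwardCascade <- function(imgs, bank1, bank2, params) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  f1 <- filters(bank1); f2 <- filters(bank2)
  if (dim(f1)[1L] != params@s1 || dim(f1)[2L] != params@s2 ||
      any(dim(f2)[1:2] != dim(f1)[1:2]))
    stop("filter bank geometry does not match 'params'")
  lapply(imgs, function(img) {
    if (!is.matrix(img)) stop("each image must be a numeric matrix")
    if (nrow(img) < params@s1 || ncol(img) < params@s2)
      stop("image smaller than the filter")
    C1 <- convolveTanhBank(img, f1)
    T1 <- if (params@useNT)
      lapply(C1, nonlinearTransform, eps = params@eps, a = params@a)
    else C1
    C2 <- lapply(T1, convolveTanhBank, farr = f2)
    T2 <- if (params@useNT)
      lapply(C2, function(maps)
        lapply(maps, nonlinearTransform, eps = params@eps, a = params@a))
    else C2
    list(C2 = C2, T2 = T2)
  })
}

#' Learn both filter banks from a set of training images
#'
#' Stage-1 filters come from the pooled mean-removed patches of all
#' training images; the stage-1 maps (post-transform) of those images are
#' then pooled the same way to learn the stage-2 filters.
#'
#' @param imgs list of numeric matrices.
#' @param params a \code{\linkS4class{NetParams}}.
#' @return list with elements \code{bank1} and \code{bank2}.
#' @export
learnCascade <- function(imgs, params) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  s1 <- params@s1; s2 <- params@s2
  ps1 <- lapply(imgs, function(img)
    removePatchMeans(extractPatches(img, s1, s2)))
  bank1 <- learnFilters(ps1, V = params@V1, s1 = s1, s2 = s2, stage = 1L)
  ps2 <- vector("list", length(imgs) * params@V1)
  i <- 0L
  for (img in imgs) {
    C1 <- convolveTanhBank(img, filters(bank1))
    T1 <- if (params@useNT)
      lapply(C1, nonlinearTransform, eps = params@eps, a = params@a)
    else C1
    for (tmap in T1) {
      i <- i + 1L
      ps2[[i]] <- removePatchMeans(extractPatches(tmap, s1, s2))
    }
  }
  bank2 <- learnFilters(ps2, V = params@V2, s1 = s1, s2 = s2, stage = 2L)
  list(bank1 = bank1, bank2 = bank2)
}
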