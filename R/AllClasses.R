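#' @import methods
NULL

#' PCA eigenfilter bank for one cascade stage
#'
#' An ordered set of \code{s1 x s2} convolution kernels obtained as the top
#' eigenvectors of the pooled scatter matrix of mean-removed image patches,
#' together with their eigenvalues (descending) and the stage index (1 or 2).
#'
#' Vectorised (row-major) filters are pairwise orthonormal because they are
#' eigenvectors of a symmetric matrix; validity enforces this to 1e-8, the
#' non-increasing eigenvalue order, and the filter count.
#'
#' @slot filters array of dimension \code{c(s1, s2, V)}; \code{filters[,,j]}
#'   is the j-th kernel.
#' @slot eigenvalues numeric vector of length V, non-increasing.
#' @slot stage integer, 1 or 2.
#' @exportClass PCAFilterBank
setClass("PCAFilterBank",
  representation(filters = "array", eigenvalues = "numeric",
                 stage = "integer"),
  validity = function(object) {
    f <- object@filters
    if (length(dim(f)) != 3L)
      return("'filters' must be an s1 x s2 x V array")
    V <- dim(f)[3L]
    if (length(object@eigenvalues) != V)
      return("one eigenvalue per filter required")
    if (V > 1L && any(diff(object@eigenvalues) > 1e-9 * max(abs(object@eigenvalues), 1)))
      return("eigenvalues must be non-increasing")
    if (!object@stage %in% c(1L, 2L))
      return("'stage' must be 1 or 2")
    # row-major vectorisation; Gram matrix must be the identity
    M <- apply(f, 3L, function(k) as.vector(t(k)))
    G <- crossprod(M)
    if (max(abs(G - diag(V))) > 1e-8)
      return("vectorised filters are not orthonormal")
    TRUE
  })

#' Network hyperparameters
#'
#' All tunable parameters of the two-stage cascade and the pooling layer,
#' plus the component ablation switches. Defaults are the operating point
#' used throughout: \code{eps = 1e-8}, \code{a = 1}, \code{gamma = 2},
#' \code{alpha = 1e-4}, \code{beta = 0.75}, \code{sigma = 2.238},
#' \code{nLrn = 5}, \code{V1 = V2 = 8}, 5x5 filters, pyramid depth
#' \code{L = 2}.
#'
#' @slot eps small positive real of the smoothed-absolute-value transform.
#' @slot a selector of the nonlinear transform: 1 = sqrt(eps + C^2),
#'   0 = softplus log(1 + exp(C)).
#' @slot gamma,alpha,beta local-response-normalization constants.
#' @slot sigma target Euclidean norm of the high-dispersal rescaling (> 0).
#' @slot nLrn LRN window size across neighbouring filter maps (>= 1).
#' @slot V1,V2 filter counts of stages 1 and 2.
#' @slot s1,s2 filter height and width (odd).
#' @slot L spatial-pyramid depth (levels 0..L).
#' @slot useNT,useMFA,useHD,useLRN ablation switches for the nonlinear
#'   transform, the multiscale pyramid, high dispersal and LRN.
#' @slot binarizeSource which stage-2 map the Heaviside step binarises:
#'   \code{"pre_nt"} (the tanh convolution map, default) or
#'   \code{"nt_centered"} (post-transform map minus its mean).
#' @slot hdSqrt logical; TRUE divides by the Euclidean norm (default),
#'   FALSE by the plain sum of squares.
#' @exportClass NetParams
setClass("NetParams",
  representation(eps = "numeric", a = "integer", gamma = "numeric",
                 alpha = "numeric", beta = "numeric", sigma = "numeric",
                 nLrn = "integer", V1 = "integer", V2 = "integer",
                 s1 = "integer", s2 = "integer", L = "integer",
                 useNT = "logical", useMFA = "logical", useHD = "logical",
                 useLRN = "logical", binarizeSource = "character",
                 hdSqrt = "logical"),
  validity = function(object) {
    if (object@eps <= 0) return("'eps' must be > 0")
    if (!object@a %in% c(0L, 1L)) return("'a' must be 0 or 1")
    if (object@sigma <= 0) return("'sigma' must be > 0")
    if (object@nLrn < 1L) return("'nLrn' must be >= 1")
    if (object@L < 0L) return("'L' must be >= 0")
    if (object@V1 < 1L || object@V2 < 1L) return("filter counts must be >= 1")
    if (object@s1 < 1L || object@s2 < 1L) return("filter dims must be >= 1")
    if (!object@binarizeSource %in% c("pre_nt", "nt_centered"))
      return("'binarizeSource' must be \"pre_nt\" or \"nt_centered\"")
    TRUE
  })

#' Cross-validation configuration
#'
#' @slot k number of folds (>= 2).
#' @slot repeats number of repeated rounds (>= 1).
#' @slot stratified logical; folds preserve the class ratio.
#' @slot seed integer RNG seed for the fold shuffles.
#' @slot wMinority,wMajority per-class misclassification weights (> 0);
#'   the minority class is the rarer label in the data.
#' @slot cost SVM cost parameter C.
#' @exportClass CVConfig
setClass("CVConfig",
  representation(k = "integer", repeats = "integer", stratified = "logical",
                 seed = "integer", wMinority = "numeric",
                 wMajority = "numeric", cost = "numeric"),
  validity = function(object) {
    if (object@k < 2L) return("'k' must be >= 2")
    if (object@repeats < 1L) return("'repeats' must be >= 1")
    if (object@wMinority <= 0 || object@wMajority <= 0)
      return("class weights must be > 0")
    if (object@cost <= 0) return("'cost' must be > 0")
    TRUE
  })

#' Synthetic tongue-image dataset configuration
#'
#' Describes a two-class set of elliptical "tongue body" images on a dark
#' background: class 0 carries a smooth, spatially correlated texture, class
#' 1 additionally carries high-frequency coating-like spots whose density
#' and amplitude scale with \code{contrast}. Defaults reproduce the 48
#' normal / 267 abnormal imbalance (about 15\% minority).
#'
#' @slot nNormal,nAbnormal class sizes.
#' @slot size image side length in pixels (square images).
#' @slot seed integer master RNG seed; identical seed, identical dataset.
#' @slot contrast non-negative class-contrast parameter; 0 makes the two
#'   class-conditional distributions identical.
#' @slot corLen correlation length (pixels) of the smooth base texture;
#'   the constructor default scales with the image size (size/6.4) so the
#'   texture keeps its apparent grain after resizing to the working size.
#' @slot spotDensity coating-spot density per foreground pixel at
#'   \code{contrast = 1}.
#' @slot noiseSD standard deviation of the additive pixel noise.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nNormal = "integer", nAbnormal = "integer", size = "integer",
                 seed = "integer", contrast = "numeric", corLen = "numeric",
                 spotDensity = "numeric", noiseSD = "numeric"),
  validity = function(object) {
    if (object@nNormal < 0L || object@nAbnormal < 0L)
      return("class counts must be >= 0")
    if (object@size < 4L) return("'size' must be >= 4")
    if (object@contrast < 0) return("'contrast' must be >= 0")
    if (object@corLen <= 0) return("'corLen' must be > 0")
    if (object@noiseSD < 0) return("'noiseSD' must be >= 0")
    TRUE
  })

#' @describeIn NetParams constructor with the default operating point.
#' @param eps,a,gamma,alpha,beta,sigma,nLrn,V1,V2,s1,s2,L see slots.
#' @param useNT,useMFA,useHD,useLRN ablation switches (all TRUE by default).
#' @param binarizeSource,hdSqrt see slots.
#' @return a validated \code{NetParams} object.
#' @export
netParams <- function(eps = 1e-8, a = 1, gamma = 2, alpha = 1e-4,
                      beta = 0.75, sigma = 2.238, nLrn = 5,
                      V1 = 8, V2 = 8, s1 = 5, s2 = 5, L = 2,
                      useNT = TRUE, useMFA = TRUE, useHD = TRUE,
                      useLRN = TRUE, binarizeSource = "pre_nt",
                      hdSqrt = TRUE) {
  new("NetParams", eps = as.numeric(eps), a = as.integer(a),
      gamma = as.numeric(gamma), alpha = as.numeric(alpha),
      beta = as.numeric(beta), sigma = as.numeric(sigma),
      nLrn = as.integer(nLrn), V1 = as.integer(V1), V2 = as.integer(V2),
      s1 = as.integer(s1), s2 = as.integer(s2), L = as.integer(L),
      useNT = useNT, useMFA = useMFA, useHD = useHD, useLRN = useLRN,
      binarizeSource = binarizeSource, hdSqrt = hdSqrt)
}

#' @describeIn CVConfig constructor; defaults to 10 rounds of stratified
#'   5-fold cross-validation with unit class weights and cost 1.
#' @param k,repeats,stratified,seed,wMinority,wMajority,cost see slots.
#' @return a validated \code{CVConfig} object.
#' @export
cvConfig <- function(k = 5, repeats = 10, stratified = TRUE, seed = 1,
                     wMinority = 1, wMajority = 1, cost = 1) {
  new("CVConfig", k = as.integer(k), repeats = as.integer(repeats),
      stratified = stratified, seed = as.integer(seed),
      wMinority = as.numeric(wMinority), wMajority = as.numeric(wMajority),
      cost = as.numeric(cost))
}

#' @describeIn SynthConfig constructor; defaults emulate the 48/267
#'   imbalanced study set on 64x64 images.
#' @param nNormal,nAbnormal,size,seed,contrast,corLen,spotDensity,noiseSD
#'   see slots.
#' @return a validated \code{SynthConfig} object.
#' @export
synthConfig <- function(nNormal = 48, nAbnormal = 267, size = 64, seed = 1,
                        contrast = 1, corLen = size / 6.4,
                        spotDensity = 0.03, noiseSD = 4) {
  new("SynthConfig", nNormal = as.integer(nNormal),
      nAbnormal = as.integer(nAbnormal), size = as.integer(size),
      seed = as.integer(seed), contrast = as.numeric(contrast),
      corLen = as.numeric(corLen), spotDensity = as.numeric(spotDensity),
      noiseSD = as.numeric(noiseSD))
}

#' @rdname PCAFilterBank-accessors
#' @param x a \code{PCAFilterBank}.
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))
#' @rdname PCAFilterBank-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname PCAFilterBank-accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname PCAFilterBank-accessors
#' @export
setGeneric("nFilters", function(x) standardGeneric("nFilters"))

#' Accessors for PCAFilterBank
#'
#' \code{filters} returns the s1 x s2 x V kernel array, \code{eigenvalues}
#' the descending eigenvalues, \code{stage} the cascade stage, and
#' \code{nFilters} the filter count V.
#'
#' @name PCAFilterBank-accessors
#' @aliases filters eigenvalues stage nFilters
NULL

#' @rdname PCAFilterBank-accessors
setMethod("filters", "PCAFilterBank", function(x) x@filters)
#' @rdname PCAFilterBank-accessors
setMethod("eigenvalues", "PCAFilterBank", function(x) x@eigenvalues)
#' @rdname PCAFilterBank-accessors
setMethod("stage", "PCAFilterBank", function(x) x@stage)
#' @rdname PCAFilterBank-accessors
setMethod("nFilters", "PCAFilterBank", function(x) dim(x@filters)[3L])

setMethod("show", "PCAFilterBank", function(object) {
  d <- dim(object@filters)
  cat(sprintf("PCAFilterBank (stage %d): %d filters of %d x %d\n",
              object@stage, d[3L], d[1L], d[2L]))
  ev <- object@eigenvalues
  cat("eigenvalues:", paste(signif(utils::head(ev, 6), 4), collapse = " "),
      if (length(ev) > 6) "...\n" else "\n")
})

setMethod("show", "NetParams", function(object) {
  cat(sprintf(paste0(
    "NetParams: V1=%d V2=%d filter %dx%d L=%d\n",
    "  eps=%g a=%d gamma=%g alpha=%g beta=%g sigma=%g nLrn=%d\n",
    "  NT=%s MFA=%s HD=%s LRN=%s binarize=%s\n"),
    object@V1, object@V2, object@s1, object@s2, object@L,
    object@eps, object@a, object@gamma, object@alpha, object@beta,
    object@sigma, object@nLrn,
    object@useNT, object@useMFA, object@useHD, object@useLRN,
    object@binarizeSource))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d normal + %d abnormal, %dx%d px, ",
                     "contrast=%g, seed=%d\n"),
      object@nNormal, object@nAbnormal, object@size, object@size,
      object@contrast, object@seed))
})
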