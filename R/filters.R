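## Eigenfilter learning: the top-V eigenvectors of the pooled scatter
## matrix of mean-removed patches, reshaped to patch geometry.

#' Fix the sign of an eigenfilter
#'
#' Eigenvectors are defined up to sign; for reproducibility the kernel is
#' flipped, if needed, so that its entry of largest absolute value is
#' positive. Ties on |entry| are broken by the earliest row-major index.
#'
#' @param filt numeric matrix (non-zero kernel) or vector.
#' @return the kernel with the fixed sign.
#' @export
fixSign <- function(filt) {
  v <- if (is.matrix(filt)) as.vector(t(filt)) else filt
  if (all(v == 0)) stop("all-zero kernel has no sign")
  i <- which.max(abs(v))  # which.max returns the earliest maximum
  if (v[i] < 0) -filt else filt
}

#' Learn a stage's PCA filter bank from pooled patches
#'
#' Pools the (already mean-removed) patch matrices of all stage-input maps,
#' forms the scatter matrix T T'/(N p V) and keeps the eigenvectors of its
#' top \code{V} eigenvalues, reshaped (row-major, the inverse of the patch
#' flattening) to s1 x s2 kernels. The 1/(N p V) prefactor is applied for
#' fidelity to the learning rule as stated, but eigenvectors are invariant
#' to any positive rescaling of the scatter matrix, so it does not affect
#' the filters.
#'
#' Each eigenvector's sign follows \code{\link{fixSign}}. Eigenvalue ties
#' (relative gap below 1e-9) are ordered by the lexicographic order of the
#' sign-fixed vectors so the output is deterministic across platforms.
#'
#' @param patchSets a list of patch matrices (each (s1*s2) x p, zero-mean
#'   columns), or a single such matrix.
#' @param V number of filters to keep; at most s1*s2.
#' @param s1,s2 patch geometry.
#' @param stage cascade stage index stored in the bank (1 or 2).
#' @return a \code{\linkS4class{PCAFilterBank}}.
#' @export
#' @examples
#' img <- matrix(rnorm(100), 10, 10)
#' pm <- removePatchMeans(extractPatches(img, 3, 3))
#' learnFilters(list(pm), V = 4, s1 = 3, s2 = 3)
learnFilters <- function(patchSets, V, s1, s2, stage = 1L) {
  if (is.matrix(patchSets)) patchSets <- list(patchSets)
  d <- s1 * s2
  if (V > d) stop("V must not exceed s1*s2 = ", d)
  if (length(patchSets) == 0L) stop("no patch matrices supplied")
  scatter <- matrix(0, d, d)
  ptot <- 0L
  for (pm in patchSets) {
    if (nrow(pm) != d) stop("patch matrix rows do not match s1*s2")
    scatter <- scatter + tcrossprod(pm)
    ptot <- ptot + ncol(pm)
  }
  # ptot = N*p pooled patch columns, so this is the stated 1/(N p V) scaling
  scatter <- scatter / (max(ptot, 1L) * V)
  if (max(abs(scatter)) == 0)
    stop("degenerate scatter matrix: all patches are constant, ",
         "no principal directions exist")
  eg <- eigen(scatter, symmetric = TRUE)
  vals <- eg$values[seq_len(V)]
  vecs <- eg$vectors[, seq_len(V), drop = FALSE]
  vecs <- apply(vecs, 2L, fixSign)
  if (!is.matrix(vecs)) vecs <- matrix(vecs, nrow = d)
  # deterministic order inside groups of (numerically) tied eigenvalues
  tol <- 1e-9 * max(abs(eg$values[1L]), 1)
  grp <- cumsum(c(TRUE, diff(vals) < -tol))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      ord <- do.call(order, as.data.frame(t(vecs[, idx, drop = FALSE])))
      vecs[, idx] <- vecs[, idx[ord]]
    }
  }
  farr <- array(0, dim = c(s1, s2, V))
  for (j in seq_len(V))  # row-major reshape, inverse of patch flattening
    farr[, , j] <- matrix(vecs[, j], nrow = s1, ncol = s2, byrow = TRUE)
  new("PCAFilterBank", filters = farr, eigenvalues = vals,
      stage = as.integer(stage))
}

#' Write / read a filter bank as flat CSV
#'
#' One filter per row (row-major entries) with its eigenvalue; a header
#' records the geometry and stage.
#'
#' @param bank a \code{PCAFilterBank}.
#' @param path output CSV path.
#' @return \code{writeFilterBank} returns \code{path} invisibly;
#'   \code{readFilterBank} returns the reconstructed bank.
#' @export
writeFilterBank <- function(bank, path) {
  d <- dim(filters(bank))
  M <- t(apply(filters(bank), 3L, function(k) as.vector(t(k))))
  df <- data.frame(stage = stage(bank), s1 = d[1L], s2 = d[2L],
                   eigenvalue = eigenvalues(bank), M)
  names(df)[-(1:4)] <- paste0("w", seq_len(d[1L] * d[2L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFilterBank
#' @export
readFilterBank <- function(path) {
  df <- utils::read.csv(path)
  s1 <- df$s1[1L]; s2 <- df$s2[1L]; V <- nrow(df)
  farr <- array(0, dim = c(s1, s2, V))
  W <- as.matrix(df[, grep("^w", names(df)), drop = FALSE])
  for (j in seq_len(V))
    farr[, , j] <- matrix(W[j, ], nrow = s1, ncol = s2, byrow = TRUE)
  new("PCAFilterBank", filters = farr, eigenvalues = df$eigenvalue,
      stage = as.integer(df$stage[1L]))
}
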