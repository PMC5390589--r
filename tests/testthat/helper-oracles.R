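# Independent brute-force oracles and small fixture builders.

# nested-loop zero-padded correlation with per-patch mean removal and tanh
convOracle <- function(img, filt) {
  s1 <- nrow(filt); s2 <- ncol(filt)
  p1 <- s1 %/% 2L; p2 <- s2 %/% 2L
  m <- nrow(img); n <- ncol(img)
  pad <- matrix(0, m + 2L * p1, n + 2L * p2)
  pad[p1 + seq_len(m), p2 + seq_len(n)] <- img
  out <- matrix(0, m, n)
  for (r in seq_len(m)) for (cc in seq_len(n)) {
    patch <- pad[r:(r + s1 - 1L), cc:(cc + s2 - 1L)]
    patch <- patch - mean(patch)
    out[r, cc] <- tanh(sum(patch * filt))
  }
  out
}

# explicit column-by-column scatter accumulation and eigendecomposition
pcaOracle <- function(patchSets, V) {
  d <- nrow(patchSets[[1L]])
  S <- matrix(0, d, d)
  for (pm in patchSets)
    for (q in seq_len(ncol(pm)))
      S <- S + pm[, q] %*% t(pm[, q])
  eigen(S, symmetric = TRUE)$vectors[, seq_len(V), drop = FALSE]
}

# largest principal angle (radians) between the column spaces of A and B
subspaceAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(max(min(sv), -1), 1))
}

# vectorise a bank's filters row-major, one column per filter
bankMatrix <- function(bank) {
  apply(filters(bank), 3L, function(k) as.vector(t(k)))
}

randomImage <- function(m, n = m, seed = 1) {
  set.seed(seed)
  matrix(runif(m * n, 0, 255), m, n)
}

# small mixed-texture image set with enough variance to learn filters from
toyImages <- function(n = 6, size = 9, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(size * size, 0, 255),
                                        size, size))
}
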