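## Image loading, resizing, overlapping-patch extraction and per-patch mean
## removal: the shared front end of filter learning and convolution.

#' Load a raster image as a grayscale intensity matrix
#'
#' Reads PNG, JPEG or TIFF and returns a numeric matrix of intensities in
#' [0, 255]. Colour inputs are reduced to one channel with the ITU-R 601
#' luma weights (0.299, 0.587, 0.114); an alpha channel, if present, is
#' dropped.
#'
#' @param path path to a readable raster file; format is chosen by
#'   extension (.png, .jpg/.jpeg, .tif/.tiff).
#' @param toGray convert colour images to a single channel (default TRUE;
#'   FALSE on a colour image is an error, the pipeline is single-channel).
#' @return numeric matrix (height x width), intensities in [0, 255].
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- loadImage(f)
#' dim(img)
loadImage <- function(path, toGray = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(px) == 0L) stop("zero-sized image: ", path)
  if (length(dim(px)) == 3L) {
    d <- dim(px)
    if (d[3L] >= 3L) {
      if (!toGray) stop("colour image; the pipeline is single-channel")
      px <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
    } else {
      px <- px[, , 1L]  # grayscale stored with an extra plane
    }
    if (!is.matrix(px)) px <- matrix(px, d[1L], d[2L])
  }
  px * 255
}

#' Resize an image by bilinear interpolation
#'
#' Pixel-centre aligned sampling: output pixel (r, c) samples the input at
#' ((r - 0.5) * m/h + 0.5, (c - 0.5) * n/w + 0.5) with clamped borders, so
#' constant images are exactly resize-invariant and a same-size request
#' returns the input unchanged.
#'
#' @param img numeric matrix.
#' @param height,width target dimensions (>= 1).
#' @return numeric matrix of dimension \code{height x width}.
#' @export
resizeImage <- function(img, height, width) {
  stopifnot(is.matrix(img))
  if (height < 1 || width < 1) stop("target dimensions must be >= 1")
  m <- nrow(img); n <- ncol(img)
  if (height == m && width == n) return(img)
  ry <- (seq_len(height) - 0.5) * m / height + 0.5
  rx <- (seq_len(width)  - 0.5) * n / width  + 0.5
  y0 <- pmin(pmax(floor(ry), 1), m); y1 <- pmin(y0 + 1, m)
  x0 <- pmin(pmax(floor(rx), 1), n); x1 <- pmin(x0 + 1, n)
  wy <- pmin(pmax(ry - y0, 0), 1);   wx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  WY <- matrix(wy, height, width); WX <- matrix(wx, height, width,
                                                byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

#' Extract all overlapping patches of an image
#'
#' Collects every s1 x s2 patch at stride 1 (valid positions only), one
#' patch per column. Top-left corners are enumerated row-major, and each
#' patch is flattened row-major, so column q holds the patch whose corner
#' is row \code{(q-1) \%/\% (n-s2+1) + 1}. The patch count is
#' p = (m - s1 + 1)(n - s2 + 1).
#'
#' @param img numeric matrix (m x n).
#' @param s1,s2 patch height and width; must not exceed the image.
#' @return numeric matrix of dimension \code{(s1*s2) x p}.
#' @export
extractPatches <- function(img, s1, s2) {
  m <- nrow(img); n <- ncol(img)
  if (s1 > m || s2 > n) stop("patch size exceeds image size")
  pr <- m - s1 + 1L; pc <- n - s2 + 1L
  # element e of the row-major flattened patch has offsets (dr, dc)
  dr <- rep(0:(s1 - 1L), each = s2)
  dc <- rep(0:(s2 - 1L), times = s1)
  # corner q, row-major enumeration
  rr <- rep(seq_len(pr), each = pc)
  cc <- rep(seq_len(pc), times = pr)
  idx <- outer(dc * m + dr, (cc - 1L) * m + rr, "+")
  matrix(img[idx], nrow = s1 * s2, ncol = pr * pc)
}

#' Subtract each patch's own mean
#'
#' After removal every column of the patch matrix sums to zero; the
#' operation is idempotent.
#'
#' @param pm patch matrix as returned by \code{\link{extractPatches}}.
#' @return patch matrix of the same shape with zero-mean columns.
#' @export
removePatchMeans <- function(pm) {
  stopifnot(is.matrix(pm))
  sweep(pm, 2L, colMeans(pm), "-")
}

# zero-pad an image by (floor(s1/2), floor(s2/2)) on each side
padImage <- function(img, s1, s2) {
  p1 <- s1 %/% 2L; p2 <- s2 %/% 2L
  out <- matrix(0, nrow(img) + 2L * p1, ncol(img) + 2L * p2)
  out[p1 + seq_len(nrow(img)), p2 + seq_len(ncol(img))] <- img
  out
}
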