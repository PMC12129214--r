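# Centered, orthonormal discrete Fourier transforms.
#
# Every module in the package shares one DFT convention: the image-domain origin
# sits at the matrix center, the k-space DC component sits at the matrix center,
# and the transform is unitary (Parseval holds exactly). Concretely
#   k = fftshift(FFT(ifftshift(img))) / sqrt(H * W).

fftshift_idx <- function(n) {
  h <- floor(n / 2)
  c((h + 1):n, seq_len(h))
}

ifftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  c((h + 1):n, seq_len(h))
}

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

#' Centered orthonormal 2D DFT
#'
#' Forward transform from image space to k-space with the DC component at the
#' matrix center and unitary scaling (`1/sqrt(H*W)`), the convention shared by
#' all encoding and simulation code in the package.
#'
#' @param img complex (or numeric) matrix.
#' @return complex matrix of the same size.
#' @export
ft2c <- function(img) {
  fftshift2(stats::fft(ifftshift2(as.matrix(img)))) / sqrt(length(img))
}

#' Centered orthonormal 2D inverse DFT
#' @param ksp complex matrix (k-space, DC at center).
#' @return complex matrix of the same size.
#' @export
ift2c <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(as.matrix(ksp)), inverse = TRUE)) / sqrt(length(ksp))
}

# centered orthonormal 1D DFT (and inverse) along a vector
ft1c <- function(v) {
  n <- length(v)
  (stats::fft(v[ifftshift_idx(n)]) / sqrt(n))[fftshift_idx(n)]
}

ift1c <- function(v) {
  n <- length(v)
  (stats::fft(v[ifftshift_idx(n)], inverse = TRUE) / sqrt(n))[fftshift_idx(n)]
}
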