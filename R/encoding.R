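# Multi-coil, multi-contrast Cartesian encoding.
#
# The encoding operator maps a per-contrast image stack x (P x H x W) to
# multi-coil k-space y (P x C x H x W):
#   y[p, c] = M_p o F(C_c * x_p)
# with F the centered orthonormal 2D DFT and M_p the per-contrast sampling
# operator that zero-fills unmeasured points. Its adjoint combines coils with
# conjugate sensitivities. Complex data is carried natively; the real/imag
# channel split happens only at the denoiser boundary.

#' Multi-contrast k-space container
#'
#' @param data complex array P x C x H x W (contrast, coil, row, col).
#' @param seq optional `sequence_params` describing the contrast dimension.
#' @param scale normalization factor already applied to `data`.
#' @return object of class `multi_contrast_kspace`.
#' @export
multi_contrast_kspace <- function(data, seq = NULL, scale = 1) {
  if (length(dim(data)) != 4) stop_invalid("k-space must be P x C x H x W")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop_invalid("k-space entries must be finite")
  structure(list(data = data, seq = seq, scale = scale),
            class = "multi_contrast_kspace")
}

kspace_data <- function(y) if (inherits(y, "multi_contrast_kspace")) y$data else y
sens_maps <- function(s) if (inherits(s, "coil_sensitivities")) s$maps else s

#' Apply the forward encoding operator E
#'
#' @param x complex image stack, P x H x W (a matrix is treated as P = 1).
#' @param sens coil sensitivities (`coil_sensitivities` or complex C x H x W).
#' @param masks logical sampling masks, P x H x W (an H x W matrix is
#'   broadcast across contrasts).
#' @return complex k-space array P x C x H x W with unsampled points zero.
#' @export
apply_E <- function(x, sens, masks) {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  S <- sens_maps(sens)
  P <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]; C <- dim(S)[1]
  if (dim(S)[2] != H || dim(S)[3] != W) stop_invalid("sensitivity shape mismatch")
  masks <- as_mask3(masks, P, H, W)
  y <- array(0i, c(P, C, H, W))
  for (p in seq_len(P)) {
    m <- masks[p, , ]
    for (ci in seq_len(C)) {
      k <- ft2c(S[ci, , ] * x[p, , ])
      k[!m] <- 0i
      y[p, ci, , ] <- k
    }
  }
  y
}

#' Apply the adjoint encoding operator E^H
#'
#' `x_p = sum_c conj(C_c) * F^-1(M_p y[p, c])`; the exact adjoint of
#' [apply_E()] under the standard complex inner product.
#'
#' @param y k-space, P x C x H x W (or a `multi_contrast_kspace`).
#' @inheritParams apply_E
#' @return complex image stack P x H x W.
#' @export
apply_EH <- function(y, sens, masks) {
  y <- kspace_data(y)
  S <- sens_maps(sens)
  P <- dim(y)[1]; C <- dim(y)[2]; H <- dim(y)[3]; W <- dim(y)[4]
  if (dim(S)[1] != C || dim(S)[2] != H || dim(S)[3] != W)
    stop_invalid("sensitivity shape mismatch")
  masks <- as_mask3(masks, P, H, W)
  x <- array(0i, c(P, H, W))
  for (p in seq_len(P)) {
    m <- masks[p, , ]
    acc <- matrix(0i, H, W)
    for (ci in seq_len(C)) {
      k <- y[p, ci, , ]
      k[!m] <- 0i
      acc <- acc + Conj(S[ci, , ]) * ift2c(k)
    }
    x[p, , ] <- acc
  }
  x
}

#' The normal operator Q = E^H E + lambda I
#'
#' Self-adjoint and positive semi-definite; positive definite for
#' `lambda > 0`. This is the system operator of the data-consistency solve.
#'
#' @inheritParams apply_E
#' @param lambda non-negative regularization weight.
#' @return complex image stack P x H x W.
#' @export
normal_op <- function(x, sens, masks, lambda = 0) {
  if (lambda < 0) stop_invalid("lambda must be non-negative")
  apply_EH(apply_E(x, sens, masks), sens, masks) + lambda * x
}

#' Decouple a fully sampled readout axis into independent 2D problems
#'
#' Applies a centered orthonormal 1D inverse DFT along the readout axis of 3D
#' k-space (P x C x Nx x Ny x Nz), yielding one 2D multi-contrast k-space case
#' per readout position. [recombine_readout()] inverts the operation exactly.
#'
#' @param kspace3d complex array P x C x Nx x Ny x Nz (readout = 3rd axis).
#' @param masks optional logical P x Nx x Ny x Nz sampling masks; if supplied,
#'   every sampled (ky, kz) column must be fully sampled along the readout.
#' @return list of Nx complex arrays, each P x C x Ny x Nz.
#' @export
decouple_readout <- function(kspace3d, masks = NULL) {
  d <- dim(kspace3d)
  if (length(d) != 5) stop_invalid("expected a P x C x Nx x Ny x Nz array")
  P <- d[1]; C <- d[2]; Nx <- d[3]; Ny <- d[4]; Nz <- d[5]
  if (!is.null(masks)) {
    md <- dim(masks)
    if (length(md) != 4 || any(md != c(P, Nx, Ny, Nz)))
      stop_invalid("masks must be P x Nx x Ny x Nz")
    for (p in seq_len(P)) {
      cnt <- apply(masks[p, , , , drop = FALSE], c(3, 4), sum)
      if (any(cnt != 0 & cnt != Nx))
        stop_invalid("readout axis not fully sampled for some (ky, kz) column")
    }
  }
  hybrid <- kspace3d
  for (p in seq_len(P)) for (ci in seq_len(C)) for (j in seq_len(Ny)) for (k in seq_len(Nz))
    hybrid[p, ci, , j, k] <- ift1c(kspace3d[p, ci, , j, k])
  lapply(seq_len(Nx), function(ix) array(hybrid[, , ix, , ], c(P, C, Ny, Nz)))
}

#' @rdname decouple_readout
#' @param slices list of per-readout-position 2D cases, as produced by
#'   [decouple_readout()].
#' @export
recombine_readout <- function(slices) {
  Nx <- length(slices)
  d <- dim(slices[[1]])
  out <- array(0i, c(d[1], d[2], Nx, d[3], d[4]))
  for (ix in seq_len(Nx)) out[, , ix, , ] <- slices[[ix]]
  for (p in seq_len(d[1])) for (ci in seq_len(d[2]))
    for (j in seq_len(d[3])) for (k in seq_len(d[4]))
      out[p, ci, , j, k] <- ft1c(out[p, ci, , j, k])
  out
}

#' Per-case intensity normalization
#'
#' Scales k-space so that the zero-filled adjoint reconstruction has maximum
#' magnitude 1; the factor is recorded in `scale` so outputs can be mapped
#' back to the acquisition scale.
#'
#' @inheritParams apply_EH
#' @return a `multi_contrast_kspace` with scaled `data` and the applied `scale`.
#' @export
normalize_kspace <- function(y, sens, masks) {
  yd <- kspace_data(y)
  x0 <- apply_EH(yd, sens, masks)
  m <- max(Mod(x0))
  if (m == 0) stop_invalid("cannot normalize all-zero k-space")
  s <- 1 / m
  multi_contrast_kspace(yd * s,
                        seq = if (inherits(y, "multi_contrast_kspace")) y$seq else NULL,
                        scale = s)
}
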