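# Conjugate-gradient data-consistency solve.
#
# Each unroll solves (E^H E + lambda I) x = E^H y + lambda z for a fixed
# number of CG iterations, warm-started from the denoiser output z. The
# gradient with respect to z is the implicit/adjoint form: since Q is
# self-adjoint, d(loss)/dz = lambda * Q^{-1} g, computed by a second CG solve
# with the incoming gradient g as the right-hand side.

#' Unrolled-network configuration
#'
#' @param n_unrolls number of denoiser/data-consistency alternations
#'   (default 10).
#' @param cg_iters conjugate-gradient iterations per data-consistency solve
#'   (default 10, fixed — no tolerance-based early exit, for determinism).
#' @param lambda positive weight balancing data consistency against the
#'   denoiser prior (default 0.05).
#' @param cg_tol unused by default (kept for completeness; a positive value
#'   enables early exit on relative residual).
#' @param share_weights use one set of denoiser weights at every unroll.
#' @return object of class `unroll_config`.
#' @export
unroll_config <- function(n_unrolls = 10L, cg_iters = 10L, lambda = 0.05,
                          cg_tol = 0, share_weights = TRUE) {
  if (n_unrolls < 1 || cg_iters < 1) stop_invalid("need >= 1 unroll and CG iteration")
  if (lambda <= 0) stop_invalid("lambda must be positive")
  structure(list(n_unrolls = as.integer(n_unrolls), cg_iters = as.integer(cg_iters),
                 lambda = lambda, cg_tol = cg_tol, share_weights = share_weights),
            class = "unroll_config")
}

# CG on the normal operator; returns the iterate and the residual-norm history
cg_normal <- function(rhs, sens, masks, lambda, x0, iters, tol = 0) {
  x <- x0
  r <- rhs - normal_op(x, sens, masks, lambda)
  p <- r
  rs <- cdot(r, r)
  hist <- sqrt(rs)
  for (i in seq_len(iters)) {
    if (sqrt(rs) == 0) break
    Ap <- normal_op(p, sens, masks, lambda)
    alpha <- rs / cdot(p, Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- cdot(r, r)
    hist <- c(hist, sqrt(rs_new))
    if (tol > 0 && sqrt(rs_new) <= tol * hist[1]) { rs <- rs_new; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, resid = hist)
}

#' Data-consistency solve
#'
#' Runs `cfg$cg_iters` conjugate-gradient iterations on
#' `(E^H E + lambda I) x = E^H y + lambda z`, warm-started at `z`.
#'
#' @param z complex image stack P x H x W (denoiser output / prior).
#' @param y measured k-space (array or `multi_contrast_kspace`).
#' @param sens coil sensitivities.
#' @param masks sampling masks for `y`.
#' @param cfg an `unroll_config` (uses `lambda`, `cg_iters`, `cg_tol`).
#' @param keep_resid also return the CG residual-norm history.
#' @return complex image stack, or a list `(x, resid)` if `keep_resid`.
#' @export
dc_solve <- function(z, y, sens, masks, cfg, keep_resid = FALSE) {
  yd <- kspace_data(y)
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z))))
    stop_invalid("non-finite input to the data-consistency solve")
  rhs <- apply_EH(yd, sens, masks) + cfg$lambda * z
  out <- cg_normal(rhs, sens, masks, cfg$lambda, z, cfg$cg_iters, cfg$cg_tol)
  if (keep_resid) out else out$x
}

# adjoint of the DC solve w.r.t. z: lambda * Q^{-1} g (implicit gradient)
dc_backward <- function(g, sens, masks, cfg) {
  sol <- cg_normal(g, sens, masks, cfg$lambda, 0 * g, cfg$cg_iters, cfg$cg_tol)
  cfg$lambda * sol$x
}
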