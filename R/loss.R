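# Reconstruction loss: normalized L1 plus normalized L2 over complex k-space,
#   L(u, v) = ||u - v||_1 / ||u||_1 + ||u - v||_2 / ||u||_2,
# where the L1 norm is the sum of complex moduli and the L2 norm the Euclidean
# norm of the moduli. The loss is invariant to a common rescaling of u and v.

#' Normalized L1 + L2 reconstruction loss
#'
#' @param u reference complex k-space tensor (must not be all zero).
#' @param v predicted complex k-space tensor, same shape.
#' @return non-negative scalar; 0 iff `u == v`, exactly 2 when `v = 0`.
#' @export
recon_loss <- function(u, v) {
  if (!identical(dim(u), dim(v))) stop_invalid("u and v must share a shape")
  n1 <- sum(Mod(u)); n2 <- sqrt(sum(Mod(u)^2))
  if (n1 == 0) stop_invalid("reference u must not be all zero")
  d <- u - v
  sum(Mod(d)) / n1 + sqrt(sum(Mod(d)^2)) / n2
}

# gradient of recon_loss w.r.t. v, as a complex array with the convention
# g = dL/dRe(v) + i dL/dIm(v)
recon_loss_grad <- function(u, v) {
  n1 <- sum(Mod(u)); n2 <- sqrt(sum(Mod(u)^2))
  if (n1 == 0) stop_invalid("reference u must not be all zero")
  d <- v - u
  md <- Mod(d)
  g1 <- d
  nz <- md > 0
  g1[nz] <- d[nz] / md[nz]
  g1[!nz] <- 0i
  l2 <- sqrt(sum(md^2))
  g2 <- if (l2 > 0) d / l2 else 0i * d
  g1 / n1 + g2 / n2
}
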