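# Residual convolutional denoiser.
#
# The complex contrast stack (P x H x W) is split into 2P real channels
# ([Re(contrast 1..P), Im(contrast 1..P)]), passed through an input 3x3
# convolution, n_blocks residual blocks (conv 3x3 -> ReLU -> conv 3x3 -> scale
# by alpha, plus a block skip), an output 3x3 convolution, and a global skip
# that adds the input; the result is mapped back to complex. Forward and
# backward passes are hand-written (the convolution kernels live in src/),
# which keeps the whole computation graph explicit for the gradient
# checkpointing contract.

#' Initialize denoiser parameters
#'
#' He-style Gaussian initialization of the input/output convolutions and
#' `n_blocks` residual blocks (each two 3x3 convolutions with `n_filters`
#' channels and a residual scaling `alpha_scale`).
#'
#' @param n_contrasts number of complex contrasts P (input has 2P channels).
#' @param n_filters convolution width (default 64).
#' @param n_blocks number of residual blocks (default 10).
#' @param alpha_scale residual scaling factor (default 0.1).
#' @param seed integer seed for the weight draw.
#' @return object of class `denoiser_params`.
#' @export
denoiser_params <- function(n_contrasts, n_filters = 64L, n_blocks = 10L,
                            alpha_scale = 0.1, seed = 1L) {
  if (alpha_scale <= 0) stop_invalid("alpha_scale must be positive")
  if (n_blocks < 1 || n_filters < 1) stop_invalid("need >= 1 block and filter")
  cin <- 2L * n_contrasts
  he <- function(k, ci, co) array(rnorm(k * k * ci * co, 0, sqrt(2 / (k * k * ci))),
                                  c(k, k, ci, co))
  p <- with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b)
      list(w1 = he(3, n_filters, n_filters), b1 = numeric(n_filters),
           w2 = he(3, n_filters, n_filters), b2 = numeric(n_filters)))
    list(w_in = he(3, cin, n_filters), b_in = numeric(n_filters),
         blocks = blocks,
         w_out = he(3, n_filters, cin), b_out = numeric(cin))
  })
  structure(c(p, list(n_contrasts = as.integer(n_contrasts),
                      n_filters = as.integer(n_filters),
                      n_blocks = as.integer(n_blocks),
                      alpha_scale = alpha_scale)),
            class = "denoiser_params")
}

#' Zero-weight denoiser (identity through the global skip)
#' @inheritParams denoiser_params
#' @return a `denoiser_params` whose forward map is the identity.
#' @export
zero_denoiser_params <- function(n_contrasts, n_filters = 8L, n_blocks = 2L,
                                 alpha_scale = 0.1) {
  p <- denoiser_params(n_contrasts, n_filters, n_blocks, alpha_scale, seed = 1L)
  scale_params(p, 0)
}

# elementwise map over the numeric leaves of a parameter list
map_params <- function(p, f) {
  p$w_in <- f(p$w_in); p$b_in <- f(p$b_in)
  p$blocks <- lapply(p$blocks, function(b)
    list(w1 = f(b$w1), b1 = f(b$b1), w2 = f(b$w2), b2 = f(b$b2)))
  p$w_out <- f(p$w_out); p$b_out <- f(p$b_out)
  p
}

map2_params <- function(p, q, f) {
  p$w_in <- f(p$w_in, q$w_in); p$b_in <- f(p$b_in, q$b_in)
  p$blocks <- Map(function(a, b)
    list(w1 = f(a$w1, b$w1), b1 = f(a$b1, b$b1),
         w2 = f(a$w2, b$w2), b2 = f(a$b2, b$b2)),
    p$blocks, q$blocks)
  p$w_out <- f(p$w_out, q$w_out); p$b_out <- f(p$b_out, q$b_out)
  p
}

scale_params <- function(p, s) map_params(p, function(x) x * s)
add_params <- function(p, q) map2_params(p, q, `+`)

zero_like_params <- function(p) scale_params(p, 0)

param_vector <- function(p) {
  c(as.vector(p$w_in), p$b_in,
    unlist(lapply(p$blocks, function(b) c(as.vector(b$w1), b$b1, as.vector(b$w2), b$b2))),
    as.vector(p$w_out), p$b_out)
}

complex_to_channels <- function(x) {
  P <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  ch <- array(0, c(H, W, 2 * P))
  for (p in seq_len(P)) {
    ch[, , p] <- Re(x[p, , ])
    ch[, , P + p] <- Im(x[p, , ])
  }
  ch
}

channels_to_complex <- function(ch) {
  P <- dim(ch)[3] / 2
  H <- dim(ch)[1]; W <- dim(ch)[2]
  x <- array(0i, c(P, H, W))
  for (p in seq_len(P))
    x[p, , ] <- matrix(complex(real = ch[, , p], imaginary = ch[, , P + p]), H, W)
  x
}

# forward pass in channel space; returns output and, optionally, the
# activation cache needed for the backward pass
denoiser_fwd_ch <- function(ch, params, keep_cache = FALSE) {
  .qmap_state$denoiser_evals <- .qmap_state$denoiser_evals + 1L
  h <- .conv2d_fwd(ch, params$w_in, params$b_in)
  cache <- if (keep_cache) list(x = ch, blocks = vector("list", params$n_blocks)) else NULL
  for (b in seq_len(params$n_blocks)) {
    blk <- params$blocks[[b]]
    r1 <- .conv2d_fwd(h, blk$w1, blk$b1)
    a <- r1 * (r1 > 0)
    r2 <- .conv2d_fwd(a, blk$w2, blk$b2)
    if (keep_cache) cache$blocks[[b]] <- list(h_in = h, a = a, relu_mask = r1 > 0)
    h <- h + params$alpha_scale * r2
  }
  if (keep_cache) cache$h_out <- h
  out <- .conv2d_fwd(h, params$w_out, params$b_out) + ch
  list(out = out, cache = cache)
}

# backward pass; g is the gradient w.r.t. the channel-space output
denoiser_bwd_ch <- function(cache, params, g) {
  grads <- zero_like_params(params)
  bw <- .conv2d_bwd(cache$h_out, params$w_out, g)
  grads$w_out <- bw$gw; grads$b_out <- bw$gb
  gh <- bw$gx
  for (b in rev(seq_len(params$n_blocks))) {
    blk <- params$blocks[[b]]
    cb <- cache$blocks[[b]]
    g_r2 <- params$alpha_scale * gh
    bw2 <- .conv2d_bwd(cb$a, blk$w2, g_r2)
    g_r1 <- bw2$gx * cb$relu_mask
    bw1 <- .conv2d_bwd(cb$h_in, blk$w1, g_r1)
    grads$blocks[[b]] <- list(w1 = bw1$gw, b1 = bw1$gb, w2 = bw2$gw, b2 = bw2$gb)
    gh <- gh + bw1$gx
  }
  bwi <- .conv2d_bwd(cache$x, params$w_in, gh)
  grads$w_in <- bwi$gw; grads$b_in <- bwi$gb
  gx <- bwi$gx + g        # global skip
  list(gx = gx, grads = grads)
}

#' Apply the denoiser to a complex contrast stack
#'
#' @param x complex image stack P x H x W.
#' @param params a `denoiser_params` with matching `n_contrasts`.
#' @return denoised complex image stack of the same shape.
#' @export
denoise <- function(x, params) {
  if (dim(x)[1] != params$n_contrasts)
    stop_invalid("contrast count does not match denoiser channels")
  fw <- denoiser_fwd_ch(complex_to_channels(x), params)
  channels_to_complex(fw$out)
}
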