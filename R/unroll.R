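# The unrolled reconstruction network.
#
# x_0 = E^H y; for n = 1..N: z_n = D_w(x_n), x_{n+1} = DC(z_n). One set of
# denoiser weights is shared across unrolls. Two training-time modes share a
# bit-identical forward pass and differ only in what the tape retains:
#   - plain: every denoiser activation cache is stored (memory grows with the
#     number of residual blocks);
#   - checkpointed: only the per-unroll denoiser *inputs* are stored, and the
#     activations are recomputed from those checkpoints during the backward
#     pass (memory bounded by n_unrolls checkpoints + one block-level cache).

#' Unrolled reconstruction
#'
#' @param y measured k-space (array P x C x H x W or `multi_contrast_kspace`).
#' @param sens coil sensitivities.
#' @param masks sampling masks matching `y`.
#' @param dparams a `denoiser_params`.
#' @param cfg an `unroll_config`.
#' @return reconstructed complex image stack P x H x W.
#' @export
unrolled_recon <- function(y, sens, masks, dparams, cfg) {
  recon_forward(y, sens, masks, dparams, cfg, tape = FALSE)$x
}

#' @rdname unrolled_recon
#' @details `checkpointed_unrolled_recon` produces a bit-identical forward
#'   result; the difference is only in what a training tape would retain.
#' @export
checkpointed_unrolled_recon <- function(y, sens, masks, dparams, cfg) {
  recon_forward(y, sens, masks, dparams, cfg, tape = FALSE, checkpoint = TRUE)$x
}

#' Forward pass with an optional gradient tape
#'
#' Training-time entry point. With `tape = TRUE` the returned object carries
#' what the backward pass needs: full activation caches (`checkpoint = FALSE`)
#' or only the per-unroll denoiser inputs (`checkpoint = TRUE`).
#'
#' @inheritParams unrolled_recon
#' @param tape retain backward-pass state.
#' @param checkpoint retain only per-unroll checkpoints instead of full caches.
#' @return list with `x` (reconstruction) and, when taped, `tape`.
#' @export
recon_forward <- function(y, sens, masks, dparams, cfg, tape = TRUE,
                          checkpoint = FALSE) {
  yd <- kspace_data(y)
  x <- apply_EH(yd, sens, masks)
  caches <- if (tape && !checkpoint) vector("list", cfg$n_unrolls) else NULL
  ckpts <- if (tape && checkpoint) vector("list", cfg$n_unrolls) else NULL
  for (n in seq_len(cfg$n_unrolls)) {
    ch <- complex_to_channels(x)
    if (tape && checkpoint) ckpts[[n]] <- ch
    fw <- denoiser_fwd_ch(ch, dparams, keep_cache = tape && !checkpoint)
    if (tape && !checkpoint) caches[[n]] <- fw$cache
    z <- channels_to_complex(fw$out)
    x <- dc_solve(z, yd, sens, masks, cfg)
  }
  tp <- if (tape) list(caches = caches, checkpoints = ckpts,
                       checkpointed = checkpoint, y = yd) else NULL
  list(x = x, tape = tp)
}

#' Backward pass through the unrolled network
#'
#' Propagates a gradient with respect to the reconstruction back to the shared
#' denoiser weights. The data-consistency layers use the implicit (adjoint CG)
#' gradient; denoiser activations come from the tape, recomputed from the
#' stored checkpoints in checkpointed mode.
#'
#' @param g_x complex gradient w.r.t. the reconstructed image stack.
#' @param fwd the output of [recon_forward()] with `tape = TRUE`.
#' @inheritParams unrolled_recon
#' @return a `denoiser_params`-shaped list of accumulated weight gradients.
#' @export
recon_backward <- function(g_x, fwd, sens, masks, dparams, cfg) {
  tp <- fwd$tape
  if (is.null(tp)) stop_invalid("forward pass was not taped")
  grads <- zero_like_params(dparams)
  g <- g_x
  for (n in rev(seq_len(cfg$n_unrolls))) {
    g_z <- dc_backward(g, sens, masks, cfg)
    if (tp$checkpointed) {
      cache <- denoiser_fwd_ch(tp$checkpoints[[n]], dparams, keep_cache = TRUE)$cache
    } else {
      cache <- tp$caches[[n]]
    }
    g_z_ch <- complex_to_channels_grad(g_z)
    bw <- denoiser_bwd_ch(cache, dparams, g_z_ch)
    grads <- add_params(grads, bw$grads)
    g <- channels_to_complex_grad(bw$gx)
  }
  grads
}

# Gradients are carried as complex arrays with the convention
# g = dL/dRe + i dL/dIm; splitting/merging channels is then the same
# operation as for the data itself.
complex_to_channels_grad <- complex_to_channels
channels_to_complex_grad <- channels_to_complex

#' Count the activation arrays a training tape retains
#'
#' The measurable memory contract of checkpointing: the checkpointed tape
#' holds one array per unroll (independent of the number of residual blocks),
#' while the plain tape holds the per-block activation caches.
#'
#' @param fwd output of [recon_forward()] with `tape = TRUE`.
#' @return integer number of retained arrays.
#' @export
tape_array_count <- function(fwd) {
  tp <- fwd$tape
  if (is.null(tp)) return(0L)
  count_arrays <- function(x) {
    if (is.array(x) || is.matrix(x)) return(1L)
    if (is.list(x)) return(sum(vapply(x, count_arrays, integer(1))))
    0L
  }
  count_arrays(tp$caches) + count_arrays(tp$checkpoints)
}
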