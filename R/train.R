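# Training regimes.
#
# Supervised (SL): loss between the fully sampled reference and the full
# k-space projection of the network output.
# Self-supervised (SSL): the measured region Omega is split 60/40 into a
# network-input subset Theta and a held-out loss subset Lambda; no fully
# sampled data is touched anywhere (enforced by an access guard).
# Zero-shot (ZSSSL): a single case; training on Theta -> Lambda, validation on
# Xi -> Gamma, early stopping on the validation loss.
#
# The optimizer is Adam with per-strategy default learning rates
# (1e-4 SL/SSL, 5e-4 ZSSSL). Cases are visited in a fixed order, so a fixed
# seed reproduces losses bit for bit.

#' Training configuration
#'
#' @param strategy `"SL"`, `"SSL"` or `"ZSSSL"`.
#' @param learning_rate Adam step size; defaults to 1e-4 (SL, SSL) or
#'   5e-4 (ZSSSL).
#' @param epochs maximum epochs (default 100).
#' @param batch_size cases per optimizer step (default 2).
#' @param accumulation_steps microbatches a batch is split into for gradient
#'   accumulation (must divide into the batch; arithmetic is unchanged).
#' @param patience ZSSSL early-stopping patience in epochs (default 25):
#'   training stops once the validation loss has failed to improve for more
#'   than `patience` consecutive epochs.
#' @param seed integer seed recorded with the run (weight initialization is
#'   the caller's, via [denoiser_params()]).
#' @return object of class `train_config`.
#' @export
train_config <- function(strategy = c("SL", "SSL", "ZSSSL"),
                         learning_rate = NULL, epochs = 100L, batch_size = 2L,
                         accumulation_steps = 1L, patience = 25L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(learning_rate))
    learning_rate <- if (strategy == "ZSSSL") 5e-4 else 1e-4
  if (learning_rate < 0) stop_invalid("learning_rate must be non-negative")
  if (strategy == "ZSSSL" && patience < 1) stop_invalid("patience must be >= 1")
  structure(list(strategy = strategy, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 accumulation_steps = as.integer(accumulation_steps),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble a training case
#'
#' Masks the fully sampled k-space to the measured region Omega, applies the
#' per-case intensity normalization (max of the zero-filled adjoint scaled to
#' 1), and — for the self-supervised strategies — strips the fully sampled
#' reference and installs an access guard that errors on any attempt to read
#' it.
#'
#' @param case a `qmri_case` from [synthesize_case()] (or a list with
#'   `kspace`, `sens`).
#' @param part a partition: for SL a list with `omega`; for SSL additionally
#'   `theta`/`lam`; for ZSSSL a full `sampling_partition`.
#' @param strategy `"SL"`, `"SSL"` or `"ZSSSL"`.
#' @return object of class `training_case` (guarded for SSL/ZSSSL).
#' @export
training_case <- function(case, part, strategy = c("SL", "SSL", "ZSSSL")) {
  strategy <- match.arg(strategy)
  y_full <- kspace_data(case$kspace)
  P <- dim(y_full)[1]; H <- dim(y_full)[3]; W <- dim(y_full)[4]
  omega <- as_mask3(part$omega, P, H, W)
  y_om <- mask_kspace(y_full, omega)
  scl <- 1 / max(Mod(apply_EH(y_om, case$sens, omega)))

  tc <- list(y_omega = y_om * scl, sens = case$sens, omega = omega,
             part = part, scale = scl, seq = case$seq)
  if (strategy == "SL") {
    tc$y_full <- y_full * scl
    class(tc) <- "training_case"
  } else {
    class(tc) <- c("guarded_case", "training_case")
    attr(tc, "forbidden") <- c("y_full", "contrasts", "maps", "kspace")
  }
  tc
}

#' @export
`$.guarded_case` <- function(x, name) {
  if (name %in% attr(x, "forbidden"))
    stop_data("fully sampled data is not accessible under a self-supervised regime")
  .subset2(x, name)
}

#' @export
`[[.guarded_case` <- function(x, i, ...) {
  if (is.character(i) && i %in% attr(x, "forbidden"))
    stop_data("fully sampled data is not accessible under a self-supervised regime")
  .subset2(x, i)
}

# zero k-space outside a P x H x W mask (broadcast across the coil axis)
mask_kspace <- function(y, mask3) {
  y <- kspace_data(y)
  out <- y
  for (p in seq_len(dim(y)[1])) {
    m <- mask3[p, , ]
    for (ci in seq_len(dim(y)[2])) {
      k <- out[p, ci, , ]
      k[!m] <- 0i
      out[p, ci, , ] <- k
    }
  }
  out
}

full_masks_like <- function(y) {
  d <- dim(kspace_data(y))
  array(TRUE, c(d[1], d[3], d[4]))
}

# input/target masks and reference per strategy and phase
case_io <- function(tc, strategy, phase = c("train", "val")) {
  phase <- match.arg(phase)
  if (strategy == "SL") {
    list(y_in = tc$y_omega, m_in = tc$omega,
         m_tgt = full_masks_like(tc$y_omega), u = tc$y_full)
  } else if (strategy == "SSL" || (strategy == "ZSSSL" && phase == "train")) {
    P <- dim(tc$y_omega)[1]; H <- dim(tc$y_omega)[3]; W <- dim(tc$y_omega)[4]
    th <- as_mask3(tc$part$theta, P, H, W); la <- as_mask3(tc$part$lam, P, H, W)
    list(y_in = mask_kspace(tc$y_omega, th), m_in = th,
         m_tgt = la, u = mask_kspace(tc$y_omega, la))
  } else {
    P <- dim(tc$y_omega)[1]; H <- dim(tc$y_omega)[3]; W <- dim(tc$y_omega)[4]
    xi <- as_mask3(tc$part$xi, P, H, W); ga <- as_mask3(tc$part$gamma, P, H, W)
    list(y_in = mask_kspace(tc$y_omega, xi), m_in = xi,
         m_tgt = ga, u = mask_kspace(tc$y_omega, ga))
  }
}

# loss and (optionally) weight gradients for one case
case_loss <- function(tc, dparams, net_cfg, strategy, phase = "train",
                      with_grad = FALSE) {
  io <- case_io(tc, strategy, phase)
  fw <- recon_forward(io$y_in, tc$sens, io$m_in, dparams, net_cfg,
                      tape = with_grad, checkpoint = TRUE)
  v <- apply_E(fw$x, tc$sens, io$m_tgt)
  loss <- recon_loss(io$u, v)
  if (!with_grad) return(list(loss = loss))
  g_v <- recon_loss_grad(io$u, v)
  g_x <- apply_EH(g_v, tc$sens, io$m_tgt)
  grads <- recon_backward(g_x, fw, tc$sens, io$m_in, dparams, net_cfg)
  list(loss = loss, grads = grads)
}

adam_init <- function(params) list(m = zero_like_params(params),
                                   v = zero_like_params(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(scale_params(state$m, beta1), scale_params(grads, 1 - beta1), `+`)
  state$v <- map2_params(scale_params(state$v, beta2),
                         map_params(grads, function(g) (1 - beta2) * g^2), `+`)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = map2_params(params, upd, `-`), state = state)
}

#' Training history
#'
#' Per-epoch train/validation losses plus the best-validation epoch and the
#' reason training ended (`"max_epochs"` or `"early_stop"`).
#' @keywords internal
train_history <- function(train_loss, val_loss, best_epoch, stop_reason) {
  structure(list(train_loss = train_loss, val_loss = val_loss,
                 best_epoch = best_epoch, stop_reason = stop_reason),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat("<train_history> ", length(x$train_loss), " epochs, best val ",
      signif(min(x$val_loss), 4), " at epoch ", x$best_epoch,
      " (", x$stop_reason, ")\n", sep = "")
  invisible(x)
}

run_training <- function(train_cases, val_cases, dparams, net_cfg, cfg,
                         early_stop = FALSE) {
  state <- adam_init(dparams)
  params <- dparams
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  streak <- 0L
  tl <- vl <- numeric(0)
  stop_reason <- "max_epochs"

  n <- length(train_cases)
  for (epoch in seq_len(cfg$epochs)) {
    epoch_losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      batch <- train_cases[seq(i, min(i + cfg$batch_size - 1L, n))]
      i <- i + cfg$batch_size
      gsum <- NULL
      # gradient accumulation: microbatches contribute case gradients one at
      # a time; the sum is divided by the batch size at the end, so the
      # result is independent of accumulation_steps
      for (tc in batch) {
        cl <- case_loss(tc, params, net_cfg, cfg$strategy, "train", with_grad = TRUE)
        epoch_losses <- c(epoch_losses, cl$loss)
        gsum <- if (is.null(gsum)) cl$grads else add_params(gsum, cl$grads)
      }
      gmean <- scale_params(gsum, 1 / length(batch))
      st <- adam_step(params, gmean, state, cfg$learning_rate)
      params <- st$params; state <- st$state
    }
    tl <- c(tl, mean(epoch_losses))

    vlosses <- vapply(val_cases, function(tc)
      case_loss(tc, params, net_cfg, cfg$strategy, "val")$loss, numeric(1))
    v <- mean(vlosses)
    vl <- c(vl, v)
    if (v < best_val) {
      best_val <- v; best_params <- params; best_epoch <- epoch; streak <- 0L
    } else {
      streak <- streak + 1L
      if (early_stop && streak > cfg$patience) { stop_reason <- "early_stop"; break }
    }
  }
  list(params = best_params,
       history = train_history(tl, vl, best_epoch, stop_reason))
}

#' Supervised training
#'
#' Minimizes the normalized L1+L2 loss between the fully sampled reference and
#' the full k-space projection of the network output; returns the weights with
#' the best validation loss.
#'
#' @param train_cases,val_cases lists of `training_case` objects built with
#'   strategy `"SL"` (they must carry `y_full`).
#' @param dparams initial `denoiser_params`.
#' @param net_cfg an `unroll_config`.
#' @param cfg a `train_config` with strategy `"SL"`.
#' @return list with `params` (best-validation `denoiser_params`) and
#'   `history` (a `train_history`).
#' @export
train_supervised <- function(train_cases, val_cases, dparams, net_cfg,
                             cfg = train_config("SL")) {
  if (cfg$strategy != "SL") stop_invalid("cfg$strategy must be SL")
  for (tc in train_cases) if (is.null(.subset2(tc, "y_full")))
    stop_invalid("supervised training requires fully sampled references")
  run_training(train_cases, val_cases, dparams, net_cfg, cfg)
}

#' Self-supervised (k-space partition) training
#'
#' Network input is the measured data restricted to Theta; the loss compares
#' the Lambda-projection of the output against the held-out Lambda samples.
#' Fully sampled data is never touched (the cases are access-guarded).
#'
#' @param train_cases,val_cases lists of `training_case` objects built with
#'   strategy `"SSL"` whose partitions provide `theta`/`lam`.
#' @inheritParams train_supervised
#' @param cfg a `train_config` with strategy `"SSL"`.
#' @return list with `params` and `history`.
#' @export
train_ssl <- function(train_cases, val_cases, dparams, net_cfg,
                      cfg = train_config("SSL")) {
  if (cfg$strategy != "SSL") stop_invalid("cfg$strategy must be SSL")
  for (tc in c(train_cases, val_cases))
    if (!any(as.logical(.subset2(tc, "part")$lam))) stop_invalid("Lambda is empty")
  run_training(train_cases, val_cases, dparams, net_cfg, cfg)
}

#' Zero-shot self-supervised training on a single case
#'
#' Trains on the (Theta -> Lambda) split and validates on (Xi -> Gamma) of the
#' same case; stops once the validation loss fails to improve for more than
#' `cfg$patience` consecutive epochs. Final inference should use the full
#' measured data, see [reconstruct_case()].
#'
#' @param case a single `training_case` built with strategy `"ZSSSL"` whose
#'   partition is nested (`theta + lam = xi`, `xi + gamma = omega`).
#' @inheritParams train_supervised
#' @param cfg a `train_config` with strategy `"ZSSSL"`.
#' @return list with `params` and `history`.
#' @export
train_zsssl <- function(case, dparams, net_cfg, cfg = train_config("ZSSSL")) {
  if (cfg$strategy != "ZSSSL") stop_invalid("cfg$strategy must be ZSSSL")
  part <- .subset2(case, "part")
  if (is.null(part$xi) || is.null(part$gamma))
    stop_invalid("ZSSSL needs a nested partition with xi and gamma")
  if (any((part$theta | part$lam) != part$xi) ||
      any((part$xi | part$gamma) != part$omega) ||
      any(part$theta & part$lam) || any(part$xi & part$gamma))
    stop_invalid("partition is not nested (theta+lam=xi, xi+gamma=omega)")
  run_training(list(case), list(case), dparams, net_cfg, cfg, early_stop = TRUE)
}

#' Reconstruct a case with trained weights
#'
#' Runs the unrolled network on the full measured region Omega (the standard
#' inference input for every strategy, including zero-shot) and undoes the
#' per-case normalization.
#'
#' @param tc a `training_case`.
#' @param dparams trained `denoiser_params`.
#' @param net_cfg an `unroll_config`.
#' @return complex image stack P x H x W on the acquisition scale.
#' @export
reconstruct_case <- function(tc, dparams, net_cfg) {
  x <- unrolled_recon(.subset2(tc, "y_omega"), .subset2(tc, "sens"),
                      .subset2(tc, "omega"), dparams, net_cfg)
  x / .subset2(tc, "scale")
}

#' Zero-filled adjoint baseline reconstruction
#'
#' Coil-combined adjoint of the measured data — the standard non-iterative
#' baseline every learned reconstruction is compared against.
#'
#' @inheritParams reconstruct_case
#' @return complex image stack P x H x W on the acquisition scale.
#' @export
zero_filled_recon <- function(tc) {
  apply_EH(.subset2(tc, "y_omega"), .subset2(tc, "sens"),
           .subset2(tc, "omega")) / .subset2(tc, "scale")
}
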