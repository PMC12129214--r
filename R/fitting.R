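# Parameter-map estimation from multi-contrast images.
#
# MSME T2: log-linear initialization followed by bounded Levenberg-Marquardt
# refinement of the mono-exponential model (minpack.lm::nls.lm).
# VFA T1: the classical DESPOT1 linearization (regress S/sin a on S/tan a;
# the slope is E1 = exp(-TR/T1)).
# qDESS T2: closed-form inversion of the echo/FID ratio (T2 appears in a
# single exponent).

#' Fit T2 and proton density from a multi-echo spin-echo decay
#'
#' Nonlinear least squares on `S_i = I0 exp(-TE_i/T2)`, initialized by
#' log-linear regression of `log |S|` on TE and refined with bounded
#' Levenberg-Marquardt. The fit is flagged invalid when any signal is
#' non-positive, the optimizer fails, or the estimate hits a bound.
#'
#' @param signals signal per echo (arbitrary units).
#' @param TE_list echo times in ms.
#' @param bounds admissible T2 range in ms, default `c(1, 5000)`.
#' @return list with `I0`, `T2` (ms) and `valid`.
#' @export
fit_t2_msme <- function(signals, TE_list, bounds = c(1, 5000)) {
  if (length(signals) < 2) stop_invalid("need at least 2 echoes")
  if (length(signals) != length(TE_list)) stop_invalid("signals/TE length mismatch")
  if (any(!is.finite(signals))) stop_invalid("signals must be finite")
  if (any(signals <= 0))
    return(list(I0 = NA_real_, T2 = NA_real_, valid = FALSE))

  fit0 <- stats::lm(log(signals) ~ TE_list)
  slope <- unname(coef(fit0)[2])
  T2_init <- if (is.finite(slope) && slope < 0) min(max(-1 / slope, bounds[1]), bounds[2]) else bounds[2]
  I0_init <- exp(unname(coef(fit0)[1]))

  res <- try(minpack.lm::nls.lm(
    par = c(I0 = I0_init, T2 = T2_init),
    lower = c(1e-12, bounds[1]), upper = c(Inf, bounds[2]),
    fn = function(p) signals - p[1] * exp(-TE_list / p[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$par[2]))
    return(list(I0 = I0_init, T2 = T2_init, valid = FALSE))

  T2 <- unname(res$par[2]); I0 <- unname(res$par[1])
  at_bound <- T2 <= bounds[1] * (1 + 1e-9) || T2 >= bounds[2] * (1 - 1e-9)
  list(I0 = I0, T2 = T2, valid = !at_bound)
}

#' Fit T1 and proton density from variable-flip-angle SPGR signals
#'
#' DESPOT1 linearization: with the sin-alpha signal form, `S/sin a` regressed
#' on `S/tan a` has slope `E1 = exp(-TR/T1)`; without it, `S` regressed on
#' `S cos a` has the same slope. A slope outside (0, 1) is non-physical and
#' flags the fit invalid.
#'
#' @param signals signal per flip angle.
#' @param flip_angles flip angles in degrees (>= 2 distinct values).
#' @param TR repetition time in ms.
#' @param include_sin whether the signals follow the sin-alpha form.
#' @param bounds admissible T1 range in ms, default `c(1, 10000)`.
#' @return list with `I0`, `T1` (ms) and `valid`.
#' @export
fit_t1_vfa <- function(signals, flip_angles, TR, include_sin = TRUE,
                       bounds = c(1, 10000)) {
  if (length(unique(flip_angles)) < 2) stop_invalid("need >= 2 distinct flip angles")
  if (length(signals) != length(flip_angles)) stop_invalid("signals/angle length mismatch")
  a <- flip_angles * pi / 180
  if (include_sin) {
    yy <- signals / sin(a); xx <- signals / tan(a)
  } else {
    yy <- signals; xx <- signals * cos(a)
  }
  fit <- stats::lm(yy ~ xx)
  E1 <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  if (!is.finite(E1) || E1 <= 0 || E1 >= 1)
    return(list(I0 = NA_real_, T1 = NA_real_, valid = FALSE))
  T1 <- -TR / log(E1)
  I0 <- icpt / (1 - E1)
  valid <- T1 > bounds[1] && T1 < bounds[2]
  T1 <- min(max(T1, bounds[1]), bounds[2])
  list(I0 = I0, T1 = T1, valid = valid)
}

#' Closed-form qDESS T2 map from FID and echo images
#'
#' Inverts the echo/FID ratio model pixelwise:
#' `T2 = -2 (TR - TE) / (log(r / F) + (TR - tau/3) dk^2 D)` with
#' `r = |echo| / |fid|`. Pixels with zero FID, a non-decaying ratio
#' (`r >= F` or `r <= 0`) or T2 outside `bounds` are flagged invalid.
#'
#' @param fid,echo FID and echo images (magnitudes are taken), same shape.
#' @param seq a `sequence_params` of kind QDESS; the TE entering the formula
#'   is the first (FID) echo time.
#' @param bounds admissible T2 range in ms, default `c(1, 500)`.
#' @param correction use the T1/diffusion steady-state factor (otherwise F = 1
#'   and the diffusion terms vanish).
#' @return list with `T2` grid (ms) and logical `valid` grid.
#' @export
fit_t2_qdess <- function(fid, echo, seq, bounds = c(1, 500), correction = TRUE) {
  if (seq$kind != "QDESS") stop_invalid("seq must be a QDESS protocol")
  fid <- as.matrix(Mod(fid)); echo <- as.matrix(Mod(echo))
  if (!all(dim(fid) == dim(echo))) stop_invalid("fid/echo shape mismatch")
  TE <- seq$TE_list[1]
  if (correction) {
    Ff <- qdess_F(seq)
    dk2D <- qdess_dk(seq)^2 * seq$diffusivity_D
    diff_term <- (seq$TR - seq$spoiler_duration_tau / 3) * dk2D
  } else {
    Ff <- 1; diff_term <- 0
  }
  r <- echo / fid
  denom <- log(r / Ff) + diff_term
  T2 <- -2 * (seq$TR - TE) / denom
  valid <- is.finite(r) & fid > 0 & r > 0 & r < Ff &
    is.finite(T2) & T2 > bounds[1] & T2 < bounds[2]
  T2[!valid] <- NA_real_
  list(T2 = T2, valid = valid)
}

#' Fit quantitative maps from a stack of contrast images
#'
#' Dispatches on the sequence kind: MSME yields PD + T2 (pixelwise nonlinear
#' fit), VFA-SPGR yields PD + T1 (vectorized DESPOT1 linearization), qDESS
#' yields T2 (closed form). Pixels whose first-contrast magnitude is zero are
#' skipped and flagged invalid.
#'
#' @param contrasts list of contrast-image grids (or complex grids; magnitudes
#'   are used), ordered as produced by the matching protocol.
#' @param seq a `sequence_params`.
#' @param include_sin VFA only: signal form, see [fit_t1_vfa()].
#' @return a `parameter_maps` object.
#' @export
fit_maps <- function(contrasts, seq, include_sin = TRUE) {
  mags <- lapply(contrasts, function(m) as.matrix(Mod(m)))
  H <- nrow(mags[[1]]); W <- ncol(mags[[1]])
  valid <- matrix(FALSE, H, W)

  if (seq$kind == "MSME") {
    if (length(mags) != length(seq$TE_list)) stop_invalid("contrast count != echo count")
    PD <- matrix(NA_real_, H, W); T2 <- matrix(NA_real_, H, W)
    sig <- sapply(mags, as.vector)          # (H*W) x n_echoes
    do_fit <- rowSums(sig <= 0) == 0
    for (i in which(do_fit)) {
      f <- fit_t2_msme(sig[i, ], seq$TE_list)
      PD[i] <- f$I0; T2[i] <- f$T2; valid[i] <- f$valid
    }
    return(parameter_maps(PD = PD, T2 = T2, validity = valid))
  }

  if (seq$kind == "VFA_SPGR") {
    if (length(mags) != length(seq$flip_angles)) stop_invalid("contrast count != angle count")
    a <- seq$flip_angles * pi / 180
    n <- length(a)
    sx <- sxx <- sy <- sxy <- matrix(0, H, W)
    for (i in seq_len(n)) {
      S <- mags[[i]]
      if (include_sin) { yy <- S / sin(a[i]); xx <- S / tan(a[i]) }
      else { yy <- S; xx <- S * cos(a[i]) }
      sx <- sx + xx; sy <- sy + yy; sxx <- sxx + xx^2; sxy <- sxy + xx * yy
    }
    den <- n * sxx - sx^2
    E1 <- (n * sxy - sx * sy) / den
    icpt <- (sy - E1 * sx) / n
    ok <- is.finite(E1) & E1 > 0 & E1 < 1
    T1 <- matrix(NA_real_, H, W); PD <- matrix(NA_real_, H, W)
    T1[ok] <- -seq$TR / log(E1[ok])
    PD[ok] <- icpt[ok] / (1 - E1[ok])
    valid <- ok & !is.na(T1) & T1 > 1 & T1 < 10000
    return(parameter_maps(PD = PD, T1 = T1, validity = valid))
  }

  if (seq$kind == "QDESS") {
    if (length(mags) != 2) stop_invalid("qDESS expects exactly FID and echo contrasts")
    f <- fit_t2_qdess(mags[[1]], mags[[2]], seq)
    return(parameter_maps(PD = mags[[1]], T2 = f$T2, validity = f$valid))
  }

  stop_invalid("unsupported sequence kind: ", seq$kind)
}
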