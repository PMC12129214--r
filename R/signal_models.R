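# Forward signal models for the three supported sequences.
#
# MSME:      S_i = I0 * exp(-TE_i / T2)                     (mono-exponential decay)
# VFA-SPGR:  S_i = I0 * sin(a_i) * (1 - E1) / (1 - E1 cos(a_i)),  E1 = exp(-TR/T1)
#            (the sin-alpha numerator is the standard DESPOT1 form; a variant
#             without it is selectable via include_sin = FALSE)
# qDESS:     S_echo / S_fid = F(alpha, T1, D) * exp(-2 (TR - TE)/T2 - (TR - tau/3) dk^2 D)
#            with F = sin^2(a/2) (1 + E) / (1 - cos(a) E),
#            E = exp(-TR/T1 - TR dk^2 D) and dk = gamma * G * tau.
#            With the steady-state correction off, the ratio reduces to the
#            plain exp(-2 (TR - TE)/T2) FID/echo relationship.

#' Construct sequence parameters
#'
#' @param kind one of `"MSME"`, `"VFA_SPGR"`, `"QDESS"`.
#' @param TE_list echo times in ms, strictly increasing.
#' @param TR repetition time in ms, larger than every TE.
#' @param flip_angles flip angles in degrees, in (0, 90].
#' @param assumed_T1 qDESS only: T1 (ms) assumed by the T2 estimator.
#' @param diffusivity_D qDESS only: apparent diffusivity in mm^2/s (default 0,
#'   which removes the diffusion terms).
#' @param spoiler_amplitude_G qDESS spoiler gradient amplitude, mT/m.
#' @param spoiler_duration_tau qDESS spoiler duration, ms.
#' @param gamma gyromagnetic ratio, rad/(s*mT), so that `dk = gamma * G * tau`
#'   (consistent units are the caller's responsibility; with the default
#'   `diffusivity_D = 0` they are irrelevant).
#' @return object of class `sequence_params`.
#' @export
sequence_params <- function(kind = c("MSME", "VFA_SPGR", "QDESS"),
                            TE_list, TR, flip_angles,
                            assumed_T1 = 1000, diffusivity_D = 0,
                            spoiler_amplitude_G = 30,
                            spoiler_duration_tau = 2,
                            gamma = 267.513) {
  kind <- match.arg(kind)
  TE_list <- as.numeric(TE_list)
  if (any(TE_list <= 0) || any(diff(TE_list) <= 0))
    stop_invalid("TE_list must be strictly increasing and positive")
  # qDESS reports the second echo at 2*TR - TE1, which exceeds TR by design;
  # for the other sequences every echo must fit inside the repetition time
  if (kind != "QDESS" && TR <= max(TE_list)) stop_invalid("TR must exceed every TE")
  if (kind == "QDESS" && TR <= TE_list[1]) stop_invalid("TR must exceed the FID echo time")
  if (any(flip_angles <= 0) || any(flip_angles > 90))
    stop_invalid("flip angles must lie in (0, 90] degrees")
  if (kind == "MSME" && length(TE_list) < 2) stop_invalid("MSME needs >= 2 echoes")
  if (kind == "VFA_SPGR" && length(unique(flip_angles)) < 2)
    stop_invalid("VFA needs >= 2 distinct flip angles")
  structure(list(kind = kind, TE_list = TE_list, TR = TR,
                 flip_angles = as.numeric(flip_angles),
                 assumed_T1 = assumed_T1, diffusivity_D = diffusivity_D,
                 spoiler_amplitude_G = spoiler_amplitude_G,
                 spoiler_duration_tau = spoiler_duration_tau, gamma = gamma),
            class = "sequence_params")
}

#' Standard protocols
#'
#' Convenience constructors mirroring common acquisition settings: a 16-echo
#' multi-echo spin-echo T2 protocol (TE 10-160 ms every 10, TR 4000 ms, 90
#' degree flip), a two-angle variable-flip-angle SPGR T1 protocol (4/24
#' degrees, TR 18 ms, TE 8 ms) and a knee-type qDESS protocol (TE 5.7/30.1 ms,
#' TR 17.9 ms, 20 degrees, assumed T1 1000 ms).
#'
#' @param n_echoes for `msme_protocol`, number of echoes retained; fewer than
#'   16 echoes are spread evenly across the 10-160 ms train so the TE range
#'   (and hence the T2-fit conditioning) is preserved.
#' @return a `sequence_params` object.
#' @export
msme_protocol <- function(n_echoes = 16L) {
  sequence_params("MSME", TE_list = seq(10, 160, length.out = n_echoes),
                  TR = 4000, flip_angles = 90)
}

#' @rdname msme_protocol
#' @export
vfa_protocol <- function() {
  sequence_params("VFA_SPGR", TE_list = 8, TR = 18, flip_angles = c(4, 24))
}

#' @rdname msme_protocol
#' @export
qdess_protocol <- function() {
  sequence_params("QDESS", TE_list = c(5.7, 30.1), TR = 17.9, flip_angles = 20,
                  assumed_T1 = 1000, diffusivity_D = 0)
}

#' Multi-echo spin-echo signal
#'
#' `S_i = I0 * exp(-TE_i / T2)`, vectorized over `TE_list` and over grids of
#' `I0`/`T2` (recycled elementwise).
#'
#' @param I0 proton density (arbitrary units), scalar or grid.
#' @param T2 T2 in ms, positive, scalar or grid.
#' @param TE_list echo times in ms.
#' @return numeric vector (per echo) for scalar inputs, or a list of grids.
#' @export
msme_signal <- function(I0, T2, TE_list) {
  if (any(T2 <= 0)) stop_invalid("T2 must be positive")
  if (any(TE_list < 0)) stop_invalid("TE must be non-negative")
  if (length(I0) == 1 && length(T2) == 1) return(I0 * exp(-TE_list / T2))
  lapply(TE_list, function(te) I0 * exp(-te / T2))
}

#' Spoiled gradient-echo signal
#'
#' With `include_sin = TRUE` (default): `S = I0 sin(a) (1 - E1)/(1 - E1 cos a)`
#' where `E1 = exp(-TR/T1)`; with `include_sin = FALSE` the sin numerator is
#' dropped.
#'
#' @param I0 proton density, scalar or grid.
#' @param T1 T1 in ms, positive.
#' @param TR repetition time in ms.
#' @param alpha flip angle in degrees (scalar).
#' @param include_sin include the `sin(alpha)` numerator factor.
#' @return signal, same shape as `I0`/`T1`.
#' @export
spgr_signal <- function(I0, T1, TR, alpha, include_sin = TRUE) {
  if (any(T1 <= 0)) stop_invalid("T1 must be positive")
  if (alpha <= 0 || alpha > 90) stop_invalid("alpha must lie in (0, 90] degrees")
  a <- alpha * pi / 180
  E1 <- exp(-TR / T1)
  s <- I0 * (1 - E1) / (1 - E1 * cos(a))
  if (include_sin) s <- s * sin(a)
  s
}

qdess_dk <- function(seq) seq$gamma * seq$spoiler_amplitude_G * seq$spoiler_duration_tau

# steady-state correction factor F(alpha, T1, D) of the echo/FID ratio
qdess_F <- function(seq, T1 = seq$assumed_T1) {
  a <- seq$flip_angles[1] * pi / 180
  dk2D <- qdess_dk(seq)^2 * seq$diffusivity_D
  E <- exp(-seq$TR / T1 - seq$TR * dk2D)
  sin(a / 2)^2 * (1 + E) / (1 - cos(a) * E)
}

#' qDESS echo-to-FID signal ratio
#'
#' Ratio of the second (echo) to first (FID) steady-state signal. With
#' `correction = TRUE` the T1/diffusion steady-state factor is applied:
#' `F * exp(-2 (TR - TE)/T2 - (TR - tau/3) dk^2 D)`; with `correction = FALSE`
#' the ratio is the plain `exp(-2 (TR - TE)/T2)`. TE is the first (FID) echo
#' time of the protocol.
#'
#' @param T2 T2 in ms, positive, scalar or grid.
#' @param seq a `sequence_params` of kind QDESS.
#' @param correction apply the T1/diffusion steady-state factor.
#' @return dimensionless ratio, same shape as `T2`.
#' @export
qdess_ratio <- function(T2, seq, correction = TRUE) {
  if (seq$kind != "QDESS") stop_invalid("seq must be a QDESS protocol")
  if (any(T2 <= 0)) stop_invalid("T2 must be positive")
  TE <- seq$TE_list[1]
  base <- exp(-2 * (seq$TR - TE) / T2)
  if (!correction) return(base)
  dk2D <- qdess_dk(seq)^2 * seq$diffusivity_D
  qdess_F(seq) * base * exp(-(seq$TR - seq$spoiler_duration_tau / 3) * dk2D)
}

# contrast-image series for a phantom's PD/T1/T2 grids under a given sequence
signal_model_images <- function(maps, seq) {
  switch(seq$kind,
    MSME = lapply(seq$TE_list, function(te) maps$PD * exp(-te / pmax(maps$T2, 1e-9))),
    VFA_SPGR = lapply(seq$flip_angles, function(a)
      spgr_signal(maps$PD, pmax(maps$T1, 1e-9), seq$TR, a)),
    QDESS = {
      fid <- maps$PD
      echo <- maps$PD * qdess_ratio(pmax(maps$T2, 1e-9), seq)
      list(fid, echo)
    },
    stop_invalid("unsupported sequence kind: ", seq$kind)
  )
}
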