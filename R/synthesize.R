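# Fully sampled multi-coil, multi-contrast k-space synthesis.
#
# Pipeline per contrast: evaluate the sequence signal model on the phantom's
# PD/T1/T2 grids, weight by each coil sensitivity, take the centered
# orthonormal 2D DFT, and add complex Gaussian noise whose standard deviation
# is a fixed fraction of the maximum k-space magnitude (default 0.01%), added
# independently to the real and imaginary parts.

#' Simulation configuration
#'
#' @param matrix_size `(rows, cols)`, both >= 8.
#' @param n_coils number of receive coils.
#' @param noise_fraction k-space noise standard deviation as a fraction of the
#'   maximum clean k-space magnitude; default `1e-4` (0.01 percent).
#' @param seed integer seed for the noise draw.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(matrix_size = c(64, 64), n_coils = 6L,
                       noise_fraction = 1e-4, seed = 1L) {
  if (any(matrix_size < 8)) stop_invalid("matrix dimensions must be >= 8")
  if (noise_fraction < 0) stop_invalid("noise_fraction must be non-negative")
  structure(list(matrix_size = as.integer(matrix_size),
                 n_coils = as.integer(n_coils),
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthesize a fully sampled multi-coil, multi-contrast case
#'
#' @param phantom a `tissue_phantom` whose grid matches `cfg$matrix_size`.
#' @param seq a `sequence_params` (MSME, VFA-SPGR or qDESS).
#' @param sens a `coil_sensitivities` on the same grid.
#' @param cfg a `sim_config`.
#' @return list of class `qmri_case`: `kspace` (`multi_contrast_kspace`,
#'   fully sampled, noisy per `cfg`), `maps` (ground-truth `parameter_maps`),
#'   `sens`, `contrasts` (clean complex contrast images P x H x W), `seq`,
#'   `cfg`.
#' @export
synthesize_case <- function(phantom, seq, sens, cfg) {
  H <- cfg$matrix_size[1]; W <- cfg$matrix_size[2]
  if (!all(dim(phantom$label_map) == c(H, W)))
    stop_invalid("phantom grid does not match cfg$matrix_size")
  S <- sens_maps(sens)
  if (dim(S)[1] != cfg$n_coils || dim(S)[2] != H || dim(S)[3] != W)
    stop_invalid("sensitivities do not match cfg (coils or grid)")

  maps <- phantom_maps(phantom)
  imgs <- signal_model_images(maps, seq)
  P <- length(imgs)
  contrasts <- array(0i, c(P, H, W))
  y <- array(0i, c(P, cfg$n_coils, H, W))
  for (p in seq_len(P)) {
    contrasts[p, , ] <- imgs[[p]] + 0i
    for (ci in seq_len(cfg$n_coils))
      y[p, ci, , ] <- ft2c(S[ci, , ] * imgs[[p]])
  }

  if (cfg$noise_fraction > 0) {
    sdv <- cfg$noise_fraction * max(Mod(y))
    n <- length(y)
    y <- with_seed(cfg$seed, {
      y + array(complex(real = rnorm(n, 0, sdv), imaginary = rnorm(n, 0, sdv)),
                dim(y))
    })
  }

  structure(list(kspace = multi_contrast_kspace(y, seq = seq, scale = 1),
                 maps = maps, sens = sens, contrasts = contrasts,
                 seq = seq, cfg = cfg, phantom = phantom),
            class = "qmri_case")
}

#' @export
print.qmri_case <- function(x, ...) {
  d <- dim(x$kspace$data)
  cat("<qmri_case> ", x$seq$kind, ": ", d[1], " contrasts x ", d[2], " coils x ",
      d[3], "x", d[4], " k-space\n", sep = "")
  invisible(x)
}
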