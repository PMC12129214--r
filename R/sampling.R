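# Retrospective Cartesian undersampling and self-supervision k-space splits.
#
# The undersampled region Omega is generated retrospectively (whole
# phase-encode lines or individual points, with a fully sampled central
# autocalibration region). Self-supervised training splits Omega into a
# network-input subset Theta and a held-out loss subset Lambda (60/40 by
# default); the zero-shot variant first holds out a validation subset Gamma
# (20%), leaving Xi = Omega \ Gamma to be split into Theta/Lambda. All splits
# are disjoint unions; autocalibration points stay in the network input and
# are never assigned to loss or validation sets.

#' Undersampling mask specification
#'
#' @param pattern `"random_lines"` (whole phase-encode rows) or
#'   `"random_points"`.
#' @param af target acceleration factor (>= 1).
#' @param acs fully sampled center region: number of central lines for
#'   `random_lines`, central block edge length for `random_points`.
#' @param seed integer seed.
#' @return object of class `mask_spec`.
#' @export
mask_spec <- function(pattern = c("random_lines", "random_points"),
                      af = 4, acs = 4L, seed = 1L) {
  pattern <- match.arg(pattern)
  if (af < 1) stop_invalid("acceleration factor must be >= 1")
  if (acs < 0) stop_invalid("acs must be non-negative")
  structure(list(pattern = pattern, af = af, acs = as.integer(acs),
                 seed = as.integer(seed)),
            class = "mask_spec")
}

center_range <- function(n, width) {
  if (width <= 0) return(integer(0))
  lo <- floor(n / 2) - floor(width / 2) + 1
  seq(lo, lo + width - 1)
}

#' Generate a retrospective undersampling mask
#'
#' The autocalibration region is always fully sampled; the remaining budget is
#' drawn uniformly at random. For `random_lines` the budget is
#' `round(rows / af)` whole lines; for `random_points` it is
#' `round(rows * cols / af)` individual points. Deterministic per seed.
#'
#' @param rows,cols grid size.
#' @param spec a `mask_spec`.
#' @return logical rows x cols mask.
#' @export
gen_mask <- function(rows, cols, spec) {
  if (spec$af == 1) return(matrix(TRUE, rows, cols))
  m <- matrix(FALSE, rows, cols)
  if (spec$pattern == "random_lines") {
    n_lines <- round(rows / spec$af)
    acs_rows <- center_range(rows, spec$acs)
    if (length(acs_rows) > n_lines)
      stop_invalid("ACS region alone exceeds the sampling budget at this AF")
    pool <- setdiff(seq_len(rows), acs_rows)
    extra <- with_seed(spec$seed, sample(pool, n_lines - length(acs_rows)))
    m[c(acs_rows, extra), ] <- TRUE
  } else {
    total <- round(rows * cols / spec$af)
    ar <- center_range(rows, spec$acs); ac <- center_range(cols, spec$acs)
    acs_idx <- as.vector(outer(ar, (ac - 1) * rows, "+"))
    if (length(acs_idx) > total)
      stop_invalid("ACS region alone exceeds the sampling budget at this AF")
    pool <- setdiff(seq_len(rows * cols), acs_idx)
    extra <- with_seed(spec$seed, sample(pool, total - length(acs_idx)))
    m[c(acs_idx, extra)] <- TRUE
  }
  m
}

#' Generate per-contrast undersampling masks
#'
#' @param n_contrasts number of contrasts P.
#' @inheritParams gen_mask
#' @param independent draw an independent mask per contrast (seeded
#'   `spec$seed + p - 1`); otherwise reuse one mask for all contrasts.
#' @return logical P x rows x cols array.
#' @export
gen_masks <- function(n_contrasts, rows, cols, spec, independent = TRUE) {
  out <- array(FALSE, c(n_contrasts, rows, cols))
  for (p in seq_len(n_contrasts)) {
    sp <- spec
    if (independent) sp$seed <- spec$seed + p - 1L
    out[p, , ] <- gen_mask(rows, cols, sp)
  }
  out
}

# ACS mask implied by a mask_spec, same shape as the sampling mask
acs_mask <- function(rows, cols, spec) {
  m <- matrix(FALSE, rows, cols)
  if (spec$acs <= 0) return(m)
  if (spec$pattern == "random_lines") m[center_range(rows, spec$acs), ] <- TRUE
  else m[center_range(rows, spec$acs), center_range(cols, spec$acs)] <- TRUE
  m
}

select_subset <- function(eligible_idx, n_pick, selection, dims) {
  if (selection == "uniform") return(sample(eligible_idx, n_pick))
  # Gaussian-weighted selection concentrated around the k-space center
  H <- dims[1]; W <- dims[2]
  ri <- (eligible_idx - 1) %% H + 1
  ci <- (eligible_idx - 1) %/% H + 1
  d2 <- ((ri - (H + 1) / 2) / (H / 6))^2 + ((ci - (W + 1) / 2) / (W / 6))^2
  sample(eligible_idx, n_pick, prob = exp(-d2 / 2))
}

split_mask <- function(omega2, frac, seed, acs2, selection) {
  eligible <- which(omega2 & !acs2)
  if (length(eligible) == 0) stop_invalid("no eligible points to split")
  n_pick <- round(frac * length(eligible))
  picked <- with_seed(seed, select_subset(eligible, n_pick, selection, dim(omega2)))
  sub <- matrix(FALSE, nrow(omega2), ncol(omega2))
  sub[picked] <- TRUE
  sub
}

#' Split an undersampling mask for self-supervised training
#'
#' Assigns `round(loss_fraction * |Omega \ ACS|)` points to the loss subset
#' Lambda (uniformly by default; Gaussian-weighted around the k-space center
#' optionally) and the rest, including the ACS, to the network-input subset
#' Theta. Theta and Lambda form a disjoint cover of Omega.
#'
#' @param omega logical H x W mask or P x H x W array.
#' @param loss_fraction fraction of eligible points assigned to Lambda
#'   (default 0.4, the 60/40 split).
#' @param seed integer seed (per-contrast seeds are offset by the contrast
#'   index for array input).
#' @param acs optional logical mask (same 2D shape) of autocalibration points
#'   kept in Theta; `NULL` means no ACS exemption.
#' @param selection `"uniform"` or `"gaussian"` point selection for Lambda.
#' @return list with logical `theta` and `lam` of the same shape as `omega`.
#' @export
partition_ssdu <- function(omega, loss_fraction = 0.4, seed = 1L, acs = NULL,
                           selection = c("uniform", "gaussian")) {
  selection <- match.arg(selection)
  if (loss_fraction <= 0 || loss_fraction >= 1)
    stop_invalid("loss_fraction must lie in (0, 1)")
  if (is.matrix(omega)) {
    if (!any(omega)) stop_invalid("omega is empty")
    acs2 <- if (is.null(acs)) matrix(FALSE, nrow(omega), ncol(omega)) else acs
    lam <- split_mask(omega, loss_fraction, seed, acs2, selection)
    return(list(theta = omega & !lam, lam = lam))
  }
  P <- dim(omega)[1]
  theta <- lam <- array(FALSE, dim(omega))
  for (p in seq_len(P)) {
    sp <- partition_ssdu(omega[p, , ], loss_fraction, seed + p - 1L, acs, selection)
    theta[p, , ] <- sp$theta; lam[p, , ] <- sp$lam
  }
  list(theta = theta, lam = lam)
}

#' Nested k-space partition for zero-shot self-supervised training
#'
#' First holds out a validation subset Gamma (`validation_fraction` of the
#' eligible points of Omega), leaving Xi = Omega \ Gamma; then splits Xi into
#' Theta/Lambda via [partition_ssdu()]. With the default 20% and 40% ratios,
#' Theta retains 48% of Omega.
#'
#' @inheritParams partition_ssdu
#' @param validation_fraction fraction of eligible points assigned to Gamma.
#' @return object of class `sampling_partition` with logical `omega`, `theta`,
#'   `lam`, `xi`, `gamma`, plus `ratios` and `seed`.
#' @export
partition_zsssl <- function(omega, validation_fraction = 0.2,
                            loss_fraction = 0.4, seed = 1L, acs = NULL,
                            selection = c("uniform", "gaussian")) {
  selection <- match.arg(selection)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_invalid("validation_fraction must lie in (0, 1)")
  was2d <- is.matrix(omega)
  if (was2d) omega <- array(omega, c(1, nrow(omega), ncol(omega)))
  P <- dim(omega)[1]
  xi <- gam <- theta <- lam <- array(FALSE, dim(omega))
  for (p in seq_len(P)) {
    om2 <- omega[p, , ]
    if (!any(om2)) stop_invalid("omega is empty")
    acs2 <- if (is.null(acs)) matrix(FALSE, nrow(om2), ncol(om2)) else acs
    g <- split_mask(om2, validation_fraction, seed + 1000L + p - 1L, acs2, selection)
    x2 <- om2 & !g
    sp <- partition_ssdu(x2, loss_fraction, seed + p - 1L, acs2, selection)
    gam[p, , ] <- g; xi[p, , ] <- x2
    theta[p, , ] <- sp$theta; lam[p, , ] <- sp$lam
  }
  drop2 <- function(a) if (was2d) a[1, , ] else a
  structure(list(omega = drop2(omega), theta = drop2(theta), lam = drop2(lam),
                 xi = drop2(xi), gamma = drop2(gam),
                 ratios = c(loss_fraction = loss_fraction,
                            validation_fraction = validation_fraction),
                 seed = as.integer(seed)),
            class = "sampling_partition")
}

#' Effective acceleration factor of a k-space subset
#'
#' The acceleration experienced by the network input after self-supervision
#' splits: `nominal_af / retained_fraction`, truncated to one decimal (the
#' conventional way these factors are reported). For example a nominal AF of 4
#' with 60% of points retained gives 6.6, and with 48% retained gives 8.3.
#'
#' @param nominal_af nominal acceleration factor of Omega.
#' @param retained_fraction fraction of Omega retained in the input subset.
#' @return effective AF, truncated to one decimal.
#' @export
effective_af <- function(nominal_af, retained_fraction) {
  if (retained_fraction <= 0 || retained_fraction > 1)
    stop_invalid("retained_fraction must lie in (0, 1]")
  floor(nominal_af / retained_fraction * 10 + 1e-9) / 10
}
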