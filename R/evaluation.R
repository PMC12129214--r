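# Quantitative evaluation of reconstructed maps and contrast images.
#
# NRMSE on parameter maps is computed over an evaluation region Phi that
# combines a region-of-interest variant (whole image, T2 <= 120 ms,
# T1 <= 1000 ms, or an external mask) with exclusion rules: predicted
# T1 > 5000 ms or T2 > 500 ms, ground-truth first-contrast intensity below 5%
# of its maximum, and fit-validity masks. SSIM on magnitude contrast images
# uses a single-scale Gaussian-window implementation (11 x 11, sigma 1.5,
# K1 = 0.01, K2 = 0.03, data range = max of the reference).

#' Region-of-interest specification for map evaluation
#'
#' @param mode `"whole"`, `"t2_le_120"`, `"t1_le_1000"` or `"external_mask"`.
#' @param external logical grid, required iff `mode = "external_mask"`.
#' @param strict use strict inequalities for the T1/T2 region thresholds.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(mode = c("whole", "t2_le_120", "t1_le_1000", "external_mask"),
                        external = NULL, strict = FALSE) {
  mode <- match.arg(mode)
  if (mode == "external_mask" && is.null(external))
    stop_invalid("external mask required for mode external_mask")
  if (mode != "external_mask" && !is.null(external))
    stop_invalid("external mask only allowed for mode external_mask")
  structure(list(mode = mode, external = external, strict = strict),
            class = "region_spec")
}

#' Build the evaluation region Phi
#'
#' Conjunction of the region-of-interest (from the ground-truth maps), the
#' outlier exclusions on the *predicted* maps (T1 <= 5000 ms where a T1 map is
#' evaluated, T2 <= 500 ms where a T2 map is evaluated), the low-intensity
#' exclusion (ground-truth first-contrast magnitude >= 5% of its maximum) and
#' both validity masks.
#'
#' @param gt_maps,pred_maps `parameter_maps` (components may be NULL).
#' @param gt_contrasts ground-truth contrast stack (complex P x H x W or a
#'   list of grids); the first contrast sets the intensity exclusion.
#' @param region a `region_spec`.
#' @param t1_exclude,t2_exclude,intensity_frac exclusion thresholds
#'   (ms, ms, fraction of max).
#' @return logical H x W region grid Phi.
#' @export
evaluation_region <- function(gt_maps, pred_maps, gt_contrasts,
                              region = region_spec("whole"),
                              t1_exclude = 5000, t2_exclude = 500,
                              intensity_frac = 0.05) {
  first_contrast <- if (is.list(gt_contrasts)) gt_contrasts[[1]]
                    else matrix(gt_contrasts[1, , ], dim(gt_contrasts)[2], dim(gt_contrasts)[3])
  mag <- Mod(first_contrast)
  H <- nrow(mag); W <- ncol(mag)
  cmp <- if (region$strict) `<` else `<=`

  phi <- switch(region$mode,
    whole = matrix(TRUE, H, W),
    t2_le_120 = cmp(gt_maps$T2, 120),
    t1_le_1000 = cmp(gt_maps$T1, 1000),
    external_mask = {
      if (!all(dim(region$external) == c(H, W)))
        stop_invalid("external region shape mismatch")
      region$external
    })
  if (!all(dim(phi) == c(H, W))) stop_invalid("region/contrast shape mismatch")

  if (!is.null(pred_maps$T1)) phi <- phi & !is.na(pred_maps$T1) & pred_maps$T1 <= t1_exclude
  if (!is.null(pred_maps$T2)) phi <- phi & !is.na(pred_maps$T2) & pred_maps$T2 <= t2_exclude
  phi <- phi & (mag >= intensity_frac * max(mag))
  phi & gt_maps$validity & pred_maps$validity
}

#' Normalized root-mean-square error over a region
#'
#' `||(pred - gt) 1_Phi||_2 / ||gt 1_Phi||_2` (Euclidean-norm normalization).
#'
#' @param pred,gt numeric grids of equal shape.
#' @param phi logical region grid; must select at least one pixel and a
#'   nonzero reference.
#' @return non-negative scalar.
#' @export
nrmse <- function(pred, gt, phi = NULL) {
  if (!all(dim(pred) == dim(gt))) stop_invalid("pred/gt shape mismatch")
  if (is.null(phi)) phi <- !is.na(gt) & !is.na(pred)
  if (!any(phi)) stop_invalid("evaluation region is empty")
  g <- gt[phi]; p <- pred[phi]
  den <- sqrt(sum(g^2))
  if (den == 0) stop_invalid("reference is zero over the evaluation region")
  sqrt(sum((p - g)^2)) / den
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 'valid' 2D correlation with an odd square kernel
filter_valid <- function(img, kern) {
  k <- nrow(kern); h <- (k - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H - 2 * h, W - 2 * h)
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    w <- kern[dy, dx]
    if (w == 0) next
    out <- out + w * img[seq(dy, dy + H - 2 * h - 1), seq(dx, dx + W - 2 * h - 1)]
  }
  out
}

#' Structural similarity between magnitude images
#'
#' Single-scale SSIM with a Gaussian window, averaged over the valid interior
#' (pixels whose window fits inside the image). The data range defaults to
#' the maximum of the reference.
#'
#' @param pred,ref non-negative magnitude images of equal shape (at least as
#'   large as the window).
#' @param win_size odd window edge length (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 stabilization constants (defaults 0.01, 0.03).
#' @param data_range dynamic range; default `max(ref)`.
#' @return mean SSIM, at most 1 (1 iff the images are identical).
#' @export
ssim <- function(pred, ref, win_size = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, data_range = max(ref)) {
  pred <- as.matrix(pred); ref <- as.matrix(ref)
  if (!all(dim(pred) == dim(ref))) stop_invalid("pred/ref shape mismatch")
  if (any(dim(ref) < win_size)) stop_invalid("image smaller than the SSIM window")
  kern <- gaussian_kernel(win_size, sigma)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mu_x <- filter_valid(pred, kern); mu_y <- filter_valid(ref, kern)
  sxx <- filter_valid(pred^2, kern) - mu_x^2
  syy <- filter_valid(ref^2, kern) - mu_y^2
  sxy <- filter_valid(pred * ref, kern) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Evaluate one reconstructed case
#'
#' Computes per-contrast SSIM between reconstructed and ground-truth magnitude
#' images and per-map NRMSE for every requested region variant.
#'
#' @param recon_contrasts,gt_contrasts complex contrast stacks P x H x W.
#' @param pred_maps,gt_maps `parameter_maps`.
#' @param regions named list of `region_spec`s (default: whole image).
#' @return object of class `metrics_report` with data.frames `ssim`
#'   (contrast, value) and `nrmse` (map, region, value).
#' @export
evaluate_case <- function(recon_contrasts, gt_contrasts, pred_maps, gt_maps,
                          regions = list(whole = region_spec("whole"))) {
  P <- dim(gt_contrasts)[1]
  ssim_df <- data.frame(contrast = seq_len(P), value = vapply(seq_len(P), function(p)
    ssim(Mod(recon_contrasts[p, , ]), Mod(gt_contrasts[p, , ])), numeric(1)))

  rows <- list()
  for (rn in names(regions)) {
    phi <- evaluation_region(gt_maps, pred_maps, gt_contrasts, regions[[rn]])
    for (mp in c("PD", "T1", "T2")) {
      if (is.null(gt_maps[[mp]]) || is.null(pred_maps[[mp]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        map = mp, region = rn, value = nrmse(pred_maps[[mp]], gt_maps[[mp]], phi))
    }
  }
  structure(list(ssim = ssim_df, nrmse = do.call(rbind, rows)),
            class = "metrics_report")
}

#' Aggregate metric reports across cases
#'
#' @param reports list of `metrics_report`s.
#' @return list of data.frames (`ssim`, `nrmse`) with mean and sd columns.
#' @export
aggregate_reports <- function(reports) {
  sv <- sapply(reports, function(r) r$ssim$value)
  sv <- matrix(sv, nrow = nrow(reports[[1]]$ssim))
  nv <- sapply(reports, function(r) r$nrmse$value)
  nv <- matrix(nv, nrow = nrow(reports[[1]]$nrmse))
  list(
    ssim = data.frame(contrast = reports[[1]]$ssim$contrast,
                      mean = rowMeans(sv), sd = apply(sv, 1, sd)),
    nrmse = data.frame(map = reports[[1]]$nrmse$map,
                       region = reports[[1]]$nrmse$region,
                       mean = rowMeans(nv), sd = apply(nv, 1, sd))
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n  SSIM per contrast:\n")
  print(x$ssim, row.names = FALSE)
  cat("  NRMSE per map/region:\n")
  print(x$nrmse, row.names = FALSE)
  invisible(x)
}
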