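# Case container I/O.
#
# A case is stored as a directory of NIfTI volumes plus a JSON metadata
# sidecar (`meta.json`): complex groups are split into `_real`/`_imag`
# volumes, masks are stored as 0/1 volumes, and the metadata records the
# sequence parameters, seeds, acceleration factor and normalization scale so
# the case can be reconstructed exactly.

case_groups <- list(
  kspace = "complex4", sens = "complex3", contrasts_gt = "complex3",
  recon_contrasts = "complex3",
  maps_pd = "real", maps_t1 = "real", maps_t2 = "real", maps_validity = "mask",
  maps_pred_pd = "real", maps_pred_t1 = "real", maps_pred_t2 = "real",
  maps_pred_validity = "mask",
  mask_omega = "mask", mask_theta = "mask", mask_lambda = "mask",
  mask_xi = "mask", mask_gamma = "mask"
)

nii_path <- function(dir, name) file.path(dir, paste0(name, ".nii"))

write_group <- function(dir, name, value) {
  kind <- case_groups[[name]]
  if (is.null(kind)) stop_invalid("unknown container group: ", name)
  if (kind %in% c("complex3", "complex4")) {
    RNifti::writeNifti(RNifti::asNifti(Re(value)), nii_path(dir, paste0(name, "_real")),
                       datatype = "double")
    RNifti::writeNifti(RNifti::asNifti(Im(value)), nii_path(dir, paste0(name, "_imag")),
                       datatype = "double")
  } else if (kind == "mask") {
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(value), dim(value))),
                       nii_path(dir, name), datatype = "uint8")
  } else {
    RNifti::writeNifti(RNifti::asNifti(value), nii_path(dir, name), datatype = "double")
  }
}

read_group <- function(dir, name) {
  kind <- case_groups[[name]]
  if (is.null(kind)) stop_invalid("unknown container group: ", name)
  if (kind %in% c("complex3", "complex4")) {
    pr <- nii_path(dir, paste0(name, "_real"))
    if (!file.exists(pr)) return(NULL)
    re <- as.array(RNifti::readNifti(pr))
    im <- as.array(RNifti::readNifti(nii_path(dir, paste0(name, "_imag"))))
    array(complex(real = re, imaginary = im), dim(re))
  } else {
    p <- nii_path(dir, name)
    if (!file.exists(p)) return(NULL)
    a <- as.array(RNifti::readNifti(p))
    if (kind == "mask") array(a != 0, dim(a)) else array(as.numeric(a), dim(a))
  }
}

seq_to_meta <- function(seq) {
  unclass(seq)
}

meta_to_seq <- function(m) {
  sequence_params(m$kind, TE_list = unlist(m$TE_list), TR = m$TR,
                  flip_angles = unlist(m$flip_angles),
                  assumed_T1 = m$assumed_T1, diffusivity_D = m$diffusivity_D,
                  spoiler_amplitude_G = m$spoiler_amplitude_G,
                  spoiler_duration_tau = m$spoiler_duration_tau, gamma = m$gamma)
}

#' Write a case container
#'
#' @param case a `qmri_case` (see [synthesize_case()]).
#' @param dir target directory (created if missing).
#' @param partition optional masks to store: a list or `sampling_partition`
#'   with any of `omega`, `theta`, `lam`, `xi`, `gamma` (logical P x H x W).
#' @param af optional nominal acceleration factor recorded in the metadata.
#' @return the directory path, invisibly.
#' @export
write_case <- function(case, dir, partition = NULL, af = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_group(dir, "kspace", kspace_data(case$kspace))
  write_group(dir, "sens", sens_maps(case$sens))
  write_group(dir, "contrasts_gt", case$contrasts)
  if (!is.null(case$maps$PD)) write_group(dir, "maps_pd", case$maps$PD)
  if (!is.null(case$maps$T1)) write_group(dir, "maps_t1", case$maps$T1)
  if (!is.null(case$maps$T2)) write_group(dir, "maps_t2", case$maps$T2)
  write_group(dir, "maps_validity", case$maps$validity)
  if (!is.null(partition)) {
    pn <- list(omega = "mask_omega", theta = "mask_theta", lam = "mask_lambda",
               xi = "mask_xi", gamma = "mask_gamma")
    for (nm in names(pn))
      if (!is.null(partition[[nm]])) write_group(dir, pn[[nm]], partition[[nm]])
  }
  meta <- list(seq = seq_to_meta(case$seq),
               sim = unclass(case$cfg),
               af = af,
               scale = case$kspace$scale,
               shape = dim(kspace_data(case$kspace)),
               package_version = as.character(utils::packageVersion("qmapnet")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a case container
#'
#' @param dir case directory written by [write_case()] or the CLI stages.
#' @return list with the available groups (`kspace`, `sens`, `contrasts_gt`,
#'   `maps`, `partition`, `recon_contrasts`, `maps_pred`, `seq`, `meta`).
#' @export
read_case <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop_data("not a case container (missing meta.json): ", dir)
  meta <- jsonlite::read_json(mp)
  seq <- meta_to_seq(meta$seq)
  part <- list(omega = read_group(dir, "mask_omega"),
               theta = read_group(dir, "mask_theta"),
               lam = read_group(dir, "mask_lambda"),
               xi = read_group(dir, "mask_xi"),
               gamma = read_group(dir, "mask_gamma"))
  part <- part[!vapply(part, is.null, logical(1))]
  val <- read_group(dir, "maps_validity")
  maps <- if (!is.null(val))
    parameter_maps(PD = read_group(dir, "maps_pd"), T1 = read_group(dir, "maps_t1"),
                   T2 = read_group(dir, "maps_t2"), validity = val)
  else NULL
  pval <- read_group(dir, "maps_pred_validity")
  maps_pred <- if (!is.null(pval))
    parameter_maps(PD = read_group(dir, "maps_pred_pd"),
                   T1 = read_group(dir, "maps_pred_t1"),
                   T2 = read_group(dir, "maps_pred_t2"), validity = pval)
  else NULL
  ksp <- read_group(dir, "kspace")
  structure(list(
    kspace = if (!is.null(ksp))
      multi_contrast_kspace(ksp, seq = seq,
                            scale = if (is.null(meta$scale)) 1 else meta$scale)
      else NULL,
    sens = read_group(dir, "sens"),
    contrasts = read_group(dir, "contrasts_gt"),
    recon_contrasts = read_group(dir, "recon_contrasts"),
    maps = maps, maps_pred = maps_pred,
    partition = if (length(part)) part else NULL,
    seq = seq, meta = meta, dir = dir
  ), class = "qmri_case")
}

#' Export a container group as NIfTI
#'
#' Writes maps or magnitude contrast images with pixel-size metadata; complex
#' groups are refused unless `magnitude = TRUE`. Re-importing the file
#' reproduces the exported values exactly (double precision).
#'
#' @param dir case directory.
#' @param group one of the stored group names (e.g. `"maps_t2"`,
#'   `"contrasts_gt"`).
#' @param file output path (`.nii`).
#' @param magnitude export the magnitude of a complex group.
#' @param pixel_size pixel edge length in mm written to the header.
#' @return `file`, invisibly.
#' @export
export_nifti <- function(dir, group, file, magnitude = FALSE, pixel_size = 1) {
  v <- read_group(dir, group)
  if (is.null(v)) stop_data("group not present in container: ", group)
  if (is.complex(v)) {
    if (!magnitude) stop_invalid("complex group; pass magnitude = TRUE to export |.|")
    v <- Mod(v)
  }
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- rep(pixel_size, length(dim(v)))
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}

#' Save / load a trained checkpoint
#'
#' Weights go to `<prefix>.rds`; a JSON sidecar `<prefix>.json` records the
#' unroll configuration, training configuration and history for traceability.
#'
#' @param params trained `denoiser_params`.
#' @param net_cfg an `unroll_config`.
#' @param cfg a `train_config`.
#' @param history a `train_history` (optional).
#' @param prefix path prefix without extension.
#' @return `prefix`, invisibly.
#' @export
save_checkpoint <- function(params, net_cfg, cfg, history = NULL, prefix) {
  saveRDS(params, paste0(prefix, ".rds"))
  jsonlite::write_json(list(unroll = unclass(net_cfg), train = unclass(cfg),
                            history = if (!is.null(history)) unclass(history),
                            package_version = as.character(utils::packageVersion("qmapnet"))),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(prefix)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(prefix) {
  if (!file.exists(paste0(prefix, ".rds"))) stop_data("checkpoint not found: ", prefix)
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  net_cfg <- unroll_config(n_unrolls = meta$unroll$n_unrolls,
                           cg_iters = meta$unroll$cg_iters,
                           lambda = meta$unroll$lambda,
                           cg_tol = meta$unroll$cg_tol,
                           share_weights = isTRUE(meta$unroll$share_weights))
  list(params = readRDS(paste0(prefix, ".rds")), net_cfg = net_cfg, meta = meta)
}
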