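# YAML run configuration.
#
# One document drives the whole pipeline (simulate -> mask -> partition ->
# train -> reconstruct -> fit -> evaluate). The schema is validated before
# any stage runs: every section and required key must be present and unknown
# keys are rejected.

config_schema <- list(
  sequence = list(required = c("kind"), optional = c("n_echoes")),
  sim = list(required = c("rows", "cols", "n_coils", "n_train", "n_val", "n_test",
                          "base_seed"),
             optional = c("noise_fraction", "fov", "n_lesions")),
  mask = list(required = c("pattern", "af"), optional = c("acs", "seed", "independent")),
  net = list(required = c("n_unrolls", "cg_iters", "lambda"),
             optional = c("n_filters", "n_blocks", "alpha_scale")),
  train = list(required = c("strategy", "epochs"),
               optional = c("learning_rate", "batch_size", "accumulation_steps",
                            "patience", "seed")),
  output = list(required = c("dir"), optional = character(0))
)

config_defaults <- list(
  sim = list(noise_fraction = 1e-4, fov = 256, n_lesions = 3L),
  mask = list(acs = 4L, seed = 1L, independent = TRUE),
  net = list(n_filters = 64L, n_blocks = 10L, alpha_scale = 0.1),
  train = list(learning_rate = NULL, batch_size = 2L, accumulation_steps = 1L,
               patience = 25L, seed = 1L)
)

#' Validate a run configuration
#'
#' Checks the section/key schema (required keys present, unknown keys
#' rejected), fills in defaults, and sanity-checks a few values. Raises a
#' condition of class `qmapnet_config_error` on failure.
#'
#' @param cfg named list, typically from [read_run_config()].
#' @return the validated configuration with defaults merged.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_config("configuration must be a mapping")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) stop_config("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config_schema)) {
    if (is.null(cfg[[sec]])) stop_config("missing config section: ", sec)
    sch <- config_schema[[sec]]
    miss <- setdiff(sch$required, names(cfg[[sec]]))
    if (length(miss)) stop_config("section '", sec, "' missing key(s): ",
                                  paste(miss, collapse = ", "))
    unk <- setdiff(names(cfg[[sec]]), c(sch$required, sch$optional))
    if (length(unk)) stop_config("section '", sec, "' has unknown key(s): ",
                                 paste(unk, collapse = ", "))
    if (!is.null(config_defaults[[sec]]))
      cfg[[sec]] <- modifyList(config_defaults[[sec]], cfg[[sec]])
  }
  if (!cfg$sequence$kind %in% c("MSME", "VFA_SPGR", "QDESS"))
    stop_config("unknown sequence kind: ", cfg$sequence$kind)
  if (!cfg$mask$pattern %in% c("random_lines", "random_points"))
    stop_config("unknown mask pattern: ", cfg$mask$pattern)
  if (!cfg$train$strategy %in% c("SL", "SSL", "ZSSSL"))
    stop_config("unknown training strategy: ", cfg$train$strategy)
  if (cfg$mask$af < 1) stop_config("mask.af must be >= 1")
  cfg
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' A complete default run configuration
#'
#' A small, self-contained template (MSME sequence, 10/2/2 case split) that
#' passes validation as-is; useful as a starting point and in tests.
#'
#' @param dir output directory recorded in the config.
#' @return configuration list.
#' @export
default_run_config <- function(dir = "qmapnet_out") {
  validate_run_config(list(
    sequence = list(kind = "MSME", n_echoes = 16L),
    sim = list(rows = 64L, cols = 64L, n_coils = 6L, n_train = 10L, n_val = 2L,
               n_test = 2L, base_seed = 100L),
    mask = list(pattern = "random_lines", af = 4, acs = 4L, seed = 1L,
                independent = TRUE),
    net = list(n_unrolls = 10L, cg_iters = 10L, lambda = 0.05,
               n_filters = 64L, n_blocks = 10L, alpha_scale = 0.1),
    train = list(strategy = "SSL", epochs = 100L),
    output = list(dir = dir)
  ))
}

config_sequence <- function(cfg) {
  switch(cfg$sequence$kind,
    MSME = msme_protocol(if (is.null(cfg$sequence$n_echoes)) 16L else cfg$sequence$n_echoes),
    VFA_SPGR = vfa_protocol(),
    QDESS = qdess_protocol())
}
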