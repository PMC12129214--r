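# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("qmapnet_invalid_argument", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("qmapnet_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("qmapnet_config_error", "error")))
}

# real part of the standard complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) Re(sum(Conj(a) * b))

cnorm <- function(a) sqrt(Re(sum(Conj(a) * a)))

# Coerce masks to a logical P x H x W array, broadcasting a single H x W mask.
as_mask3 <- function(masks, P, H, W) {
  if (is.matrix(masks)) {
    m <- array(FALSE, c(P, H, W))
    for (p in seq_len(P)) m[p, , ] <- masks
    return(m)
  }
  d <- dim(masks)
  if (length(d) != 3L || d[1] != P || d[2] != H || d[3] != W)
    stop_invalid("mask array must be ", P, " x ", H, " x ", W)
  masks
}
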