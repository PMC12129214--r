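# Parametric tissue phantoms.
#
# A brain-like nested-ellipse geometry stands in for a voxelized digital brain:
# an outer CSF ring, a gray-matter ribbon, a white-matter interior and optional
# randomized elliptical lesions. Each label carries its own proton density (PD,
# arbitrary units), T1 and T2 (ms). The defaults are chosen so that WM and GM
# fall inside both threshold regions used in evaluation (T1 <= 1000 ms and
# T2 <= 120 ms) while CSF violates both.

#' Default tissue table for the nested-ellipse phantom
#'
#' Per-label proton density (arbitrary units) and relaxation times (ms). These
#' are package defaults for a plausible brain-like phantom, not literature
#' values; WM and GM satisfy T1 <= 1000 ms and T2 <= 120 ms, CSF and lesions
#' violate both.
#'
#' @return data.frame with columns `label`, `name`, `PD`, `T1`, `T2`.
#' @export
default_tissue_table <- function() {
  data.frame(
    label = 0:4,
    name  = c("background", "WM", "GM", "CSF", "lesion"),
    PD    = c(0.00, 0.70, 0.85, 1.00, 0.90),
    T1    = c(4500,  800,  950, 4000, 1400),
    T2    = c(2000,   70,  100, 1800,  250),
    stringsAsFactors = FALSE
  )
}

validate_tissue_table <- function(tt) {
  need <- c("background", "WM", "GM", "CSF")
  if (!all(need %in% tt$name))
    stop_invalid("tissue_table must contain labels: ", paste(need, collapse = ", "))
  if (any(tt$PD < 0)) stop_invalid("PD must be non-negative")
  if (any(tt$T1 <= 0) || any(tt$T2 <= 0)) stop_invalid("T1 and T2 must be positive")
  if (tt$PD[tt$name == "background"] != 0)
    stop_invalid("background label must have PD = 0")
  tt
}

in_ellipse <- function(X, Y, cx, cy, a, b, phi = 0) {
  xr <- (X - cx) * cos(phi) + (Y - cy) * sin(phi)
  yr <- -(X - cx) * sin(phi) + (Y - cy) * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a brain-like nested-ellipse tissue phantom
#'
#' Builds a label map with an outer CSF ellipse, a GM ribbon, a WM interior and
#' (optionally) randomized elliptical lesions inside the WM. The outer anatomy
#' is deterministic; only lesion placement depends on `seed`, so two seeds give
#' identical anatomy with different lesions.
#'
#' @param rows,cols grid size in pixels (>= 8).
#' @param seed integer seed controlling lesion placement.
#' @param tissue_table per-label PD/T1/T2 table, see [default_tissue_table()].
#' @param n_lesions number of lesion ellipses (0 disables; requires a `lesion`
#'   row in `tissue_table` when positive).
#' @param pixel_size pixel edge length in mm.
#' @return object of class `tissue_phantom`: `label_map` (integer rows x cols),
#'   `tissue_table`, `pixel_size`.
#' @export
make_tissue_phantom <- function(rows, cols, seed = 1L,
                                tissue_table = default_tissue_table(),
                                n_lesions = 3L, pixel_size = 1) {
  if (rows < 8 || cols < 8) stop_invalid("rows and cols must be >= 8")
  tt <- validate_tissue_table(tissue_table)

  # normalized coordinates in [-1, 1] x [-1, 1]
  y <- seq(-1, 1, length.out = rows)
  x <- seq(-1, 1, length.out = cols)
  X <- matrix(rep(x, each = rows), rows, cols)
  Y <- matrix(rep(y, times = cols), rows, cols)

  lab <- function(nm) tt$label[tt$name == nm]
  map <- matrix(lab("background"), rows, cols)
  map[in_ellipse(X, Y, 0, 0, 0.92, 0.78)] <- lab("CSF")
  map[in_ellipse(X, Y, 0, 0, 0.80, 0.66)] <- lab("GM")
  map[in_ellipse(X, Y, 0, 0, 0.62, 0.50)] <- lab("WM")

  if (n_lesions > 0) {
    if (!"lesion" %in% tt$name)
      stop_invalid("tissue_table needs a 'lesion' row when n_lesions > 0")
    with_seed(seed, {
      for (i in seq_len(n_lesions)) {
        # lesion centers drawn inside the WM ellipse
        repeat {
          cx <- runif(1, -0.45, 0.45); cy <- runif(1, -0.35, 0.35)
          if ((cx / 0.62)^2 + (cy / 0.50)^2 <= 0.6) break
        }
        a <- runif(1, 0.04, 0.10); b <- runif(1, 0.04, 0.10)
        phi <- runif(1, 0, pi)
        sel <- in_ellipse(X, Y, cx, cy, a, b, phi) & map == lab("WM")
        map[sel] <- lab("lesion")
      }
    })
  }

  structure(
    list(label_map = map, tissue_table = tt, pixel_size = pixel_size, seed = seed),
    class = "tissue_phantom"
  )
}

#' Look up per-pixel PD/T1/T2 maps for a phantom
#'
#' @param phantom a `tissue_phantom`.
#' @return object of class `parameter_maps` with `PD`, `T1`, `T2` grids and a
#'   `validity` grid (all `TRUE` for ground truth).
#' @export
phantom_maps <- function(phantom) {
  tt <- phantom$tissue_table
  idx <- match(phantom$label_map, tt$label)
  dims <- dim(phantom$label_map)
  parameter_maps(
    PD = matrix(tt$PD[idx], dims[1], dims[2]),
    T1 = matrix(tt$T1[idx], dims[1], dims[2]),
    T2 = matrix(tt$T2[idx], dims[1], dims[2]),
    validity = matrix(TRUE, dims[1], dims[2])
  )
}

#' Construct a parameter-map container
#'
#' @param PD,T1,T2 numeric grids (any may be NULL if the sequence does not
#'   estimate it); units: PD arbitrary, T1/T2 ms.
#' @param validity logical grid marking pixels where the fit succeeded.
#' @return object of class `parameter_maps`.
#' @export
parameter_maps <- function(PD = NULL, T1 = NULL, T2 = NULL, validity) {
  for (m in list(PD, T1, T2)) {
    if (!is.null(m) && !all(dim(m) == dim(validity)))
      stop_invalid("map and validity grids must share dimensions")
  }
  structure(list(PD = PD, T1 = T1, T2 = T2, validity = validity),
            class = "parameter_maps")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", nrow(x$label_map), "x", ncol(x$label_map),
      " pixels, ", length(unique(as.vector(x$label_map))), " labels present\n", sep = "")
  invisible(x)
}
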