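#' Source locations of the somatosensory network nodes
#'
#' Group-level activation maxima (MNI mm) used as fixed source-location
#' fixtures for the three network nodes, with their group t-values.
#'
#' @return Data frame with columns `node`, `mni_x`, `mni_y`, `mni_z`,
#'   `t_value`.
#' @export
source_locations <- function() {
  path <- system.file("extdata", "source_locations.csv", package = "dcmerp")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Quasi-uniform scalp sensor layout
#'
#' Places `n` sensors on the upper part of a unit sphere with a Fibonacci
#' lattice (a stand-in for a helmet layout; 102 matches a whole-scalp
#' magnetometer map, 306 a full triple-sensor array).
#'
#' @param n Number of sensors.
#' @return Object of class `sensor_layout`: `positions` (`[n x 3]` unit
#'   vectors) and `channel_ids`.
#' @export
sensor_layout <- function(n = 102) {
  stopifnot(n >= 8)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  # z from 1 (vertex) down to -0.3: helmet covers more than a hemisphere
  z <- 1 - 1.3 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  structure(list(positions = pos,
                 channel_ids = sprintf("MEG%03d", seq_len(n))),
            class = "sensor_layout")
}

#' Synthetic gain (lead-field) matrix
#'
#' Maps the three sources to sensors with smooth topographies: for each node
#' a spatial pattern `exp(-d^2 / (2 w^2))` over the layout sphere, where `d`
#' is the great-circle distance from the sensor nearest the node's MNI
#' direction.  A small seeded multiplicative channel jitter emulates
#' per-sensor gain variation; the matrix is reproducible given the seed.
#'
#' @param layout A [sensor_layout()].
#' @param locations Data frame as from [source_locations()].
#' @param width Pattern width `w`, radians of great-circle distance.
#' @param scale Overall gain, fT per arbitrary source unit.
#' @param jitter_sd SD of the multiplicative channel jitter.
#' @param seed Integer seed for the jitter.
#' @return Object of class `gain_matrix`: `values` (`[channels x nodes]`),
#'   `channel_ids`.
#' @export
synthetic_gain <- function(layout = sensor_layout(),
                           locations = source_locations(),
                           width = 0.5, scale = 100, jitter_sd = 0.05,
                           seed = 1L) {
  pos <- layout$positions
  n_ch <- nrow(pos)
  vals <- matrix(0, n_ch, nrow(locations))
  colnames(vals) <- locations$node
  for (k in seq_len(nrow(locations))) {
    dir <- as.numeric(locations[k, c("mni_x", "mni_y", "mni_z")])
    dir <- dir / sqrt(sum(dir^2))
    cosang <- pmin(1, pmax(-1, pos %*% dir))
    centre <- pos[which.max(cosang), ]
    d <- acos(pmin(1, pmax(-1, pos %*% centre)))
    vals[, k] <- scale * exp(-d^2 / (2 * width^2))
  }
  jit <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    j <- 1 + stats::rnorm(n_ch, 0, jitter_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    j
  })
  vals <- vals * jit
  if (any(colSums(abs(vals)) == 0)) stop("gain matrix has a zero column")
  structure(list(values = vals, channel_ids = layout$channel_ids),
            class = "gain_matrix")
}

#' Project source activity to sensors
#'
#' Linear observation stage `y = G s`.
#'
#' @param src A `source_timeseries` (or a `[nodes x samples]` matrix).
#' @param gain A `gain_matrix` (or a `[channels x nodes]` matrix).
#' @return `[channels x samples]` sensor matrix.
#' @export
project_to_sensors <- function(src, gain) {
  s <- if (inherits(src, "source_timeseries")) src$values else src
  g <- if (inherits(gain, "gain_matrix")) gain$values else gain
  if (ncol(g) != nrow(s))
    stop(sprintf("dimension mismatch: gain has %d columns, sources have %d rows",
                 ncol(g), nrow(s)))
  g %*% s
}

#' Leading spatial modes of sensor data
#'
#' The `n_modes` leading left singular vectors of the `[channels x samples]`
#' data matrix, ordered by decreasing singular value; columns orthonormal.
#' Seven modes reduce whole-scalp data to the subspace used for inversion.
#'
#' @param data `[channels x samples]` matrix.
#' @param n_modes Number of modes; must not exceed `min(dim(data))`.
#' @return Object of class `spatial_modes`: `basis` (`[channels x n_modes]`),
#'   `n_modes`, `singular_values` and `var_explained` (fraction of total
#'   variance captured).
#' @export
compute_modes <- function(data, n_modes = 7) {
  stopifnot(is.matrix(data))
  if (n_modes > min(dim(data)))
    stop("n_modes exceeds min(channels, samples)")
  sv <- svd(data, nu = n_modes, nv = 0)
  structure(list(basis = sv$u, n_modes = n_modes,
                 singular_values = sv$d,
                 var_explained = sum(sv$d[seq_len(n_modes)]^2) / sum(sv$d^2)),
            class = "spatial_modes")
}
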