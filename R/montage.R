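#' Standard 10-10 montage with approximate spherical positions
#'
#' Returns a 64-channel EEG montage in the extended 10-20 ("10-10") naming
#' scheme, together with approximate unit-sphere head coordinates. Positions
#' are derived from the conventional angular layout: the anterior-posterior
#' row (Fp, AF, F, FC, C, CP, P, PO, O) advances in 18-degree steps from the
#' vertex, and the lateral index (z, 1/2, 3/4, 5/6, 7/8, 9/10) in 18-degree
#' steps towards the ears. Coordinates are only used for smooth topography
#' weights in the simulator, not for source modelling.
#'
#' @param channels optional character vector of labels to subset (order kept).
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   x = right, y = anterior, z = up).
#' @export
montage_1010 <- function(channels = NULL) {
  labels <- c(
    "Fp1", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  pos <- t(vapply(labels, channel_position, numeric(3)))
  out <- data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(channels)) {
    miss <- setdiff(channels, out$label)
    if (length(miss))
      stop("unknown channel label(s): ", paste(miss, collapse = ", "))
    out <- out[match(channels, out$label), , drop = FALSE]
    row.names(out) <- NULL
  }
  out
}

# Parse a 10-10 label into (anterior angle, lateral angle) in degrees and
# return a unit-sphere position. T/FT/TP chains map onto the C/FC/CP rows.
channel_position <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("cannot parse channel label: ", label)
  row <- m[2]
  idx <- m[3]
  row_map <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, C = 0, T = 0,
               TP = -18, CP = -18, P = -36, PO = -54, O = -72)
  key <- switch(row, T = "T", FT = "FT", TP = "TP", row)
  if (!key %in% names(row_map)) stop("unknown 10-10 row in label: ", label)
  ant <- row_map[[key]]
  if (idx == "z") {
    lat <- 0
  } else {
    n <- as.integer(idx)
    # odd = left hemisphere; lateral index advances in 18-degree steps,
    # temporal chains (T7/T8, FT9/TP10, ...) sit on the outer arcs
    lat <- ceiling(n / 2) * 18 * if (n %% 2 == 1) -1 else 1
  }
  theta <- sqrt(ant^2 + lat^2) * pi / 180
  if (theta == 0) return(c(0, 0, 1))
  dir_ant <- ant / sqrt(ant^2 + lat^2)
  dir_lat <- lat / sqrt(ant^2 + lat^2)
  c(sin(theta) * dir_lat, sin(theta) * dir_ant, cos(theta))
}

#' Angular scalp distance between channels
#'
#' Great-circle angle (radians) between two montage positions.
#'
#' @param montage data.frame as returned by [montage_1010()].
#' @param from,to channel labels; `from` may be a vector.
#' @return numeric vector of angles in radians.
#' @export
channel_angle <- function(montage, from, to) {
  p <- as.matrix(montage[match(from, montage$label), c("x", "y", "z")])
  q <- as.numeric(montage[match(to, montage$label), c("x", "y", "z")])
  if (anyNA(p) || anyNA(q)) stop("channel not present in montage")
  d <- pmin(pmax(p %*% q, -1), 1)
  acos(as.numeric(d))
}

# Cosine-falloff topography weight, peaked at `peak`, floored at zero.
topography_weights <- function(montage, peak) {
  ang <- channel_angle(montage, montage$label, peak)
  pmax(cos(ang), 0)
}
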