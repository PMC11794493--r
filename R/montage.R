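#' Standard 64-channel extended 10-20 montage
#'
#' An idealized spherical layout of the 64-channel extended 10-20 montage
#' used by the simulator, the bad-channel interpolation and the region
#' summaries. Electrode positions are placed on a unit sphere with an
#' azimuthal-equidistant parameterization of the 10-10 grid: the
#' front-to-back row letter sets the sagittal angle and the electrode number
#' the lateral angle (odd = left, even = right), which reproduces the
#' familiar relative geometry (Cz at the vertex, T7/T8 on the 10% ring,
#' TP9/TP10 below the ears). Exact manufacturer coordinates are not needed:
#' positions only drive distance weighting and region grouping.
#'
#' Regions follow the row-letter convention: Fp/AF = prefrontal, F = frontal,
#' FC/C = central, FT/T/TP = temporal, CP/P = parietal, PO/O = occipital.
#'
#' @param n number of leading channels to return (default all 64).
#' @return data.frame with columns \code{label}, \code{x}, \code{y}, \code{z}
#'   (unit sphere; +x right, +y anterior, +z superior) and \code{region}.
#' @export
#' @examples
#' head(standardMontage())
standardMontage <- function(n = 64L) {
  labels <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8"
  )
  stopifnot(n >= 1L, n <= length(labels))
  rowAngle <- c(Fp = 81, AF = 63, F = 45, FT = 27, FC = 27, C = 0,
                TP = -27, CP = -27, T = 0, P = -45, PO = -63, O = -81)
  parse1 <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)(z|[0-9]+)$", lab))[[1]]
    row <- m[2]; col <- m[3]
    u <- rowAngle[[row]] / 90
    if (col == "z") v <- 0
    else {
      num <- as.integer(col)
      side <- if (num %% 2 == 1) -1 else 1
      v <- side * (ceiling(num / 2) * 0.25)
      if (row %in% c("Fp", "O") ) v <- v * 0.6   # narrow rows near poles
    }
    # azimuthal-equidistant inverse projection from the vertex
    theta <- pi / 2 * sqrt(u^2 + v^2)            # inclination from Cz
    phi <- atan2(v, u)                            # 0 = toward nasion
    c(x = sin(theta) * sin(phi), y = sin(theta) * cos(phi), z = cos(theta))
  }
  xyz <- t(vapply(labels, parse1, numeric(3)))
  region <- vapply(labels, function(lab) {
    row <- regmatches(lab, regexec("^([A-Za-z]+)", lab))[[1]][2]
    switch(row,
      Fp = "prefrontal", AF = "prefrontal",
      F = "frontal",
      FC = "central", C = "central",
      FT = "temporal", T = "temporal", TP = "temporal",
      CP = "parietal", P = "parietal",
      PO = "occipital", O = "occipital",
      "other")
  }, character(1))
  out <- data.frame(label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    region = region, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[seq_len(n), , drop = FALSE]
}

#' Electrode region map
#'
#' Named list mapping region name to electrode labels, restricted to the
#' channels present in \code{labels}.
#'
#' @param labels channel labels to keep (default: full montage).
#' @return named list of character vectors.
#' @export
electrodeRegions <- function(labels = standardMontage()$label) {
  mon <- standardMontage()
  mon <- mon[mon$label %in% labels, ]
  split(mon$label, mon$region)
}

# Frontal blink-sensitivity weights: exponential fall-off with great-circle
# distance from the mid-point of Fp1/Fp2. Used by the simulator to spread the
# stereotyped blink template over anterior channels.
blinkWeights <- function(labels) {
  mon <- standardMontage()
  mon <- mon[match(labels, mon$label), ]
  fp <- standardMontage()
  fp <- fp[fp$label %in% c("Fp1", "Fp2"), c("x", "y", "z")]
  ref <- colMeans(fp)
  ref <- ref / sqrt(sum(ref^2))
  d <- acos(pmin(1, pmax(-1, as.matrix(mon[, c("x", "y", "z")]) %*% ref)))
  w <- exp(-(d / 0.55)^2)
  w[is.na(w)] <- 0
  as.numeric(w)
}
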