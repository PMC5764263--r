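## Spherical-head montage geometry. Positions are idealized 10-20 locations
## on a sphere (x = right, y = anterior, z = superior, mm); they feed the
## synthetic Gaussian-spread lead field and neighbor interpolation, not an
## anatomical forward model.

montage_table <- function() {
  # inc: inclination from the vertex (deg); azi: azimuth from the nasion,
  # clockwise toward the right ear (deg, left negative).
  rbind(
    data.frame(label = c("Fp1", "Fp2"), inc = 90, azi = c(-18, 18)),
    data.frame(label = c("F7", "F8"),   inc = 90, azi = c(-54, 54)),
    data.frame(label = c("F3", "F4"),   inc = 55, azi = c(-42, 42)),
    data.frame(label = "Fz",            inc = 45, azi = 0),
    data.frame(label = c("FC5", "FC6"), inc = 68, azi = c(-68, 68)),
    data.frame(label = c("FC1", "FC2"), inc = 28, azi = c(-45, 45)),
    data.frame(label = c("T7", "T8"),   inc = 90, azi = c(-90, 90)),
    data.frame(label = c("C3", "C4"),   inc = 45, azi = c(-90, 90)),
    data.frame(label = "Cz",            inc = 0,  azi = 0),
    data.frame(label = c("TP9", "TP10"), inc = 112, azi = c(-100, 100)),
    data.frame(label = c("CP5", "CP6"), inc = 68, azi = c(-112, 112)),
    data.frame(label = c("CP1", "CP2"), inc = 28, azi = c(-135, 135)),
    data.frame(label = c("P7", "P8"),   inc = 90, azi = c(-126, 126)),
    data.frame(label = c("P3", "P4"),   inc = 55, azi = c(-138, 138)),
    data.frame(label = "Pz",            inc = 45, azi = 180),
    data.frame(label = c("PO9", "PO10"), inc = 112, azi = c(-140, 140)),
    data.frame(label = c("O1", "O2"),   inc = 90, azi = c(-162, 162)),
    data.frame(label = "Oz",            inc = 90, azi = 180))
}

#' 32-channel 10-20 montage on a spherical head
#'
#' @param radius_mm Head sphere radius in millimetres.
#' @return Object of class `"eeg_montage"`: `labels` (32 names including
#'   C3/C4) and `positions` (32 x 3 matrix, mm).
#' @export
montage_1020_32 <- function(radius_mm = 87.5) {
  tab <- montage_table()
  inc <- tab$inc * pi / 180
  azi <- tab$azi * pi / 180
  pos <- radius_mm * cbind(x = sin(inc) * sin(azi),
                           y = sin(inc) * cos(azi),
                           z = cos(inc))
  rownames(pos) <- tab$label
  structure(list(labels = tab$label, positions = pos, radius_mm = radius_mm),
            class = "eeg_montage")
}

#' Default left-hemisphere ROI geometry
#'
#' Literature-style coordinates for left PMC (dorsal), SMA, M1 (hand area)
#' and DLPFC on the same head coordinate system as [montage_1020_32()]
#' (x = right, y = anterior, z = superior, mm). The source publication for
#' this pipeline cites prior task-fMRI coordinates without printing them,
#' so these defaults are configuration, not data: override `centers` freely.
#'
#' @param centers Optional named 4 x 3 matrix replacing the defaults.
#' @param radius_mm ROI sphere radius used by source extraction.
#' @return Object of class `"roi_set"` with `labels`, `centers`, `radius_mm`.
#' @export
default_roiset <- function(centers = NULL, radius_mm = 20) {
  if (is.null(centers)) {
    centers <- rbind(PMC   = c(-28,  -2, 56),
                     SMA   = c( -4,  -8, 60),
                     M1    = c(-37, -21, 58),
                     DLPFC = c(-38,  30, 32))
  }
  centers <- as.matrix(centers)
  if (!identical(rownames(centers), roi_nodes()) || ncol(centers) != 3L)
    stop_config("centers must be a 4x3 matrix with rows PMC, SMA, M1, DLPFC")
  colnames(centers) <- c("x", "y", "z")
  structure(list(labels = roi_nodes(), centers = centers,
                 radius_mm = radius_mm), class = "roi_set")
}
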