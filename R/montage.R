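# Idealized 10-20 electrode positions on a unit sphere, used only for
# distance weighting when a bad channel is rebuilt from its neighbours.
# Angles: inclination from the vertex (Cz = 0), azimuth from the nasion
# midline, positive to the right.

montage_angles <- data.frame(
  label = c("Cz", "Fz", "Pz", "C3", "C4",
            "Fpz", "Oz", "T7", "T8",
            "Fp1", "Fp2", "F7", "F8", "P7", "P8", "O1", "O2",
            "F3", "F4", "P3", "P4"),
  incl = c(0, 45, 45, 45, 45,
           90, 90, 90, 90,
           90, 90, 90, 90, 90, 90, 90, 90,
           60, 60, 60, 60),
  az = c(0, 0, 180, -90, 90,
         0, 180, -90, 90,
         -18, 18, -54, 54, -126, 126, -162, 162,
         -39, 39, -141, 141),
  stringsAsFactors = FALSE)

#' Idealized 10-20 electrode coordinates
#'
#' Cartesian unit-sphere positions for the standard 10-20 labels the package
#' knows about; used for inverse-distance weighting during bad-channel
#' interpolation.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
standard_1020_positions <- function() {
  a <- montage_angles
  incl <- a$incl * pi / 180
  az <- a$az * pi / 180
  data.frame(label = a$label,
             x = sin(incl) * sin(az),
             y = sin(incl) * cos(az),
             z = cos(incl),
             stringsAsFactors = FALSE)
}
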