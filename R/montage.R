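# Idealized 10-20 / 10-10 electrode positions on a unit sphere.
# Head-centred coordinates: x toward the right ear, y toward the nasion,
# z up. Constructed geometrically: midline and outer-ring electrodes at 18
# degree steps (10% of the 180 degree arcs), intermediate electrodes by
# spherical interpolation between the midline electrode of a row and the
# corresponding outer-ring electrode.

slerp <- function(a, b, t) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

build_electrode_table <- function() {
  pos <- list()
  # midline: angle from vertex toward nasion (positive = anterior)
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
           CPz = -18, Pz = -36, POz = -54, Oz = -72)
  for (lab in names(mid)) {
    a <- mid[[lab]] * pi / 180
    pos[[lab]] <- c(0, sin(a), cos(a))
  }
  # outer ring at 72 deg inclination; azimuth from anterior midline,
  # positive to the right
  ring <- c(Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
            FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
            P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162)
  for (lab in names(ring)) {
    phi <- ring[[lab]] * pi / 180
    s <- sin(72 * pi / 180)
    pos[[lab]] <- c(s * sin(phi), s * cos(phi), cos(72 * pi / 180))
  }
  # intermediate rows: slerp from the midline electrode to the ring electrode
  rows <- list(
    AF = list(midline = "AFz", left = "AF7", right = "AF8",
              lnum = c(AF3 = 0.5), rnum = c(AF4 = 0.5)),
    F  = list(midline = "Fz", left = "F7", right = "F8",
              lnum = c(F1 = 0.25, F3 = 0.5, F5 = 0.75),
              rnum = c(F2 = 0.25, F4 = 0.5, F6 = 0.75)),
    FC = list(midline = "FCz", left = "FT7", right = "FT8",
              lnum = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
              rnum = c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    C  = list(midline = "Cz", left = "T7", right = "T8",
              lnum = c(C1 = 0.25, C3 = 0.5, C5 = 0.75),
              rnum = c(C2 = 0.25, C4 = 0.5, C6 = 0.75)),
    CP = list(midline = "CPz", left = "TP7", right = "TP8",
              lnum = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
              rnum = c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    P  = list(midline = "Pz", left = "P7", right = "P8",
              lnum = c(P1 = 0.25, P3 = 0.5, P5 = 0.75),
              rnum = c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    PO = list(midline = "POz", left = "PO7", right = "PO8",
              lnum = c(PO3 = 0.5), rnum = c(PO4 = 0.5))
  )
  for (r in rows) {
    m <- pos[[r$midline]]
    for (side in c("l", "r")) {
      edge <- pos[[if (side == "l") r$left else r$right]]
      nums <- if (side == "l") r$lnum else r$rnum
      for (lab in names(nums)) pos[[lab]] <- slerp(m, edge, nums[[lab]])
    }
  }
  # earlobe references, slightly below the equator
  a1 <- 100 * pi / 180
  pos[["A1"]] <- c(-sin(a1), 0, cos(a1))
  pos[["A2"]] <- c(sin(a1), 0, cos(a1))
  tab <- do.call(rbind, pos)
  rownames(tab) <- names(pos)
  colnames(tab) <- c("x", "y", "z")
  tab
}

.electrode_table <- NULL

electrode_table <- function() {
  if (is.null(.electrode_table))
    utils::assignInMyNamespace(".electrode_table", build_electrode_table())
  .electrode_table
}

#' Look up built-in 10-20/10-10 electrode positions
#'
#' @param labels character vector of channel labels (case-insensitive;
#'   `T3/T4/T5/T6` accepted as aliases of `T7/T8/P7/P8`).
#' @return labels x 3 matrix of unit-sphere coordinates.
#' @export
lookup_electrode_positions <- function(labels) {
  tab <- electrode_table()
  alias <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  key <- toupper(labels)
  names_up <- toupper(rownames(tab))
  out <- matrix(NA_real_, length(labels), 3,
                dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) {
    k <- key[i]
    if (k %in% toupper(names(alias))) k <- toupper(alias[[k]])
    j <- match(k, names_up)
    if (is.na(j))
      stop("no built-in position for channel label '", labels[i], "'")
    out[i, ] <- tab[j, ]
  }
  out
}

#' Default 61-channel montage labels
#'
#' The 61-channel 10-10 montage used throughout the synthetic generator
#' (earlobe channels A1/A2 are not part of it).
#'
#' @return Character vector of 61 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}
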