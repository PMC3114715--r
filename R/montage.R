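## Electrode montage: 63 scalp channels of the extended 10-10 system plus the
## infraorbital EOG electrode, on a unit sphere. Coordinates are inclination
## from the vertex (theta, degrees) and azimuth from the nasion (phi, degrees;
## positive = right hemisphere, |phi| = 180 at the inion).

.sph2cart <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  cbind(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

.cart2sph <- function(xyz) {
  xyz <- xyz / sqrt(rowSums(xyz^2))
  theta <- acos(pmin(1, pmax(-1, xyz[, 3]))) * 180 / pi
  phi <- atan2(xyz[, 1], xyz[, 2]) * 180 / pi
  cbind(theta_deg = theta, phi_deg = phi)
}

## great-circle interpolation between two unit vectors
.slerp <- function(a, b, f) {
  om <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
}

## Layout construction. The nasion-inion midline arc spans 180 degrees in 10%
## steps of 18 degrees; the classical outer ring (Fp, AF7/8 ... O1/2) is the
## circle at 72 degrees inclination with electrodes every 18 degrees of
## azimuth; the 9/10-index electrodes sit one step further down, on the
## 90-degree circle at the azimuth of their 7/8 neighbours. Interior
## electrodes are placed by great-circle interpolation between the midline
## electrode of their row and the outer-ring electrode, at quarter fractions
## (index 1 -> 1/4, 3 -> 2/4, 5 -> 3/4, 7 -> ring).
.build1010 <- function() {
  ringAzL <- c(Fp1 = -18, AF7 = -36, F7 = -54, FT7 = -72, T7 = -90,
               TP7 = -108, P7 = -126, PO7 = -144, O1 = -162)
  midTheta <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
                CPz = 18, Pz = 36, POz = 54, Oz = 72, Iz = 90)
  midPhi <- c(Fpz = 0, AFz = 0, Fz = 0, FCz = 0, Cz = 0,
              CPz = 180, Pz = 180, POz = 180, Oz = 180, Iz = 180)
  pos <- list()
  add <- function(label, theta, phi) pos[[label]] <<- c(theta, phi)

  for (l in names(midTheta)) add(l, midTheta[[l]], midPhi[[l]])
  for (l in names(ringAzL)) {
    add(l, 72, ringAzL[[l]])
    r <- sub("1$", "2", sub("7$", "8", l))          # mirror label
    add(r, 72, -ringAzL[[l]])
  }
  ## 9/10 ring and inion neighbours
  low <- c(F9 = -54, FT9 = -72, T9 = -90, TP9 = -108, P9 = -126,
           PO9 = -144, I1 = -162)
  for (l in names(low)) {
    add(l, 90, low[[l]])
    r <- sub("1$", "2", sub("9$", "10", l))
    add(r, 90, -low[[l]])
  }
  ## interior rows
  rows <- list(AF = c("AFz", "AF7"), F = c("Fz", "F7"), FC = c("FCz", "FT7"),
               C = c("Cz", "T7"), CP = c("CPz", "TP7"), P = c("Pz", "P7"),
               PO = c("POz", "PO7"))
  for (row in names(rows)) {
    mid <- pos[[rows[[row]][1]]]
    ring <- pos[[rows[[row]][2]]]
    a <- .sph2cart(mid[1], mid[2])[1, ]
    b <- .sph2cart(ring[1], ring[2])[1, ]
    bR <- .sph2cart(ring[1], -ring[2])[1, ]
    for (idx in c(1, 3, 5)) {
      f <- (idx + 1) / 2 / 4
      sp <- .cart2sph(rbind(.slerp(a, b, f)))
      add(paste0(row, idx), sp[1, 1], sp[1, 2])
      sp <- .cart2sph(rbind(.slerp(a, bR, f)))
      add(paste0(row, idx + 1), sp[1, 1], sp[1, 2])
    }
  }
  add("EOGvu", 108, 18)   # below the right eye
  data.frame(label = names(pos),
             theta_deg = vapply(pos, `[`, 0, 1),
             phi_deg = vapply(pos, `[`, 0, 2),
             row.names = NULL)
}

#' Scalp channel labels used throughout the analysis
#'
#' The 63 scalp electrodes of the recording montage (extended 10-10 system).
#' The infraorbital electrode \code{EOGvu} is recorded alongside but is not a
#' scalp channel.
#'
#' @return character vector of 63 labels.
#' @export
scalpLabels <- function() {
  c("Fp2", "AF3", "AF4", "Fz", paste0("F", 1:10), "FCz", paste0("FC", 1:6),
    "T7", "T8", "Cz", paste0("C", 1:6), "TP7", "TP8", "CPz",
    paste0("CP", 1:6), "Pz", paste0("P", 1:10), "POz", "PO3", "PO4",
    paste0("PO", 7:10), "Oz", "O1", "O2", "Iz", "I1", "I2")
}

#' Posterior electrode subset used for classification
#'
#' @return the nine parieto-occipital/occipital labels entering the feature
#'   matrix.
#' @export
posteriorElectrodes <- function() {
  c("PO3", "PO4", "PO7", "PO8", "PO9", "PO10", "Oz", "O1", "O2")
}

#' Left/right hemisphere subsets of the posterior electrodes
#'
#' @return named list with elements \code{left}, \code{right}, \code{both}.
#' @export
hemisphereSubsets <- function() {
  list(left = c("PO3", "PO7", "PO9", "O1"),
       right = c("PO4", "PO8", "PO10", "O2"),
       both = posteriorElectrodes())
}

#' Default electrode montage
#'
#' Returns spherical unit-sphere coordinates for the 63 scalp channels of the
#' recording montage plus the infraorbital \code{EOGvu} electrode, computed
#' from the standard 10-10 construction (18-degree midline steps, outer ring
#' at 72 degrees inclination, 9/10-index electrodes at 90 degrees,
#' great-circle interpolation for interior electrodes).
#'
#' @return data.frame with columns \code{label}, \code{theta_deg} (inclination
#'   from the vertex) and \code{phi_deg} (azimuth from the nasion, positive
#'   right).
#' @examples
#' m <- defaultMontage()
#' subset(m, label %in% c("Cz", "Oz", "PO3"))
#' @export
defaultMontage <- function() {
  all <- .build1010()
  want <- c(scalpLabels(), "EOGvu")
  stopifnot(all(want %in% all$label))
  out <- all[match(want, all$label), ]
  rownames(out) <- NULL
  out
}

#' Cartesian unit-sphere positions for montage rows
#'
#' @param montage data.frame as returned by [defaultMontage()].
#' @return matrix with one unit-norm xyz row per electrode, rownames = labels.
#' @export
montagePositions <- function(montage) {
  xyz <- .sph2cart(montage$theta_deg, montage$phi_deg)
  rownames(xyz) <- montage$label
  xyz
}

#' Read / write a montage TSV
#'
#' Tab-separated file with columns \code{label}, \code{theta_deg},
#' \code{phi_deg}.
#'
#' @param path file path.
#' @return [readMontage()] returns the montage data.frame.
#' @export
readMontage <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "theta_deg", "phi_deg")
  if (!all(need %in% names(m)))
    stop("montage file must have columns label, theta_deg, phi_deg")
  m[, need]
}

#' @param montage montage data.frame to write.
#' @rdname readMontage
#' @export
writeMontage <- function(montage, path) {
  utils::write.table(montage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## assert that a montage covers the channels the simulator needs
.checkMontage <- function(montage, required) {
  missing <- setdiff(required, montage$label)
  if (length(missing))
    stop("montage is missing required channels: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
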