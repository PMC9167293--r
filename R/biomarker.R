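## The azimuth center-of-mass biomarker: elevation-integrated azimuth
## marginals, per-patient per-class centers of mass, benign-referenced
## relative shifts, and the sign-based phenotype call.
##
## For each patient, all pixels of a gland class are pooled across regions
## into one cumulative histogram before the center of mass is taken (pooling
## pixels, not averaging per-region centers). Stroma and inflammation are
## excluded from the gland classes by default.

#' Integrate a 2D angle histogram over elevation
#'
#' @param hist an \linkS4class{AngleHistogram2D}.
#' @return data.frame with columns \code{azimuth} (bin centers, radians) and
#'   \code{mass}; total mass is preserved exactly.
#' @export
azimuthMarginal <- function(hist) {
  stopifnot(is(hist, "AngleHistogram2D"))
  edges <- hist@azEdges
  data.frame(
    azimuth = (edges[-1] + edges[-length(edges)]) / 2,
    mass = rowSums(hist@counts))
}

#' Center of mass of an azimuth marginal
#'
#' CoM = sum(theta_j * w_j) / sum(w_j) over bin centers, computed linearly
#' (no circular wrap). If more than \code{seamFrac} of the mass lies within
#' \code{seamDeg} degrees of the +/-pi seam, a warning is issued because a
#' linear mean is then unreliable; \code{method = "circular"} is available
#' for that case (angle of the mean resultant vector).
#'
#' @param marginal data.frame from \code{\link{azimuthMarginal}}, or a
#'   numeric vector of masses with bin centers in \code{centers}.
#' @param centers bin centers, required when \code{marginal} is a vector.
#' @param method "linear" (default) or "circular".
#' @param seamFrac,seamDeg seam-warning parameters (defaults 0.01 and 5).
#' @return center of mass in radians.
#' @export
centerOfMass <- function(marginal, centers = NULL,
                         method = c("linear", "circular"),
                         seamFrac = 0.01, seamDeg = 5) {
  method <- match.arg(method)
  if (is.data.frame(marginal)) {
    w <- marginal$mass; th <- marginal$azimuth
  } else {
    w <- as.numeric(marginal); th <- centers
    if (is.null(th)) stop("centers are required for a bare mass vector")
  }
  tot <- sum(w)
  if (tot <= 0) stop("zero total mass")
  seam <- abs(abs(th) - pi) < seamDeg * pi / 180
  if (sum(w[seam]) / tot > seamFrac)
    warning(sprintf("%.1f%% of mass lies within %g deg of the +/-pi seam; linear CoM may wrap",
                    100 * sum(w[seam]) / tot, seamDeg))
  if (method == "circular")
    return(atan2(sum(w * sin(th)), sum(w * cos(th))))
  sum(w * th) / tot
}

## Mode of the marginal (bin center of the maximum), the secondary summary.
.marginalMode <- function(marginal) marginal$azimuth[which.max(marginal$mass)]

#' Per-patient, per-class azimuth centers of mass
#'
#' For each requested gland class, pools all labeled pixels of that class
#' across the supplied regions of each patient into one cumulative 2D
#' histogram, integrates over elevation, and records the azimuth center of
#' mass (and, as a secondary summary, the azimuth mode). Classes with zero
#' pixels are omitted with a warning.
#'
#' @param fields a \linkS4class{SphericalField} or list of them, one per
#'   region, computed from PC triplet (1, 2, 3) (the malignancy stain space).
#' @param annotations a \linkS4class{RegionAnnotation} or list congruent with
#'   \code{fields}.
#' @param classes gland classes to summarize (default benign, G3, G4, G5;
#'   stroma/inflammation/exclude are never pooled into gland histograms).
#' @param azBins,elBins histogram bins (defaults 360 x 180).
#' @param weight "count" (default) or "radius".
#' @param comMethod passed to \code{\link{centerOfMass}}.
#' @return data.frame: patient_id, gland_class, com_azimuth, mode_azimuth,
#'   n_pixels.
#' @export
perClassCoM <- function(fields, annotations,
                        classes = c("benign", "G3", "G4", "G5"),
                        azBins = 360L, elBins = 180L,
                        weight = c("count", "radius"),
                        comMethod = c("linear", "circular")) {
  weight <- match.arg(weight)
  comMethod <- match.arg(comMethod)
  if (is(fields, "SphericalField")) fields <- list(fields)
  if (is(annotations, "RegionAnnotation")) annotations <- list(annotations)
  if (length(fields) != length(annotations))
    stop("fields and annotations must pair one-to-one")
  classes <- setdiff(classes, c("stroma", "inflammation", "exclude"))
  for (f in fields)
    if (!identical(f@triplet, c(1L, 2L, 3L)))
      warning("biomarker fields are expected in PC triplet (1, 2, 3)")
  pids <- vapply(annotations, patientId, character(1))
  out <- list()
  for (pid in unique(pids)) {
    ridx <- which(pids == pid)
    for (cls in classes) {
      az <- el <- rad <- numeric(0)
      for (i in ridx) {
        ann <- annotations[[i]]; fld <- fields[[i]]
        if (!all(dim(regionLabels(ann)) == dim(fld@azimuth)))
          stop("annotation and field dimensions differ for patient ", pid)
        ct <- classTable(ann)
        labs <- ct$label[ct$class == cls]
        if (!length(labs)) next
        sel <- matrix(regionLabels(ann) %in% labs, nrow(fld@azimuth)) &
          fld@validMask & is.finite(fld@azimuth)
        az <- c(az, fld@azimuth[sel])
        el <- c(el, fld@elevation[sel])
        rad <- c(rad, fld@radius[sel])
      }
      if (!length(az)) {
        warning(sprintf("patient %s: no pixels for class %s; omitted", pid, cls))
        next
      }
      ## cumulative histogram of the pooled pixels, then the marginal
      ai <- .angleBin(az, -pi, pi, as.integer(azBins))
      w <- if (weight == "count") rep(1, length(az)) else rad
      mass <- numeric(azBins)
      agg <- rowsum(w, ai)
      mass[as.integer(rownames(agg))] <- agg[, 1]
      edges <- seq(-pi, pi, length.out = azBins + 1L)
      marg <- data.frame(azimuth = (edges[-1] + edges[-length(edges)]) / 2,
                         mass = mass)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, gland_class = cls,
        com_azimuth = centerOfMass(marg, method = comMethod),
        mode_azimuth = .marginalMode(marg),
        n_pixels = length(az))
    }
  }
  if (!length(out)) stop("no pixels found for any requested class")
  do.call(rbind, out)
}

#' Benign-referenced relative azimuthal shifts
#'
#' shift = com(class) - com(benign) within each patient; the benign shift is
#' exactly 0. Self-calibration against each patient's own benign glands
#' removes inter-patient variability that would otherwise obscure the
#' phenotype signal.
#'
#' @param records data.frame from \code{\link{perClassCoM}}; every patient
#'   must carry a benign record.
#' @return the records with a \code{relative_shift} column (radians).
#' @export
relativeShifts <- function(records) {
  stopifnot(all(c("patient_id", "gland_class", "com_azimuth") %in% names(records)))
  out <- records
  out$relative_shift <- NA_real_
  for (pid in unique(records$patient_id)) {
    rows <- records$patient_id == pid
    ben <- which(rows & records$gland_class == "benign")
    if (!length(ben))
      stop("patient ", pid, " has no benign reference record")
    ref <- records$com_azimuth[ben[1]]
    out$relative_shift[rows] <- records$com_azimuth[rows] - ref
    out$relative_shift[ben] <- 0
  }
  out
}

#' Sign-based aggressive-phenotype call for one patient
#'
#' The aggressive glandular phenotype expresses as a negative azimuth CoM
#' shift in every cancerous gland class; the non-aggressive phenotype as a
#' positive shift. With the default threshold of 0 this is a pure sign rule;
#' mixed signs (or shifts within the threshold band) are indeterminate.
#'
#' @param shifts data.frame for one patient with columns \code{gland_class}
#'   and \code{relative_shift} (see \code{\link{relativeShifts}}).
#' @param threshold non-negative dead band in radians (default 0).
#' @return "aggressive_phenotype", "non_aggressive_phenotype" or
#'   "indeterminate".
#' @export
classifyPhenotype <- function(shifts, threshold = 0) {
  stopifnot(all(c("gland_class", "relative_shift") %in% names(shifts)))
  if (length(unique(shifts$patient_id)) > 1)
    stop("classifyPhenotype expects records of a single patient")
  s <- shifts$relative_shift[shifts$gland_class != "benign"]
  if (!length(s)) stop("no cancerous-class shifts present")
  if (all(s < -threshold)) return("aggressive_phenotype")
  if (all(s > threshold)) return("non_aggressive_phenotype")
  "indeterminate"
}

#' Write the biomarker table as CSV
#'
#' Angles are reported in degrees at the I/O surface.
#'
#' @param shifts data.frame from \code{\link{relativeShifts}}.
#' @param path output CSV path.
#' @param threshold classification threshold (radians) passed to
#'   \code{\link{classifyPhenotype}}.
#' @return the written data.frame, invisibly.
#' @export
writeBiomarker <- function(shifts, path, threshold = 0) {
  out <- data.frame(
    patient_id = shifts$patient_id,
    gland_class = shifts$gland_class,
    n_pixels = shifts$n_pixels,
    com_azimuth_deg = shifts$com_azimuth * 180 / pi,
    relative_shift_deg = shifts$relative_shift * 180 / pi)
  out$phenotype_call <- NA_character_
  for (pid in unique(out$patient_id)) {
    rows <- shifts$patient_id == pid
    call <- tryCatch(classifyPhenotype(shifts[rows, , drop = FALSE], threshold),
                     error = function(e) NA_character_)
    out$phenotype_call[rows] <- call
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
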