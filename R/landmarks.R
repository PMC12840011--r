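#' Craniocaudal extent of a structure
#'
#' The z positions (mm) of the centers of the most caudal and most cranial
#' occupied slices. With the slab model every border sits on a slice
#' center, so on a 4 mm CT all extents are multiples of 4 mm apart.
#'
#' @param volume a non-empty [BinaryVolume-class].
#' @return numeric(2): `c(caudal, cranial)` in mm.
#' @export
craniocaudalExtent <- function(volume) {
    zOcc <- apply(volume@voxels, 3, any)
    if (!any(zOcc)) stop("craniocaudal extent undefined: empty volume")
    zc <- sliceZ(volume@grid)[zOcc]
    c(caudal = min(zc), cranial = max(zc))
}

#' Signed offset of a border from a landmark
#'
#' Expresses a border position in the clinical phrasing "x mm below/above
#' the landmark": with `sense = "below"` the offset is
#' `landmark_z - extent_z` (positive when the border lies caudal to the
#' landmark); with `sense = "above"` it is `extent_z - landmark_z`
#' (positive when the border lies cranial to the landmark).
#'
#' @param extentZ border z position, mm.
#' @param landmarkZ landmark z position, mm.
#' @param sense `"below"` or `"above"`.
#' @return signed offset, mm.
#' @examples
#' borderOffset(96, 100, "below")  # +4: border 4 mm below the landmark
#' borderOffset(32, 20, "above")   # +12: border 12 mm above the landmark
#' @export
borderOffset <- function(extentZ, landmarkZ, sense = c("below", "above")) {
    sense <- match.arg(sense)
    if (sense == "below") landmarkZ - extentZ else extentZ - landmarkZ
}

#' Axial width of a structure at a reference slice
#'
#' The occupied extent along one in-plane axis on the slice at `z`:
#' (max - min occupied voxel-center coordinate + one voxel size), reported
#' in cm. The outer-edge convention means a single occupied voxel has
#' width dx, not 0. An empty slice has width 0.
#'
#' @param volume a [BinaryVolume-class].
#' @param z slice position, mm (must match a grid slice within dz/2).
#' @param axis `"x"` (left-right, default) or `"y"` (antero-posterior).
#' @return width, cm.
#' @export
axialWidth <- function(volume, z, axis = c("x", "y")) {
    axis <- match.arg(axis)
    k <- sliceIndex(z, volume@grid, "width reference slice")
    sl <- volume@voxels[, , k, drop = FALSE]
    if (!any(sl)) return(0)
    ax <- if (axis == "x") 1L else 2L
    occ <- if (ax == 1L) apply(sl, 1, any) else apply(sl, 2, any)
    co <- axisCoords(volume@grid, ax)[occ]
    (max(co) - min(co) + volume@grid@spacing[ax]) / 10
}

#' Spread and mean of a cohort of scalar measurements
#'
#' @param values numeric vector (n >= 1), any single unit.
#' @return `c(spread = max - min, mean = arithmetic mean)`.
#' @examples
#' cohortSpread(c(0, -4, -8))  # spread 8
#' @export
cohortSpread <- function(values) {
    if (length(values) == 0L) stop("cohortSpread needs at least one value")
    c(spread = max(values) - min(values), mean = mean(values))
}

#' Landmark-referenced border and width report for a cohort
#'
#' For every observer who delineated the structure: the cranial and caudal
#' border z positions, their signed offsets to the cranial landmark
#' (sense "below") and caudal landmark (sense "above"), and the axial
#' width at each requested reference slice. Cohort rows give the spread
#' (max pairwise difference) and mean of each quantity.
#'
#' @param cohort an [ObserverCohort-class].
#' @param structure structure name, default `"PTV1"`.
#' @param landmarks named numeric vector of landmark z positions, mm (see
#'   [readLandmarks()]).
#' @param cranialLandmark,caudalLandmark names in `landmarks` used as the
#'   cranial and caudal references (either may be NA to skip).
#' @param widthZ numeric vector of reference slice z positions (mm) for
#'   width measurement; may be empty.
#' @param axis width axis, `"x"` or `"y"`.
#' @return list with `perObserver` (data.frame, one row per observer) and
#'   `cohort` (data.frame of spread/mean per measured quantity).
#' @export
borderReport <- function(cohort, structure = "PTV1", landmarks,
                         cranialLandmark = NA, caudalLandmark = NA,
                         widthZ = numeric(), axis = "x") {
    for (nm in c(cranialLandmark, caudalLandmark))
        if (!is.na(nm) && !nm %in% names(landmarks))
            stop("config error: unknown landmark '", nm, "'")
    obs <- observersWith(cohort, structure)
    if (length(obs) == 0L)
        stop("no observer has structure '", structure, "'")
    rows <- lapply(obs, function(o) {
        d <- getDelineation(cohort, o, structure)
        vol <- rasterize(d, cohort@grid)
        ext <- craniocaudalExtent(vol)
        row <- data.frame(observer = o, caudal_z_mm = ext[["caudal"]],
                          cranial_z_mm = ext[["cranial"]])
        if (!is.na(cranialLandmark))
            row$cranial_offset_mm <- borderOffset(
                ext[["cranial"]], landmarks[[cranialLandmark]], "below")
        if (!is.na(caudalLandmark))
            row$caudal_offset_mm <- borderOffset(
                ext[["caudal"]], landmarks[[caudalLandmark]], "above")
        for (i in seq_along(widthZ))
            row[[sprintf("width_cm_z%g", widthZ[i])]] <-
                axialWidth(vol, widthZ[i], axis)
        row
    })
    per <- do.call(rbind, rows)
    qcols <- setdiff(names(per), "observer")
    coh <- do.call(rbind, lapply(qcols, function(cn) {
        sp <- cohortSpread(per[[cn]])
        data.frame(quantity = cn, spread = sp[["spread"]], mean = sp[["mean"]])
    }))
    list(perObserver = per, cohort = coh)
}
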