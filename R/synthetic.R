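#' Geometric shape primitives for the synthetic cohort
#'
#' Base ("true") structure shapes from which observer delineations are
#' derived: sphere, ellipsoid, axis-aligned box and a z-axis tube
#' (cylinder). All dimensions in mm.
#'
#' @param center numeric(3) shape center (x, y, z), mm. For `tubeShape`
#'   only (x, y) are used.
#' @param r radius, mm.
#' @param semiAxes numeric(3) ellipsoid semi-axes (a, b, c), mm.
#' @param size numeric(3) full box edge lengths, mm.
#' @param zRange numeric(2) tube z extent (caudal, cranial), mm.
#' @return list of class `"iovShape"`.
#' @export
sphereShape <- function(center, r) {
    stopifnot(r > 0)
    structure(list(type = "sphere", center = as.numeric(center), r = r),
              class = "iovShape")
}

#' @rdname sphereShape
#' @export
ellipsoidShape <- function(center, semiAxes) {
    stopifnot(length(semiAxes) == 3L, all(semiAxes > 0))
    structure(list(type = "ellipsoid", center = as.numeric(center),
                   semiAxes = as.numeric(semiAxes)), class = "iovShape")
}

#' @rdname sphereShape
#' @export
boxShape <- function(center, size) {
    stopifnot(length(size) == 3L, all(size > 0))
    structure(list(type = "box", center = as.numeric(center),
                   half = as.numeric(size) / 2), class = "iovShape")
}

#' @rdname sphereShape
#' @export
tubeShape <- function(center, r, zRange) {
    stopifnot(r > 0, length(zRange) == 2L, zRange[2] >= zRange[1])
    structure(list(type = "tube", center = as.numeric(center)[1:2], r = r,
                   zRange = as.numeric(zRange)), class = "iovShape")
}

#' Closed-form volume of a shape
#'
#' The analytic oracle for [volumeCC()] convergence checks: sphere
#' 4/3 pi r^3, ellipsoid 4/3 pi abc, box product of edges, tube
#' pi r^2 length. Reported in cm^3.
#'
#' @param shape an `"iovShape"`.
#' @param delta optional isotropic dilation margin, mm.
#' @return volume, cm^3.
#' @examples
#' analyticVolume(sphereShape(c(0, 0, 0), 10))  # 4.18879
#' @export
analyticVolume <- function(shape, delta = 0) {
    v <- switch(shape$type,
        sphere = 4 / 3 * pi * (shape$r + delta)^3,
        ellipsoid = 4 / 3 * pi * prod(shape$semiAxes + delta),
        box = prod(2 * (shape$half + delta)),
        tube = pi * (shape$r + delta)^2 *
            (diff(shape$zRange) + 2 * delta),
        stop("unsupported shape type: ", shape$type))
    v / 1000
}

# physical bounding box (mm) of a shape dilated by delta
shapeBBox <- function(shape, delta = 0) {
    switch(shape$type,
        sphere = rbind(shape$center - shape$r - delta,
                       shape$center + shape$r + delta),
        ellipsoid = rbind(shape$center - shape$semiAxes - delta,
                          shape$center + shape$semiAxes + delta),
        box = rbind(shape$center - shape$half - delta,
                    shape$center + shape$half + delta),
        tube = rbind(c(shape$center - shape$r - delta,
                       shape$zRange[1] - delta),
                     c(shape$center + shape$r + delta,
                       shape$zRange[2] + delta)))
}

# caudal z extent of the undilated shape (truncation reference plane)
shapeCaudalZ <- function(shape) shapeBBox(shape, 0)[1, 3]

#' Specification of a synthetic multi-observer cohort
#'
#' Describes the study conditions a generated cohort emulates: the CT grid,
#' the true structure shapes, and a three-part observer error model —
#' a per-observer systematic margin (isotropic dilation
#' delta_i ~ Normal(marginMean, marginSD), clamped at minus half the
#' smallest shape radius), a smooth random boundary perturbation
#' (low-order angular harmonics of sd ~ boundaryNoiseSD), and a
#' craniocaudal truncation of designated structures (per-observer caudal
#' offsets, multiples of dz). Structures can additionally be omitted
#' entirely with probability `omissionProb`, mirroring observers who did
#' not contour every requested organ.
#'
#' @param seed RNG seed for [generateCohort()].
#' @param nObservers number of observers (>= 2).
#' @param grid the common [ImageGrid-class].
#' @param structures named list; each element is
#'   `list(shape = <iovShape>, omissionProb = 0, truncated = FALSE)`.
#' @param marginMean,marginSD systematic margin model, mm.
#' @param boundaryNoiseSD smooth boundary noise, mm.
#' @param caudalTruncation per-observer caudal offsets, mm (<= 0, multiples
#'   of dz, length nObservers); applied to structures flagged
#'   `truncated = TRUE`. 0 keeps the full extent; -20 cuts the caudal
#'   20 mm.
#' @param levels named list of `"iovShape"` boxes standing in for nodal
#'   levels.
#' @param landmarks named numeric vector of landmark z positions, mm.
#' @return list of class `"cohortSpec"`.
#' @seealso [defaultCohortSpec()] for the packaged study-scale conditions.
#' @export
cohortSpec <- function(seed = 1L, nObservers = 10L,
                       grid = imageGrid(spacing = c(1, 1, 4),
                                        size = c(512, 512, 80)),
                       structures, marginMean = 0, marginSD = 0,
                       boundaryNoiseSD = 0, caudalTruncation = NULL,
                       levels = list(), landmarks = numeric()) {
    if (nObservers < 2L) stop("nObservers must be >= 2")
    if (marginSD < 0 || boundaryNoiseSD < 0) stop("sd parameters must be >= 0")
    if (is.null(names(structures)) || anyDuplicated(names(structures)))
        stop("structures must be a uniquely named list")
    structures <- lapply(structures, function(s) {
        if (inherits(s, "iovShape")) s <- list(shape = s)
        s$omissionProb <- s$omissionProb %||% 0
        s$truncated <- isTRUE(s$truncated)
        if (s$omissionProb < 0 || s$omissionProb > 1)
            stop("omissionProb must lie in [0, 1]")
        s
    })
    if (is.null(caudalTruncation)) caudalTruncation <- rep(0, nObservers)
    if (length(caudalTruncation) != nObservers)
        stop("caudalTruncation must have one offset per observer")
    if (any(caudalTruncation > 0))
        stop("caudal truncation offsets must be <= 0")
    structure(list(seed = as.integer(seed), nObservers = as.integer(nObservers),
                   grid = grid, structures = structures,
                   marginMean = marginMean, marginSD = marginSD,
                   boundaryNoiseSD = boundaryNoiseSD,
                   caudalTruncation = caudalTruncation,
                   levels = levels, landmarks = landmarks),
              class = "cohortSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic multi-observer cohort
#'
#' Deterministic given `spec$seed`: observer i's delineation of each
#' structure is the true shape dilated by that observer's realized margin
#' delta_i, radially perturbed by a smooth per-(observer, structure)
#' angular harmonic field, and — for truncated structures — cut below the
#' observer's caudal truncation plane. Omitted structures are absent from
#' the cohort, never empty.
#'
#' @param spec a [cohortSpec()].
#' @param nVertices polygon vertices per contour ring.
#' @return list with `cohort` (an [ObserverCohort-class] of planar
#'   contours), `truth` (realized margins, truncations and omissions plus
#'   per-structure analytic volumes), `levels` (named list of
#'   [BinaryVolume-class] level masks) and `landmarks`.
#' @examples
#' sp <- cohortSpec(seed = 7, nObservers = 3,
#'     grid = imageGrid(spacing = c(2, 2, 4), size = c(40, 40, 16)),
#'     structures = list(organ = sphereShape(c(40, 40, 30), 12)))
#' g <- generateCohort(sp)
#' structureCount(g$cohort)
#' @export
generateCohort <- function(spec, nVertices = 72L) {
    stopifnot(inherits(spec, "cohortSpec"))
    grid <- spec$grid
    gmin <- grid@origin - grid@spacing / 2
    gmax <- grid@origin + (grid@size - 0.5) * grid@spacing
    set.seed(spec$seed)
    nObs <- spec$nObservers
    obsIds <- sprintf("obs%02d", seq_len(nObs))
    deltas <- stats::rnorm(nObs, spec$marginMean, spec$marginSD)

    sNames <- names(spec$structures)
    omitted <- matrix(FALSE, nObs, length(sNames),
                      dimnames = list(obsIds, sNames))
    realizedDelta <- matrix(NA_real_, nObs, length(sNames),
                            dimnames = list(obsIds, sNames))
    dels <- list()
    for (i in seq_len(nObs)) {
        for (k in seq_along(sNames)) {
            st <- spec$structures[[k]]
            omit <- stats::runif(1) < st$omissionProb
            noisePar <- drawNoiseParams(spec$boundaryNoiseSD)
            if (omit) { omitted[i, k] <- TRUE; next }
            minR <- minShapeRadius(st$shape)
            delta <- max(deltas[i], -minR / 2)
            realizedDelta[i, k] <- delta
            bb <- shapeBBox(st$shape, delta)
            if (any(bb[1, ] < gmin - 1e-9) || any(bb[2, ] > gmax + 1e-9))
                stop("spec error: structure '", sNames[k],
                     "' exceeds the grid after dilation by ",
                     signif(delta, 3), " mm")
            truncZ <- if (st$truncated)
                shapeCaudalZ(st$shape) - spec$caudalTruncation[i] else -Inf
            contours <- shapeContours(st$shape, delta, noisePar, grid,
                                      truncZ, nVertices)
            if (length(contours) == 0L) { omitted[i, k] <- TRUE; next }
            dels[[length(dels) + 1L]] <-
                structureDelineation(obsIds[i], sNames[k], contours)
        }
    }
    truth <- list(
        structures = lapply(stats::setNames(sNames, sNames), function(nm)
            list(shape = spec$structures[[nm]]$shape,
                 volume_cc = analyticVolume(spec$structures[[nm]]$shape))),
        observers = data.frame(observer = obsIds, margin_mm = deltas,
                               caudal_truncation_mm = spec$caudalTruncation),
        realizedDelta = realizedDelta, omitted = omitted)
    lvls <- lapply(spec$levels, function(sh) rasterize(
        structureDelineation("atlas", "level",
                             shapeContours(sh, 0, NULL, grid, -Inf, nVertices)),
        grid))
    list(cohort = observerCohort(grid, dels, observers = obsIds),
         truth = truth, levels = lvls, landmarks = spec$landmarks)
}

minShapeRadius <- function(shape) {
    switch(shape$type,
        sphere = shape$r,
        ellipsoid = min(shape$semiAxes),
        box = min(shape$half),
        tube = min(shape$r, diff(shape$zRange) / 2))
}

# Smooth angular boundary-noise field: three harmonics with random
# amplitude and phase, phases drifting slowly along z. Pointwise sd is
# approximately the configured value.
drawNoiseParams <- function(sd) {
    list(c = stats::rnorm(3, 0, sd * sqrt(2 / 3)),
         phi = stats::runif(3, 0, 2 * pi),
         psi = stats::rnorm(3, 0, 1))
}

noiseAt <- function(par, theta, u) {
    if (is.null(par) || all(par$c == 0)) return(rep(0, length(theta)))
    v <- 0
    for (m in 1:3)
        v <- v + par$c[m] * cos(m * theta + par$phi[m] + par$psi[m] * u)
    v
}

# Planar contours of a dilated, noise-perturbed shape on the grid slices,
# cut below truncZ. Boxes get the margin and truncation but no radial
# noise (they stand in for nodal levels and rectangular aids).
shapeContours <- function(shape, delta, noisePar, grid, truncZ = -Inf,
                          nVertices = 72L) {
    zc <- sliceZ(grid)
    bb <- shapeBBox(shape, delta)
    keep <- zc > bb[1, 3] - 1e-9 & zc < bb[2, 3] + 1e-9 & zc >= truncZ - 1e-9
    zs <- zc[keep]
    if (length(zs) == 0L) return(list())
    zmid <- mean(bb[, 3]); zspan <- max(diff(bb[, 3]), 1)
    theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
    out <- list()
    for (z in zs) {
        u <- (z - zmid) / zspan
        if (shape$type == "box") {
            hx <- shape$half[1] + delta; hy <- shape$half[2] + delta
            if (hx <= 0 || hy <= 0) next
            v <- cbind(shape$center[1] + c(-hx, hx, hx, -hx),
                       shape$center[2] + c(-hy, -hy, hy, hy))
            out[[length(out) + 1L]] <- planarContour(z, v)
            next
        }
        rho <- switch(shape$type,
            sphere = {
                R <- shape$r + delta
                s2 <- R^2 - (z - shape$center[3])^2
                if (s2 <= 0) next
                rep(sqrt(s2), nVertices)
            },
            tube = rep(shape$r + delta, nVertices),
            ellipsoid = {
                ax <- shape$semiAxes + delta
                s2 <- 1 - ((z - shape$center[3]) / ax[3])^2
                if (s2 <= 0) next
                ae <- ax[1] * sqrt(s2); be <- ax[2] * sqrt(s2)
                ae * be / sqrt((be * cos(theta))^2 + (ae * sin(theta))^2)
            })
        rho <- pmax(rho + noiseAt(noisePar, theta, u), 0.05)
        cx <- if (shape$type == "tube") shape$center[1] else shape$center[1]
        cy <- shape$center[2]
        v <- cbind(cx + rho * cos(theta), cy + rho * sin(theta))
        out[[length(out) + 1L]] <- planarContour(z, v)
    }
    out
}

#' Study-scale default cohort conditions
#'
#' The packaged stand-in for a ten-observer head-and-neck contouring study
#' on a 1 x 1 x 4 mm planning-CT grid (512 x 512 x 80 voxels): two target
#' volumes and sixteen organs at risk with paper-scale true volumes
#' (PTV1 ~ 850 cm^3 down to eye lenses ~ 0.27 cm^3), a 2 +/- 1 mm
#' systematic observer margin, 1.5 mm smooth boundary noise, caudal PTV1
#' truncation offsets spanning 20 mm, and omission probabilities that make
#' small midline organs (pituitary, optic chiasm, TMJs) likely to be
#' skipped by some observers. Six box-shaped nodal-level stand-ins abut
#' the PTV1 tube; two landmarks bracket its craniocaudal extent.
#'
#' @param seed RNG seed.
#' @param nObservers number of observers.
#' @return A [cohortSpec()].
#' @export
defaultCohortSpec <- function(seed = 1L, nObservers = 10L) {
    cx <- 255; cy <- 255          # in-plane grid center, mm
    ptv1 <- tubeShape(c(cx, cy), r = 50, zRange = c(40, 148))
    structures <- list(
        PTV1 = list(shape = ptv1, truncated = TRUE),
        PTV2 = sphereShape(c(cx, cy - 60, 120), 45),
        brainstem = tubeShape(c(cx, cy + 90), r = 9, zRange = c(180, 280)),
        pituitary = list(shape = sphereShape(c(cx, cy + 60, 288), 5.5),
                         omissionProb = 0.3),
        inner_ear_L = sphereShape(c(cx + 70, cy + 80, 272), 6.2),
        inner_ear_R = sphereShape(c(cx - 70, cy + 80, 272), 6.2),
        optic_chiasm = list(
            shape = ellipsoidShape(c(cx, cy + 45, 296), c(15, 7, 4)),
            omissionProb = 0.1),
        spinal_canal = tubeShape(c(cx, cy + 110), r = 7.3,
                                 zRange = c(60, 260)),
        optic_nerve_L = ellipsoidShape(c(cx + 30, cy + 30, 284), c(4, 4, 24)),
        optic_nerve_R = ellipsoidShape(c(cx - 30, cy + 30, 284), c(4, 4, 24)),
        eye_lens_L = sphereShape(c(cx + 30, cy - 20, 292), 4),
        eye_lens_R = sphereShape(c(cx - 30, cy - 20, 292), 4),
        TMJ_L = list(shape = sphereShape(c(cx + 85, cy + 40, 252), 7.8),
                     omissionProb = 0.2),
        TMJ_R = list(shape = sphereShape(c(cx - 85, cy + 40, 252), 7.8),
                     omissionProb = 0.2),
        parotid_L = ellipsoidShape(c(cx + 90, cy + 55, 210), c(15, 20, 16)),
        parotid_R = ellipsoidShape(c(cx - 90, cy + 55, 210), c(15, 20, 16)),
        submandibular_L = sphereShape(c(cx + 40, cy - 10, 180), 12.7),
        submandibular_R = sphereShape(c(cx - 40, cy - 10, 180), 12.7))
    # box levels hugging the PTV1 tube; the caudal ones dip below its
    # caudal border so truncation degrades their coverage
    levels <- list(
        IIa_left  = boxShape(c(cx + 30, cy, 120), c(30, 30, 24)),
        IIa_right = boxShape(c(cx - 30, cy, 120), c(30, 30, 24)),
        III_left  = boxShape(c(cx + 30, cy, 88), c(30, 30, 24)),
        III_right = boxShape(c(cx - 30, cy, 88), c(30, 30, 24)),
        IVb_left  = boxShape(c(cx + 30, cy, 44), c(30, 30, 24)),
        IVb_right = boxShape(c(cx - 30, cy, 44), c(30, 30, 24)))
    truncation <- rep_len(c(0, 0, 0, -4, -4, -8, -8, -16, -20, -20),
                          nObservers)
    landmarks <- c(sphenoid_sinus_floor = 152, sternoclavicular_joint = 36)
    cohortSpec(seed = seed, nObservers = nObservers,
               grid = imageGrid(spacing = c(1, 1, 4), size = c(512, 512, 80)),
               structures = structures, marginMean = 2, marginSD = 1,
               boundaryNoiseSD = 1.5, caudalTruncation = truncation,
               levels = levels, landmarks = landmarks)
}
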