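#' Per-structure volume statistics
#'
#' The descriptive statistics of a structure's volumes across the observers
#' who delineated it: mean, sample standard deviation (n - 1 denominator;
#' defined 0 for a single observer), coefficient of variation
#' CoV = SD / mean, and range.
#'
#' @param volumes numeric vector of volumes, cm^3 (one per observer).
#' @param structure optional structure name carried into the result.
#' @return list with elements `structure`, `n`, `mean`, `sd`, `cov`,
#'   `range` (min, max), all in cm^3 except the dimensionless `cov`.
#' @examples
#' volumeStats(c(2, 4, 6))  # mean 4, sd 2, cov 0.5
#' @export
volumeStats <- function(volumes, structure = NA_character_) {
    if (length(volumes) == 0L) stop("volume list is empty")
    if (any(!is.finite(volumes)) || any(volumes < 0))
        stop("volumes must be finite and >= 0")
    n <- length(volumes)
    m <- mean(volumes)
    s <- if (n == 1L) 0 else stats::sd(volumes)
    cov <- if (m > 0) s / m
        else if (s > 0) stop("cov undefined: mean volume is 0 with sd > 0")
        else 0
    list(structure = structure, n = n, mean = m, sd = s, cov = cov,
         range = c(min(volumes), max(volumes)))
}

#' Dice similarity coefficient of two masks
#'
#' DSC = 2|A intersect B| / (|A| + |B|) on voxel counts. Undefined (an
#' error) when both masks are empty.
#'
#' @param a,b [BinaryVolume-class] objects on one grid.
#' @return numeric(1) in \[0, 1\].
#' @export
dice <- function(a, b) {
    checkSharedGrid(a, b)
    na <- sum(a@voxels); nb <- sum(b@voxels)
    if (na + nb == 0L) stop("Dice undefined: both masks are empty")
    2 * sum(a@voxels & b@voxels) / (na + nb)
}

#' Jaccard index of two masks
#'
#' J = |A intersect B| / |A union B|. Undefined (an error) when both masks
#' are empty.
#'
#' @inheritParams dice
#' @return numeric(1) in \[0, 1\].
#' @export
jaccard <- function(a, b) {
    checkSharedGrid(a, b)
    u <- sum(a@voxels | b@voxels)
    if (u == 0L) stop("Jaccard undefined: both masks are empty")
    sum(a@voxels & b@voxels) / u
}

#' Pairwise conformity index CIpairs
#'
#' The multi-observer conformity index that, unlike a plain mean DSC, is
#' robust to the number of participants: the sum over all unordered
#' observer pairs (i < j) of the pairwise intersection volumes, divided by
#' the sum over the same pairs of the pairwise union volumes. For n = 2 it
#' reduces to the Jaccard index; it is 1 iff all masks are identical and
#' non-empty, and is invariant under observer reordering.
#'
#' @param masks list of at least two [BinaryVolume-class] on one grid.
#' @return numeric(1) in \[0, 1\].
#' @export
ciPairs <- function(masks) {
    if (length(masks) < 2L)
        stop("CIpairs needs at least 2 observers")
    for (m in masks[-1]) checkSharedGrid(masks[[1]], m)
    cms <- lapply(masks, function(m) cmaskFromVolume(m))
    ciPairsCropped(cms)
}

ciPairsCropped <- function(cms) {
    counts <- vapply(cms, function(cm) if (is.null(cm)) 0L else cm$count,
                     integer(1))
    n <- length(cms)
    sumI <- 0; sumU <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        int <- pairIntersection(cms[[i]], cms[[j]])
        sumI <- sumI + int
        sumU <- sumU + counts[i] + counts[j] - int
    }
    if (sumU == 0) stop("CIpairs undefined: all masks are empty")
    sumI / sumU
}

#' Mean absolute surface distance of two masks
#'
#' Surface voxels are set voxels with at least one face-adjacent unset (or
#' out-of-grid) neighbour. MASD is the symmetric mean, over the surface
#' voxels of both masks, of each surface-voxel center's Euclidean distance
#' (mm, physical spacing) to the nearest surface-voxel center of the other
#' mask. Computed with an exact separable distance transform.
#'
#' @inheritParams dice
#' @return numeric(1), mm.
#' @export
masd <- function(a, b) {
    checkSharedGrid(a, b)
    ca <- cmaskFromVolume(a); cb <- cmaskFromVolume(b)
    if (is.null(ca) || is.null(cb))
        stop("MASD undefined: a mask is empty")
    masdCropped(ca, cb, a@grid@spacing)
}

#' Surface voxels of a mask
#'
#' @param x a [BinaryVolume-class].
#' @return A [BinaryVolume-class] keeping only the surface voxels.
#' @export
surfaceVolume <- function(x) {
    binaryVolume(x@grid, surfaceOcc(x@voxels))
}

## ---- internal cropped-mask machinery ------------------------------------
## A "cmask" is a structure mask cropped to a bounding sub-box of the
## analysis grid: list(x0..z1 (1-based global indices), occ, count). NULL
## stands for an empty mask. The cohort pipeline works on cmasks so that a
## full 512 x 512 x 80 study grid never has to hold dense masks for every
## observer at once.

cmaskFromVolume <- function(vol) {
    if (!any(vol@voxels)) return(NULL)
    w <- which(vol@voxels, arr.ind = TRUE)
    r <- apply(w, 2, range)
    occ <- vol@voxels[r[1, 1]:r[2, 1], r[1, 2]:r[2, 2], r[1, 3]:r[2, 3],
                      drop = FALSE]
    dim(occ) <- r[2, ] - r[1, ] + 1L
    list(x0 = r[1, 1], x1 = r[2, 1], y0 = r[1, 2], y1 = r[2, 2],
         z0 = r[1, 3], z1 = r[2, 3], occ = occ, count = nrow(w))
}

cmaskFromRaster <- function(cm) {
    if (is.null(cm)) return(NULL)
    cnt <- sum(cm$occ)
    if (cnt == 0L) return(NULL)
    c(cm[c("x0", "x1", "y0", "y1", "z0", "z1", "occ")], list(count = cnt))
}

pairIntersection <- function(a, b) {
    if (is.null(a) || is.null(b)) return(0L)
    x0 <- max(a$x0, b$x0); x1 <- min(a$x1, b$x1)
    y0 <- max(a$y0, b$y0); y1 <- min(a$y1, b$y1)
    z0 <- max(a$z0, b$z0); z1 <- min(a$z1, b$z1)
    if (x0 > x1 || y0 > y1 || z0 > z1) return(0L)
    sa <- a$occ[(x0 - a$x0 + 1L):(x1 - a$x0 + 1L),
                (y0 - a$y0 + 1L):(y1 - a$y0 + 1L),
                (z0 - a$z0 + 1L):(z1 - a$z0 + 1L), drop = FALSE]
    sb <- b$occ[(x0 - b$x0 + 1L):(x1 - b$x0 + 1L),
                (y0 - b$y0 + 1L):(y1 - b$y0 + 1L),
                (z0 - b$z0 + 1L):(z1 - b$z0 + 1L), drop = FALSE]
    sum(sa & sb)
}

# 6-connected surface: set voxels with any face neighbour unset or outside.
surfaceOcc <- function(occ) {
    d <- dim(occ)
    p <- array(FALSE, d + 2L)
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- occ
    ix <- 2:(d[1] + 1L); iy <- 2:(d[2] + 1L); iz <- 2:(d[3] + 1L)
    interior <- p[ix - 1L, iy, iz] & p[ix + 1L, iy, iz] &
                p[ix, iy - 1L, iz] & p[ix, iy + 1L, iz] &
                p[ix, iy, iz - 1L] & p[ix, iy, iz + 1L]
    res <- occ & !interior
    dim(res) <- d
    res
}

masdCropped <- function(a, b, spacing) {
    sa <- surfaceOcc(a$occ); sb <- surfaceOcc(b$occ)
    # union bounding box
    x0 <- min(a$x0, b$x0); x1 <- max(a$x1, b$x1)
    y0 <- min(a$y0, b$y0); y1 <- max(a$y1, b$y1)
    z0 <- min(a$z0, b$z0); z1 <- max(a$z1, b$z1)
    d <- c(x1 - x0 + 1L, y1 - y0 + 1L, z1 - z0 + 1L)
    place <- function(s, cm) {
        occ <- array(FALSE, d)
        occ[(cm$x0 - x0 + 1L):(cm$x1 - x0 + 1L),
            (cm$y0 - y0 + 1L):(cm$y1 - y0 + 1L),
            (cm$z0 - z0 + 1L):(cm$z1 - z0 + 1L)] <- s
        occ
    }
    oa <- place(sa, a); ob <- place(sb, b)
    da <- .edt3d(as.vector(ob), d, spacing)[which(oa)]  # A-surface -> B
    db <- .edt3d(as.vector(oa), d, spacing)[which(ob)]  # B-surface -> A
    (sum(da) + sum(db)) / (length(da) + length(db))
}

## ---- cohort-level agreement ----------------------------------------------

#' Multi-observer agreement analysis of a cohort
#'
#' For every structure: volumes and [volumeStats()] over exactly the
#' observers who delineated it, the pairwise conformity index
#' ([ciPairs()]), and the full pairwise Dice and MASD matrices with their
#' off-diagonal summaries. Structures with a single observer get volume
#' statistics only.
#'
#' @param cohort an [ObserverCohort-class].
#' @param structures structure names to analyze; default all.
#' @param computeMASD logical; MASD matrices are the most expensive part
#'   and can be switched off.
#' @return list of class `"cohortAgreement"`, one element per structure
#'   with fields `structure`, `n`, `observers`, `volumes_cc`, `stats`,
#'   `ci_pairs`, `dsc`, `masd` and `summary`. Coerce with
#'   [agreementTable()].
#' @export
cohortAgreement <- function(cohort, structures = NULL, computeMASD = TRUE) {
    if (is.null(structures)) structures <- structureNames(cohort)
    grid <- cohort@grid
    out <- lapply(structures, function(sname) {
        obs <- observersWith(cohort, sname)
        n <- length(obs)
        cms <- lapply(obs, function(o) {
            d <- getDelineation(cohort, o, sname)
            if (!is.null(d@mask)) cmaskFromVolume(d@mask)
            else cmaskFromRaster(rasterizeCropped(d@contours, grid, sname))
        })
        counts <- vapply(cms, function(cm) if (is.null(cm)) 0L else cm$count,
                         integer(1))
        vols <- counts * voxelVolume(grid) / 1000
        res <- list(structure = sname, n = n, observers = obs,
                    volumes_cc = stats::setNames(vols, obs),
                    stats = volumeStats(vols, sname),
                    ci_pairs = NA_real_, dsc = NULL, masd = NULL,
                    summary = NULL)
        if (n >= 2L) {
            dsc <- matrix(NA_real_, n, n, dimnames = list(obs, obs))
            diag(dsc) <- 1
            msd <- matrix(NA_real_, n, n, dimnames = list(obs, obs))
            diag(msd) <- 0
            sumI <- 0; sumU <- 0
            for (i in seq_len(n - 1)) for (j in (i + 1):n) {
                int <- pairIntersection(cms[[i]], cms[[j]])
                sumI <- sumI + int
                sumU <- sumU + counts[i] + counts[j] - int
                dsc[i, j] <- dsc[j, i] <-
                    if (counts[i] + counts[j] > 0)
                        2 * int / (counts[i] + counts[j]) else NA_real_
                if (computeMASD && !is.null(cms[[i]]) && !is.null(cms[[j]]))
                    msd[i, j] <- msd[j, i] <-
                        masdCropped(cms[[i]], cms[[j]], grid@spacing)
            }
            res$ci_pairs <- if (sumU > 0) sumI / sumU else NA_real_
            res$dsc <- dsc
            if (computeMASD) res$masd <- msd
            off <- dsc[upper.tri(dsc)]
            moff <- if (computeMASD) msd[upper.tri(msd)] else NA_real_
            res$summary <- list(
                dsc = c(mean = mean(off), min = min(off), max = max(off)),
                masd = c(mean = mean(moff), min = min(moff), max = max(moff)))
        }
        res
    })
    names(out) <- structures
    class(out) <- "cohortAgreement"
    out
}

#' Tabulate a cohort agreement analysis
#'
#' One row per structure in the shape of the study's variability tables:
#' N, mean, SD, range, CoV, CIpairs, mean pairwise DSC and MASD. Rows are
#' sorted most-to-least variable by CoV (ties alphabetically). Statistics
#' that are undefined for a single observer (CoV, CIpairs, DSC, MASD) are
#' `NA`, rendered blank — not 0 — by [runMetrics()].
#'
#' @param agreement result of [cohortAgreement()].
#' @return data.frame with columns `structure, n, mean_cc, sd_cc, cov,
#'   min_cc, max_cc, ci_pairs, dsc_mean, masd_mean_mm`.
#' @export
agreementTable <- function(agreement) {
    rows <- lapply(agreement, function(a) {
        data.frame(structure = a$structure, n = a$n,
                   mean_cc = a$stats$mean, sd_cc = a$stats$sd,
                   cov = if (a$n >= 2) a$stats$cov else NA_real_,
                   min_cc = a$stats$range[1], max_cc = a$stats$range[2],
                   ci_pairs = a$ci_pairs,
                   dsc_mean = if (!is.null(a$summary))
                       a$summary$dsc[["mean"]] else NA_real_,
                   masd_mean_mm = if (!is.null(a$summary))
                       a$summary$masd[["mean"]] else NA_real_)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab[order(-tab$cov, tab$structure), , drop = FALSE]
}
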