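#' Fraction of a nodal level covered by a PTV
#'
#' `|level intersect ptv| / |level|` on voxel counts (never on re-rounded
#' cm^3, to avoid double rounding).
#'
#' @param level,ptv [BinaryVolume-class] objects on one grid; `level` must
#'   be non-empty.
#' @return numeric(1) in \[0, 1\].
#' @export
overlapFraction <- function(level, ptv) {
    checkSharedGrid(level, ptv)
    nl <- sum(level@voxels)
    if (nl == 0L) stop("overlap fraction undefined: level mask is empty")
    sum(level@voxels & ptv@voxels) / nl
}

#' The strict >70% inclusion rule
#'
#' A lymph node level counts as included in the PTV iff the overlapping
#' volume is *more than* `threshold` of the level's total volume — a
#' strict inequality, so a fraction of exactly 0.70 is NOT included.
#'
#' @param fraction overlap fraction in \[0, 1\].
#' @param threshold inclusion threshold, default 0.70; must lie in (0, 1).
#' @return logical.
#' @export
isIncluded <- function(fraction, threshold = 0.70) {
    if (length(threshold) != 1L || !is.finite(threshold) ||
        threshold <= 0 || threshold >= 1)
        stop("config error: inclusion threshold must lie in (0, 1)")
    if (any(fraction < 0 | fraction > 1))
        stop("overlap fraction must lie in [0, 1]")
    fraction > threshold
}

#' Per-level PTV inclusion across a cohort
#'
#' For every nodal level, computes each observer's overlap fraction with
#' their own PTV and applies the inclusion rule; aggregates the count of
#' including observers and the covered-by-all / covered-by-no-observer
#' flags. Observers lacking the named PTV are excluded with a warning.
#'
#' @param cohort an [ObserverCohort-class].
#' @param levels named list of [BinaryVolume-class] level masks on the
#'   cohort grid (names unique, volumes > 0).
#' @param ptvName structure name of the target volume, default `"PTV1"`.
#' @param threshold see [isIncluded()].
#' @return data.frame of class `"levelCoverage"`, one row per level:
#'   `level, n_observers, n_included, covered_by_all, covered_by_none`,
#'   plus one `frac_<observer>` column per observer. Attribute
#'   `"included"` holds the logical inclusion matrix.
#' @export
levelCoverageTable <- function(cohort, levels, ptvName = "PTV1",
                               threshold = 0.70) {
    if (length(levels) == 0L) stop("validation error: empty level list")
    if (is.null(names(levels)) || anyDuplicated(names(levels)))
        stop("level masks must have unique names")
    isIncluded(0, threshold)  # validate threshold early
    obs <- observersWith(cohort, ptvName)
    missing <- setdiff(cohort@observers, obs)
    if (length(missing))
        warning("observer(s) without '", ptvName, "' excluded from level ",
                "coverage: ", paste(missing, collapse = ", "), call. = FALSE)
    if (length(obs) == 0L)
        stop("no observer in the cohort has structure '", ptvName, "'")
    grid <- cohort@grid
    ptvs <- lapply(obs, function(o) {
        d <- getDelineation(cohort, o, ptvName)
        if (!is.null(d@mask)) cmaskFromVolume(d@mask)
        else cmaskFromRaster(rasterizeCropped(d@contours, grid, ptvName))
    })
    lv <- lapply(levels, cmaskFromVolume)
    bad <- vapply(lv, is.null, logical(1))
    if (any(bad))
        stop("level mask(s) empty: ", paste(names(levels)[bad], collapse = ", "))
    frac <- t(vapply(lv, function(l)
        vapply(ptvs, function(p) pairIntersection(l, p) / l$count,
               numeric(1)), numeric(length(obs))))
    if (length(obs) == 1L) frac <- matrix(frac, ncol = 1L)
    dimnames(frac) <- list(names(levels), obs)
    inc <- isIncluded(frac, threshold)
    dim(inc) <- dim(frac); dimnames(inc) <- dimnames(frac)
    count <- rowSums(inc)
    tab <- data.frame(level = names(levels),
                      n_observers = length(obs),
                      n_included = as.integer(count),
                      covered_by_all = count == length(obs),
                      covered_by_none = count == 0)
    fr <- as.data.frame(frac)
    names(fr) <- paste0("frac_", obs)
    tab <- cbind(tab, fr)
    rownames(tab) <- NULL
    attr(tab, "included") <- inc
    attr(tab, "threshold") <- threshold
    class(tab) <- c("levelCoverage", "data.frame")
    tab
}
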