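#' @import methods
NULL

#' ImageGrid: the common voxel lattice
#'
#' All structures in an analysis are rasterized onto a single regular voxel
#' grid. Coordinates are physical millimetres with x increasing to the
#' patient's left, y posteriorly and z cranially. `origin` is the physical
#' position of the *center* of voxel (0,0,0); voxel indices are 0-based and
#' the grid extent is treated as half-open along each axis.
#'
#' @slot origin numeric(3), mm; center of voxel (0,0,0).
#' @slot spacing numeric(3), mm; in-plane dx, dy and slice thickness dz.
#' @slot size integer(3); voxel counts per axis.
#'
#' @seealso [imageGrid()], [sliceZ()], [voxelVolume()]
#' @export
setClass("ImageGrid",
    representation(origin = "numeric", spacing = "numeric", size = "integer"))

setValidity("ImageGrid", function(object) {
    msg <- character()
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (length(object@spacing) != 3L) msg <- c(msg, "spacing must have length 3")
    if (length(object@size) != 3L) msg <- c(msg, "size must have length 3")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
        msg <- c(msg, "all spacings must be > 0")
    if (any(is.na(object@size)) || any(object@size < 1L))
        msg <- c(msg, "all sizes must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct an ImageGrid
#'
#' @param origin numeric(3) physical position (mm) of the center of voxel
#'   (0,0,0).
#' @param spacing numeric(3) voxel size (mm): dx, dy, dz. The default dz of
#'   4 mm matches a typical head-and-neck planning CT.
#' @param size integer(3) voxel counts per axis.
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- imageGrid(spacing = c(1, 1, 4), size = c(64, 64, 20))
#' voxelVolume(g)  # mm^3
#' @export
imageGrid <- function(origin = c(0, 0, 0), spacing = c(1, 1, 4), size) {
    new("ImageGrid", origin = as.numeric(origin),
        spacing = as.numeric(spacing), size = as.integer(size))
}

#' @describeIn imageGrid physical z positions (mm) of all slice centers.
#' @param grid an `ImageGrid`.
#' @export
sliceZ <- function(grid) {
    grid@origin[3] + (seq_len(grid@size[3]) - 1) * grid@spacing[3]
}

#' @describeIn imageGrid volume of one voxel, mm^3.
#' @export
voxelVolume <- function(grid) prod(grid@spacing)

#' @describeIn imageGrid voxel-center coordinates (mm) along axis 1, 2 or 3.
#' @param axis integer axis index (1 = x, 2 = y, 3 = z).
#' @export
axisCoords <- function(grid, axis) {
    grid@origin[axis] + (seq_len(grid@size[axis]) - 1) * grid@spacing[axis]
}

sameGrid <- function(a, b, tol = 1e-6) {
    all(abs(a@origin - b@origin) <= tol) &&
        all(abs(a@spacing - b@spacing) <= tol) && all(a@size == b@size)
}

setMethod("show", "ImageGrid", function(object) {
    cat("ImageGrid:",
        paste(object@size, collapse = " x "), "voxels,",
        paste(format(object@spacing), collapse = " x "), "mm spacing, origin (",
        paste(format(object@origin), collapse = ", "), ") mm\n")
})

#' PlanarContour: one closed planar polygon on a CT slice
#'
#' A single ring of an observer's delineation on one axial slice: an ordered
#' polygon in the (x, y) plane at slice position `z`. The polygon is closed
#' implicitly (last vertex joins the first). A ring is either an outer
#' boundary or a hole; holes are subtracted during rasterization.
#'
#' @slot z numeric(1) slice position, mm.
#' @slot vertices numeric matrix, n x 2, ordered (x, y) vertices in mm.
#' @slot role `"outer"` or `"hole"`.
#' @export
setClass("PlanarContour",
    representation(z = "numeric", vertices = "matrix", role = "character"))

setValidity("PlanarContour", function(object) {
    msg <- character()
    if (length(object@z) != 1L || !is.finite(object@z))
        msg <- c(msg, "z must be a single finite number")
    v <- object@vertices
    if (!is.numeric(v) || ncol(v) != 2L)
        msg <- c(msg, "vertices must be a numeric n x 2 matrix")
    else if (nrow(v) < 3L)
        msg <- c(msg, "a polygon needs at least 3 vertices")
    else if (polygonArea(v) == 0)
        msg <- c(msg, "polygon has zero area")
    if (!object@role %in% c("outer", "hole"))
        msg <- c(msg, "role must be 'outer' or 'hole'")
    if (length(msg)) msg else TRUE
})

# shoelace; sign carries orientation
polygonArea <- function(v) {
    x <- v[, 1]; y <- v[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    sum(x * yn - xn * y) / 2
}

#' @rdname PlanarContour-class
#' @param z slice position, mm.
#' @param vertices n x 2 numeric matrix of (x, y) vertices, mm.
#' @param role `"outer"` (default) or `"hole"`.
#' @export
planarContour <- function(z, vertices, role = "outer") {
    new("PlanarContour", z = as.numeric(z),
        vertices = matrix(as.numeric(vertices), ncol = 2), role = role)
}

#' BinaryVolume: grid-aligned boolean occupancy
#'
#' The voxelized form of a structure on an [ImageGrid-class]: a logical
#' array whose dimensions equal the grid size. Every agreement metric in the
#' package operates on `BinaryVolume` voxel counts.
#'
#' @slot grid the `ImageGrid` the mask lives on.
#' @slot voxels logical array, dim = grid size.
#' @seealso [binaryVolume()], [volumeCC()], [volumeOp()]
#' @export
setClass("BinaryVolume",
    representation(grid = "ImageGrid", voxels = "array"))

setValidity("BinaryVolume", function(object) {
    d <- dim(object@voxels)
    if (!is.logical(object@voxels))
        return("voxels must be a logical array")
    if (length(d) != 3L || any(d != object@grid@size))
        return("voxel array dimensions must equal grid size")
    TRUE
})

#' @rdname BinaryVolume-class
#' @param grid an `ImageGrid`.
#' @param voxels logical array matching `size(grid)`; default all-empty.
#' @export
binaryVolume <- function(grid, voxels = NULL) {
    if (is.null(voxels))
        voxels <- array(FALSE, dim = grid@size)
    storage.mode(voxels) <- "logical"
    new("BinaryVolume", grid = grid, voxels = voxels)
}

setMethod("show", "BinaryVolume", function(object) {
    cat("BinaryVolume:", sum(object@voxels), "of",
        prod(object@grid@size), "voxels set,",
        format(volumeCC(object), digits = 4), "cm^3\n")
})

#' StructureDelineation: one observer's named structure
#'
#' Holds either a stack of [PlanarContour-class] rings or a pre-rasterized
#' [BinaryVolume-class] for one (observer, structure) pair. Structure names
#' come from a controlled vocabulary (see [canonicalNames()]); unmapped
#' names are preserved verbatim.
#'
#' @slot observer observer label.
#' @slot structure canonical structure name.
#' @slot contours list of `PlanarContour` (possibly empty when a mask is
#'   supplied instead).
#' @slot mask a `BinaryVolume`, or NULL when contours are supplied.
#' @export
setClass("StructureDelineation",
    representation(observer = "character", structure = "character",
                   contours = "list", mask = "ANY"))

setValidity("StructureDelineation", function(object) {
    msg <- character()
    if (!nzchar(object@structure)) msg <- c(msg, "structure name must be non-empty")
    if (!nzchar(object@observer)) msg <- c(msg, "observer id must be non-empty")
    if (!is.null(object@mask) && !is(object@mask, "BinaryVolume"))
        msg <- c(msg, "mask must be a BinaryVolume or NULL")
    if (is.null(object@mask) && length(object@contours) == 0L)
        msg <- c(msg, "a delineation needs contours or a mask")
    if (!all(vapply(object@contours, is, logical(1), "PlanarContour")))
        msg <- c(msg, "contours must all be PlanarContour objects")
    if (length(msg)) msg else TRUE
})

#' @rdname StructureDelineation-class
#' @param observer observer label.
#' @param structure structure name.
#' @param contours list of `PlanarContour`.
#' @param mask optional pre-rasterized `BinaryVolume` (bypasses
#'   rasterization but must declare the analysis grid).
#' @export
structureDelineation <- function(observer, structure, contours = list(),
                                 mask = NULL) {
    new("StructureDelineation", observer = as.character(observer),
        structure = as.character(structure), contours = contours, mask = mask)
}

setMethod("show", "StructureDelineation", function(object) {
    cat("StructureDelineation:", object@structure, "by", object@observer,
        "-", if (is.null(object@mask))
            paste(length(object@contours), "contour(s)") else "pre-rasterized mask",
        "\n")
})

#' ObserverCohort: the full multi-observer delineation set
#'
#' All delineations of a contouring study on one shared grid. An observer
#' who omitted a structure is simply absent from that structure's
#' delineation list — omissions are never represented as empty volumes, and
#' per-structure N counts only the observers who contoured the structure.
#'
#' @slot grid the common `ImageGrid`.
#' @slot observers character vector of observer ids, in input order.
#' @slot delineations list of [StructureDelineation-class].
#' @seealso [observerCohort()], [structureCount()], [cohortAgreement()]
#' @export
setClass("ObserverCohort",
    representation(grid = "ImageGrid", observers = "character",
                   delineations = "list"))

setValidity("ObserverCohort", function(object) {
    msg <- character()
    if (!all(vapply(object@delineations, is, logical(1), "StructureDelineation")))
        msg <- c(msg, "delineations must all be StructureDelineation objects")
    obs <- vapply(object@delineations, function(d) d@observer, character(1))
    if (!all(obs %in% object@observers))
        msg <- c(msg, "every delineation's observer must be listed in observers")
    if (anyDuplicated(object@observers))
        msg <- c(msg, "observer ids must be unique")
    key <- paste(obs, vapply(object@delineations, function(d) d@structure,
                             character(1)))
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate (observer, structure) pair; merge before construction")
    if (length(msg)) msg else TRUE
})

#' Construct an ObserverCohort
#'
#' Duplicate (observer, structure) pairs — e.g. a PTV split into two
#' structures with the same name — are merged by union of their contour
#' stacks, with a warning.
#'
#' @param grid the common `ImageGrid`.
#' @param delineations list of `StructureDelineation`.
#' @param observers optional explicit observer ordering; defaults to order
#'   of first appearance.
#' @return An [ObserverCohort-class].
#' @export
observerCohort <- function(grid, delineations, observers = NULL) {
    obs <- vapply(delineations, function(d) d@observer, character(1))
    str <- vapply(delineations, function(d) d@structure, character(1))
    key <- paste(obs, str, sep = "\r")
    if (anyDuplicated(key)) {
        for (k in unique(key[duplicated(key)])) {
            idx <- which(key == k)
            warning("merging ", length(idx), " same-named structures '",
                    str[idx[1]], "' for observer '", obs[idx[1]],
                    "' by union", call. = FALSE)
            merged <- delineations[[idx[1]]]
            for (i in idx[-1]) {
                other <- delineations[[i]]
                if (!is.null(merged@mask) || !is.null(other@mask)) {
                    ma <- if (is.null(merged@mask)) rasterize(merged, grid) else merged@mask
                    mb <- if (is.null(other@mask)) rasterize(other, grid) else other@mask
                    merged@mask <- volumeOp(ma, mb, "union")
                    merged@contours <- list()
                } else {
                    merged@contours <- c(merged@contours, other@contours)
                }
            }
            delineations[[idx[1]]] <- merged
        }
        delineations <- delineations[!duplicated(key)]
        obs <- obs[!duplicated(key)]
    }
    if (is.null(observers)) observers <- unique(obs)
    new("ObserverCohort", grid = grid, observers = as.character(observers),
        delineations = delineations)
}

#' Cohort accessors
#'
#' @param cohort an [ObserverCohort-class].
#' @return `structureNames()`: all structure names present;
#'   `structureCount()`: named integer vector, per-structure number of
#'   observers who delineated it (the "N" of the study tables);
#'   `getDelineation()`: one `StructureDelineation` or NULL;
#'   `cohortObservers()`: observer ids.
#' @export
structureNames <- function(cohort) {
    unique(vapply(cohort@delineations, function(d) d@structure, character(1)))
}

#' @rdname structureNames
#' @export
structureCount <- function(cohort) {
    str <- vapply(cohort@delineations, function(d) d@structure, character(1))
    tab <- table(str)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[structureNames(cohort)]
}

#' @rdname structureNames
#' @param observer,structure selection labels.
#' @export
getDelineation <- function(cohort, observer, structure) {
    for (d in cohort@delineations)
        if (d@observer == observer && d@structure == structure) return(d)
    NULL
}

#' @rdname structureNames
#' @export
cohortObservers <- function(cohort) cohort@observers

#' @rdname structureNames
#' @param structure structure name.
#' @export
observersWith <- function(cohort, structure) {
    obs <- vapply(cohort@delineations, function(d) d@observer, character(1))
    str <- vapply(cohort@delineations, function(d) d@structure, character(1))
    cohort@observers[cohort@observers %in% obs[str == structure]]
}

setMethod("show", "ObserverCohort", function(object) {
    cat("ObserverCohort:", length(object@observers), "observers,",
        length(structureNames(object)), "structures on ")
    show(object@grid)
    n <- structureCount(object)
    cat("  per-structure N:",
        paste(names(n), n, sep = "=", collapse = ", "), "\n")
})
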