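#' Structure volume in cubic centimetres
#'
#' Volume is the number of set voxels times the voxel volume dx*dy*dz,
#' converted from mm^3 to cm^3. An empty mask has volume 0.
#'
#' @param x a [BinaryVolume-class].
#' @return numeric(1), cm^3.
#' @export
setGeneric("volumeCC", function(x) standardGeneric("volumeCC"))

#' @rdname volumeCC
#' @export
setMethod("volumeCC", "BinaryVolume", function(x) {
    sum(x@voxels) * voxelVolume(x@grid) / 1000
})

#' @rdname volumeCC
#' @export
voxelCount <- function(x) sum(x@voxels)

#' Voxelwise set operations on two masks
#'
#' Element-wise intersection, union or difference of two masks that share
#' an identical grid. Masks on mismatched grids are a contract error —
#' resampling between heterogeneous grids is deliberately unsupported.
#'
#' @param a,b [BinaryVolume-class] objects on the same grid.
#' @param op `"intersect"`, `"union"` or `"minus"` (a minus b).
#' @return A [BinaryVolume-class].
#' @examples
#' g <- imageGrid(spacing = c(1, 1, 1), size = c(10, 10, 10))
#' a <- binaryVolume(g); a@voxels[1:5, , ] <- TRUE
#' b <- binaryVolume(g); b@voxels[4:10, , ] <- TRUE
#' voxelCount(volumeOp(a, b, "intersect"))  # 200
#' @export
volumeOp <- function(a, b, op = c("intersect", "union", "minus")) {
    op <- match.arg(op)
    checkSharedGrid(a, b)
    vox <- switch(op,
        intersect = a@voxels & b@voxels,
        union = a@voxels | b@voxels,
        minus = a@voxels & !b@voxels)
    binaryVolume(a@grid, vox)
}

checkSharedGrid <- function(a, b) {
    if (!sameGrid(a@grid, b@grid))
        stop("grid mismatch: operands must share one grid; got [",
             paste(a@grid@size, collapse = "x"), " @ ",
             paste(a@grid@spacing, collapse = "/"), " mm] vs [",
             paste(b@grid@size, collapse = "x"), " @ ",
             paste(b@grid@spacing, collapse = "/"), " mm]")
    invisible(TRUE)
}
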