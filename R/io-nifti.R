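#' Read a binary mask from NIfTI
#'
#' Reads one observer's pre-rasterized structure mask. The NIfTI voxel
#' dimensions and image size must match the declared analysis grid —
#' resampling is out of scope, so a mismatch is an error, not a warning.
#' Any nonzero voxel is treated as set.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param grid the analysis [ImageGrid-class] the mask must conform to.
#' @param tol spacing comparison tolerance, mm.
#' @return A [BinaryVolume-class].
#' @export
readMaskNifti <- function(path, grid, tol = 1e-3) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3-D NIfTI mask, got ", length(d), " dimensions")
    if (any(d != grid@size))
        stop("NIfTI size ", paste(d, collapse = "x"),
             " does not match grid size ", paste(grid@size, collapse = "x"))
    pd <- RNifti::pixdim(img)
    if (any(abs(pd[1:3] - grid@spacing) > tol))
        stop("NIfTI voxel spacing (", paste(signif(pd[1:3], 6), collapse = ", "),
             " mm) does not match grid spacing (",
             paste(grid@spacing, collapse = ", "), " mm)")
    binaryVolume(grid, array(as.array(img) != 0, dim = d))
}

#' Write a binary mask to NIfTI
#'
#' @param volume a [BinaryVolume-class].
#' @param path output file (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeMaskNifti <- function(volume, path) {
    g <- volume@grid
    img <- RNifti::asNifti(array(as.integer(volume@voxels), dim = g@size))
    RNifti::pixdim(img) <- g@spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}
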