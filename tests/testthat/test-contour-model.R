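test_that("grid invariants are enforced and accessors are consistent", {
    expect_error(imageGrid(spacing = c(1, 1, 0), size = c(4, 4, 4)),
                 "spacings")
    expect_error(imageGrid(spacing = c(1, 1, 4), size = c(4, 0, 4)), "sizes")
    g <- imageGrid(origin = c(-10, 5, 0), spacing = c(2, 3, 4),
                   size = c(4, 5, 6))
    expect_equal(voxelVolume(g), 24)
    expect_equal(sliceZ(g), seq(0, 20, by = 4))
    expect_equal(axisCoords(g, 1), seq(-10, -4, by = 2))
})

test_that("degenerate polygons are rejected", {
    expect_error(planarContour(0, cbind(c(0, 1), c(0, 1))), "3 vertices")
    expect_error(planarContour(0, cbind(c(0, 1, 2), c(0, 0, 0))),
                 "zero area")
})

test_that("rasterization matches its derived examples", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(20, 20, 3))
    sq <- planarContour(4, cbind(c(3, 13, 13, 3), c(3, 3, 13, 13)))
    v <- rasterize(structureDelineation("o", "s", list(sq)), g)
    expect_equal(voxelCount(v), 100)              # 10x10 mm at 1 mm
    expect_equal(sum(v@voxels[, , c(1, 3)]), 0)   # other slices empty

    hole <- planarContour(4, sq@vertices, role = "hole")
    v0 <- rasterize(structureDelineation("o", "s", list(sq, hole)), g)
    expect_equal(voxelCount(v0), 0)               # polygon minus itself

    gc <- imageGrid(spacing = c(1, 1, 4), size = c(30, 30, 1))
    circ <- circleContour(0, 14.2, 14.2, 10)
    vc <- rasterize(structureDelineation("o", "s", list(circ)), gc)
    expect_lt(abs(voxelCount(vc) - pi * 100) / (pi * 100), 0.02)
})

test_that("rasterization agrees voxel-for-voxel with the brute-force scan", {
    g <- imageGrid(spacing = c(1.5, 2, 4), size = c(16, 14, 2))
    # concave L-shape, a rotated triangle, and a ring with a hole
    fixtures <- list(
        list(planarContour(0, cbind(c(1, 20, 20, 10, 10, 1),
                                    c(1, 1, 10, 10, 24, 24)))),
        list(planarContour(4, cbind(c(2.3, 21.7, 12.1), c(25, 3.2, 20.4)))),
        list(circleContour(0, 12, 13, 10),
             circleContour(0, 12, 13, 4.5, role = "hole")))
    for (contours in fixtures) {
        v <- rasterize(structureDelineation("o", "s", contours), g)
        k <- contourIOV:::sliceIndex(contours[[1]]@z, g)
        expect_identical(v@voxels[, , k],
                         oracleRasterSlice(contours, g, k))
    }
})

test_that("volumeCC follows the slab model and is additive/translation-invariant", {
    g <- imageGrid(spacing = c(1, 1, 1), size = c(12, 12, 12))
    cube <- cubeMask(g, c(1, 10), c(1, 10), c(1, 10))
    expect_equal(volumeCC(cube), 1.0)
    expect_equal(volumeCC(binaryVolume(g)), 0)

    g4 <- imageGrid(spacing = c(1, 1, 4), size = c(20, 20, 3))
    slab <- rasterize(list(planarContour(
        0, cbind(c(3, 13, 13, 3), c(3, 3, 13, 13)))), g4)
    expect_equal(volumeCC(slab), 0.4)             # 100 mm^2 x 4 mm

    a <- cubeMask(g, c(1, 3), c(1, 3), c(1, 3))
    b <- cubeMask(g, c(7, 9), c(7, 9), c(7, 9))
    expect_equal(volumeCC(volumeOp(a, b, "union")),
                 volumeCC(a) + volumeCC(b))
    shifted <- cubeMask(g, c(4, 6), c(2, 4), c(5, 7))
    expect_equal(volumeCC(shifted), volumeCC(a))
})

test_that("boolean operations obey set identities and reject grid mismatch", {
    g <- imageGrid(spacing = c(1, 1, 1), size = c(15, 12, 12))
    a <- cubeMask(g, c(1, 10), c(1, 10), c(1, 10))
    b <- cubeMask(g, c(6, 15), c(1, 10), c(1, 10))
    expect_equal(volumeOp(a, a, "intersect")@voxels, a@voxels)
    expect_equal(volumeOp(a, a, "union")@voxels, a@voxels)
    expect_equal(voxelCount(volumeOp(a, b, "intersect")), 500)
    expect_equal(voxelCount(volumeOp(a, b, "intersect")) +
                     voxelCount(volumeOp(a, b, "union")),
                 voxelCount(a) + voxelCount(b))
    d <- cubeMask(g, c(12, 15), c(1, 10), c(1, 10))
    expect_equal(voxelCount(volumeOp(a, d, "intersect")), 0)
    expect_equal(voxelCount(volumeOp(a, d, "union")),
                 voxelCount(a) + voxelCount(d))
    g2 <- imageGrid(spacing = c(2, 2, 2), size = c(15, 12, 12))
    expect_error(volumeOp(a, cubeMask(g2, c(1, 2), c(1, 2), c(1, 2))),
                 "grid mismatch")
})

test_that("contour z matching respects the dz/2 tolerance with ties to the lower slice", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(10, 10, 4))  # slices 0,4,8,12
    d <- structureDelineation("o", "s", list(planarContour(
        5.9, cbind(c(1, 8, 8, 1), c(1, 1, 8, 8)))))
    v <- rasterize(d, g)                           # 5.9 -> slice at 4
    expect_true(all(which(apply(v@voxels, 3, any)) == 2))
    tie <- structureDelineation("o", "s", list(planarContour(
        6, cbind(c(1, 8, 8, 1), c(1, 1, 8, 8)))))  # exact midpoint
    expect_true(all(which(apply(rasterize(tie, g)@voxels, 3, any)) == 2))
    expect_error(rasterize(structureDelineation("o", "s", list(planarContour(
        30, cbind(c(1, 8, 8, 1), c(1, 1, 8, 8))))), g), "coordinate error")
})

test_that("JSON writer/reader round-trip preserves geometry and labels", {
    g <- imageGrid(origin = c(-5, -5, 0), spacing = c(1.25, 1.25, 4),
                   size = c(24, 24, 6))
    ring <- circleContour(8, 7.123456, 3.654321, 6.789012, n = 40)
    hole <- circleContour(8, 7.1, 3.6, 2.345678, n = 17, role = "hole")
    sq <- planarContour(4, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
    cohort <- observerCohort(g, list(
        structureDelineation("Obs A", "PTV1", list(sq, ring, hole)),
        structureDelineation("Obs B", "brainstem", list(sq))))
    path <- withr::local_tempfile(fileext = ".json")
    writeContours(cohort, path)
    back <- readContours(path)
    expect_identical(cohortObservers(back), c("Obs A", "Obs B"))
    expect_setequal(structureNames(back), c("brainstem", "PTV1"))
    d0 <- getDelineation(cohort, "Obs A", "PTV1")
    d1 <- getDelineation(back, "Obs A", "PTV1")
    for (i in seq_along(d0@contours)) {
        expect_lt(max(abs(d0@contours[[i]]@vertices -
                          d1@contours[[i]]@vertices)), 1e-6)
        expect_identical(d0@contours[[i]]@role, d1@contours[[i]]@role)
    }
    expect_true(contourIOV:::sameGrid(back@grid, g))
})

test_that("reader maps aliases, counts omissions, and rejects bad polygons", {
    g <- list(origin = c(0, 0, 0), spacing = c(1, 1, 4), size = c(30, 30, 4))
    sq <- list(z = 0, role = "outer",
               vertices = list(c(2, 2), c(12, 2), c(12, 12), c(2, 12)))
    # ten observers; pituitary present for only 7 (an omission pattern like
    # the study's organ-at-risk table)
    observers <- lapply(1:10, function(i) {
        st <- list(list(name = "PTV 1", contours = list(sq)))
        if (i <= 7)
            st <- c(st, list(list(name = "Pituitary Gland",
                                  contours = list(sq))))
        list(id = sprintf("RO%02d", i), structures = st)
    })
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(grid = g, observers = observers), path,
                         auto_unbox = TRUE, digits = NA)
    cohort <- readContours(path)
    n <- structureCount(cohort)
    expect_equal(unname(n["pituitary"]), 7L)
    expect_equal(unname(n["PTV1"]), 10L)

    # unmapped name kept verbatim with a warning
    observers[[1]]$structures[[1]]$name <- "Mystery ROI"
    jsonlite::write_json(list(grid = g, observers = observers), path,
                         auto_unbox = TRUE, digits = NA)
    expect_warning(c2 <- readContours(path), "kept verbatim")
    expect_true("Mystery ROI" %in% structureNames(c2))

    # degenerate 2-vertex polygon -> parse error naming the ROI
    observers[[1]]$structures[[1]]$contours[[1]]$vertices <-
        list(c(0, 0), c(5, 5))
    jsonlite::write_json(list(grid = g, observers = observers), path,
                         auto_unbox = TRUE, digits = NA)
    suppressWarnings(expect_error(readContours(path), "degenerate"))
})

test_that("single-observer cube fixture round-trips with N = 1", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(20, 20, 3))
    sq <- planarContour(0, cbind(c(2, 12, 12, 2), c(2, 2, 12, 12)))
    sq2 <- planarContour(4, sq@vertices)
    cohort <- observerCohort(g, list(
        structureDelineation("solo", "PTV1", list(sq, sq2))))
    path <- withr::local_tempfile(fileext = ".json")
    writeContours(cohort, path)
    back <- readContours(path)
    expect_equal(unname(structureCount(back)["PTV1"]), 1L)
})

test_that("same-named structures for one observer merge by union with a warning", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(30, 30, 2))
    a <- planarContour(0, cbind(c(1, 9, 9, 1), c(1, 1, 9, 9)))
    b <- planarContour(0, cbind(c(15, 25, 25, 15), c(15, 15, 25, 25)))
    expect_warning(cohort <- observerCohort(g, list(
        structureDelineation("o1", "PTV1", list(a)),
        structureDelineation("o1", "PTV1", list(b)))), "merging")
    v <- rasterize(getDelineation(cohort, "o1", "PTV1"), g)
    expect_equal(voxelCount(v), 8 * 8 + 10 * 10)
})

test_that("NIfTI masks round-trip and must match the declared grid", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(16, 16, 5))
    m <- cubeMask(g, c(2, 8), c(3, 9), c(2, 4))
    path <- withr::local_tempfile(fileext = ".nii.gz")
    writeMaskNifti(m, path)
    back <- readMaskNifti(path, g)
    expect_identical(back@voxels, m@voxels)
    g2 <- imageGrid(spacing = c(2, 2, 4), size = c(16, 16, 5))
    expect_error(readMaskNifti(path, g2), "spacing")
    g3 <- imageGrid(spacing = c(1, 1, 4), size = c(16, 16, 6))
    expect_error(readMaskNifti(path, g3), "size")
})

test_that("masks passed as delineations must declare the analysis grid", {
    g <- imageGrid(spacing = c(1, 1, 4), size = c(10, 10, 3))
    g2 <- imageGrid(spacing = c(1, 1, 2), size = c(10, 10, 3))
    m <- cubeMask(g2, c(1, 5), c(1, 5), c(1, 2))
    d <- structureDelineation("o", "s", mask = m)
    expect_error(rasterize(d, g), "different grid")
    ok <- structureDelineation("o", "s", mask = cubeMask(g, c(1, 5),
                                                         c(1, 5), c(1, 2)))
    expect_identical(rasterize(ok, g)@voxels, ok@mask@voxels)
})
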