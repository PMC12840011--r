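# Independent brute-force oracles, deliberately coded without reusing the
# package's vectorized internals.

# scalar crossing-number point-in-polygon, one point at a time
oraclePointInPolygon <- function(x, y, poly) {
    n <- nrow(poly)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1]; yi <- poly[i, 2]
        xj <- poly[j, 1]; yj <- poly[j, 2]
        if ((yi > y) != (yj > y)) {
            xcross <- (xj - xi) * (y - yi) / (yj - yi) + xi
            if (x < xcross) inside <- !inside
        }
        j <- i
    }
    inside
}

# rasterize a single-slice polygon set by scanning every voxel center
oracleRasterSlice <- function(contours, grid, sliceK) {
    xs <- contourIOV::axisCoords(grid, 1)
    ys <- contourIOV::axisCoords(grid, 2)
    occ <- matrix(FALSE, grid@size[1], grid@size[2])
    for (ix in seq_along(xs)) for (iy in seq_along(ys)) {
        inOuter <- FALSE; inHole <- FALSE
        for (ct in contours) {
            if (oraclePointInPolygon(xs[ix], ys[iy], ct@vertices)) {
                if (ct@role == "outer") inOuter <- TRUE else inHole <- TRUE
            }
        }
        occ[ix, iy] <- inOuter && !inHole
    }
    occ
}

# surface voxels by explicit neighbour enumeration
oracleSurfaceCoords <- function(vol) {
    occ <- vol@voxels
    d <- dim(occ)
    w <- which(occ, arr.ind = TRUE)
    keep <- logical(nrow(w))
    shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(w))) {
        for (s in seq_len(6)) {
            nb <- w[r, ] + shifts[s, ]
            if (any(nb < 1) || any(nb > d) ||
                !occ[nb[1], nb[2], nb[3]]) { keep[r] <- TRUE; break }
        }
    }
    w <- w[keep, , drop = FALSE]
    sp <- vol@grid@spacing
    cbind((w[, 1] - 1) * sp[1], (w[, 2] - 1) * sp[2], (w[, 3] - 1) * sp[3])
}

# exhaustive symmetric mean nearest-surface distance (chunked all-pairs)
oracleMASD <- function(a, b) {
    pa <- oracleSurfaceCoords(a)
    pb <- oracleSurfaceCoords(b)
    nearest <- function(p, q) {
        vapply(seq_len(nrow(p)), function(i) {
            sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2 +
                     (q[, 3] - p[i, 3])^2))
        }, numeric(1))
    }
    da <- nearest(pa, pb)
    db <- nearest(pb, pa)
    (sum(da) + sum(db)) / (length(da) + length(db))
}

# seeded random mask on a grid
randomMask <- function(grid, density = 0.3) {
    v <- array(stats::runif(prod(grid@size)) < density, dim = grid@size)
    contourIOV::binaryVolume(grid, v)
}

smallGrid <- function(nx = 12, ny = 12, nz = 6, spacing = c(1, 1, 1)) {
    contourIOV::imageGrid(spacing = spacing, size = c(nx, ny, nz))
}

# circle polygon helper
circleContour <- function(z, cx, cy, r, n = 128, role = "outer") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    contourIOV::planarContour(z, cbind(cx + r * cos(th), cy + r * sin(th)),
                              role = role)
}

# a solid axis-aligned cube as a BinaryVolume (index ranges, 1-based)
cubeMask <- function(grid, xr, yr, zr) {
    v <- array(FALSE, dim = grid@size)
    v[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
    contourIOV::binaryVolume(grid, v)
}
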