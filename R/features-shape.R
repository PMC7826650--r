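# Isosurface of a binary mask. The zero-padded mask is first resampled onto
# the dual (cell-corner) lattice with a 2x2x2 box average, which anti-aliases
# the staircase boundary (raw binary isosurfaces overestimate the area of
# smooth objects by 20-30%). Each dual cell is then split into the 6
# Freudenthal (Kuhn) tetrahedra, within which the interpolated field is
# linear, so the 0.5 level set is an exact plane cutting tetrahedron edges at
# linearly interpolated points. The Kuhn triangulation tiles space
# consistently, so the surface is closed. Area accumulates the cut polygons;
# enclosed volume accumulates full inside tetrahedra plus the exact volume of
# each clipped (convex) piece, triangulated about its centroid.

# cube corner offsets, binary order (x fastest)
.cube_corners <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 1L))

# the 6 Kuhn tetrahedra as rows of corner indices (1-based into .cube_corners)
.kuhn_tets <- rbind(
  c(1L, 2L, 4L, 8L),  # x, y, z
  c(1L, 2L, 6L, 8L),  # x, z, y
  c(1L, 3L, 4L, 8L),  # y, x, z
  c(1L, 3L, 7L, 8L),  # y, z, x
  c(1L, 5L, 6L, 8L),  # z, x, y
  c(1L, 5L, 7L, 8L))  # z, y, x

# vectorised triangle areas for n x 3 coordinate matrices
.tri_area <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# scalar triple products u . (v x w) for n x 3 matrices
.vec_det <- function(u, v, w) {
  u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
    u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
    u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])
}

# mesh volume (mm^3) and surface area (mm^2) of a binary mask
mesh_mask <- function(mask, voxel_size) {
  d <- dim(mask)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (mask != 0) * 1
  pd <- dim(pad)
  # dual-lattice field: 2x2x2 box average of the padded mask
  nf <- pd - 1L
  field <- array(0, dim = nf)
  for (ci in seq_len(8L)) {
    off <- .cube_corners[ci, ]
    field <- field + pad[(1:nf[1]) + off[1], (1:nf[2]) + off[2],
                         (1:nf[3]) + off[3]]
  }
  field <- field / 8

  nc <- nf - 1L  # marching cells on the dual lattice
  corner_vals <- vapply(seq_len(8L), function(ci) {
    off <- .cube_corners[ci, ]
    as.vector(field[(1:nc[1]) + off[1], (1:nc[2]) + off[2],
                    (1:nc[3]) + off[3]])
  }, numeric(prod(nc)))
  cell_idx <- arrayInd(seq_len(prod(nc)), nc)
  vs <- as.numeric(voxel_size)
  tet_vol <- prod(vs) / 6
  volume <- 0
  area <- 0
  corner_pos <- function(cells, ci) {
    sweep(cell_idx[cells, , drop = FALSE] +
            .cube_corners[rep(ci, length(cells)), , drop = FALSE],
          2L, vs, `*`)
  }
  for (t in seq_len(6L)) {
    v <- .kuhn_tets[t, ]
    val <- corner_vals[, v, drop = FALSE]
    b <- val >= 0.5
    ni <- rowSums(b)
    volume <- volume + tet_vol * sum(ni == 4L)
    mixed <- ni > 0L & ni < 4L
    if (!any(mixed)) next
    mixed_cells <- which(mixed)
    pos <- lapply(seq_len(4L), function(ci) corner_pos(mixed_cells, v[ci]))
    valm <- val[mixed_cells, , drop = FALSE]
    bm <- b[mixed_cells, , drop = FALSE]
    nim <- ni[mixed_cells]
    cut <- function(sel, ia, ib) {
      tt <- (0.5 - valm[sel, ia]) / (valm[sel, ib] - valm[sel, ia])
      pos[[ia]][sel, , drop = FALSE] +
        tt * (pos[[ib]][sel, , drop = FALSE] - pos[[ia]][sel, , drop = FALSE])
    }
    # one vertex separated from the other three: corner tetrahedron
    for (odd in seq_len(4L)) {
      others <- setdiff(seq_len(4L), odd)
      sel <- which((nim == 1L & bm[, odd]) | (nim == 3L & !bm[, odd]))
      if (length(sel) == 0L) next
      p0 <- pos[[odd]][sel, , drop = FALSE]
      m1 <- cut(sel, odd, others[1L])
      m2 <- cut(sel, odd, others[2L])
      m3 <- cut(sel, odd, others[3L])
      area <- area + sum(.tri_area(m1, m2, m3))
      corner_vol <- abs(.vec_det(m1 - p0, m2 - p0, m3 - p0)) / 6
      inside_corner <- bm[sel, odd]  # TRUE: corner piece is the inside part
      volume <- volume + sum(ifelse(inside_corner, corner_vol,
                                    tet_vol - corner_vol))
    }
    # two vertices on each side: planar cut quad, convex wedge volume
    pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                  c(2L, 3L), c(2L, 4L), c(3L, 4L))
    for (pr in pairs) {
      outs <- setdiff(seq_len(4L), pr)
      sel <- which(nim == 2L & bm[, pr[1L]] & bm[, pr[2L]])
      if (length(sel) == 0L) next
      pa <- pos[[pr[1L]]][sel, , drop = FALSE]
      pb <- pos[[pr[2L]]][sel, , drop = FALSE]
      mac <- cut(sel, pr[1L], outs[1L])
      mad <- cut(sel, pr[1L], outs[2L])
      mbc <- cut(sel, pr[2L], outs[1L])
      mbd <- cut(sel, pr[2L], outs[2L])
      area <- area + sum(.tri_area(mac, mbc, mbd)) +
        sum(.tri_area(mac, mbd, mad))
      ctr <- (pa + pb + mac + mad + mbc + mbd) / 6
      wedge <- abs(.vec_det(pa - ctr, mac - ctr, mad - ctr)) +
        abs(.vec_det(pb - ctr, mbc - ctr, mbd - ctr)) +
        abs(.vec_det(pa - ctr, pb - ctr, mbc - ctr)) +
        abs(.vec_det(pa - ctr, mbc - ctr, mac - ctr)) +
        abs(.vec_det(pa - ctr, pb - ctr, mbd - ctr)) +
        abs(.vec_det(pa - ctr, mbd - ctr, mad - ctr)) +
        abs(.vec_det(mac - ctr, mbc - ctr, mbd - ctr)) +
        abs(.vec_det(mac - ctr, mbd - ctr, mad - ctr))
      volume <- volume + sum(wedge) / 6
    }
  }
  list(volume = volume, area = area)
}

#' Shape features of a lesion mask
#'
#' Computes the 3D shape descriptors used in the repeatability analysis:
#' voxel-counting volume, mesh volume and surface area from a triangulated
#' isosurface of the mask, sphericity, elongation and major axis length from
#' principal component analysis of the voxel coordinates, and the maximum 3D
#' diameter (largest pairwise distance between surface-voxel centres). Shape
#' features depend only on the mask, never on image intensities.
#'
#' For a single-voxel mask the mesh-based and PCA-based features are undefined
#' and returned as `NA`; `shape_voxel_volume` is always returned. Masks under
#' two voxels thick along every axis carry no usable isosurface (the
#' anti-aliased field never crosses the 0.5 level) and likewise yield `NA`
#' mesh features.
#'
#' @param mask 3D 0/1 array with at least one voxel set.
#' @param voxel_size length-3 positive voxel edge lengths (mm).
#' @return Named numeric vector: `shape_voxel_volume` (mm^3),
#'   `shape_mesh_volume` (mm^3), `shape_surface_area` (mm^2),
#'   `shape_sphericity`, `shape_elongation`, `shape_major_axis_length` (mm),
#'   `shape_max_3d_diameter` (mm).
#' @export
shape_features <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  inside <- which(mask != 0)
  n <- length(inside)
  if (n < 1L) stop("mask must contain at least one voxel")
  vs <- as.numeric(voxel_size)
  voxel_volume <- n * prod(vs)
  out <- c(shape_voxel_volume = voxel_volume, shape_mesh_volume = NA_real_,
           shape_surface_area = NA_real_, shape_sphericity = NA_real_,
           shape_elongation = NA_real_, shape_major_axis_length = NA_real_,
           shape_max_3d_diameter = NA_real_)
  if (n < 2L) return(out)

  mesh <- mesh_mask(mask, vs)
  if (mesh$volume > 0 && mesh$area > 0) {
    out["shape_mesh_volume"] <- mesh$volume
    out["shape_surface_area"] <- mesh$area
    out["shape_sphericity"] <- (36 * pi * mesh$volume^2)^(1 / 3) / mesh$area
  }  # degenerate (e.g. single-voxel-thick) masks carry no usable isosurface

  coords <- sweep(arrayInd(inside, dim(mask)), 2L, vs, `*`)
  ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  if (ev[1L] > 0) {
    out["shape_major_axis_length"] <- 4 * sqrt(ev[1L])
    out["shape_elongation"] <- sqrt(ev[2L] / ev[1L])
  }

  # surface voxels: any 6-neighbour outside the mask (or outside the grid)
  d <- dim(mask)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (mask != 0) * 1L
  ai <- arrayInd(inside, d) + 1L
  nb <- c(-1L, 1L)
  neighbour_sum <- rowSums(vapply(1:3, function(ax) {
    rowSums(vapply(nb, function(s) {
      shifted <- ai
      shifted[, ax] <- shifted[, ax] + s
      pad[shifted]
    }, numeric(nrow(ai))))
  }, numeric(nrow(ai))))
  border <- coords[neighbour_sum < 6, , drop = FALSE]
  dmax <- max(stats::dist(border))
  out["shape_max_3d_diameter"] <- dmax
  out
}
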