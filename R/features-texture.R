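# 3D texture matrices over a discretised ROI. Grey levels are integers
# 1..n_levels inside the mask and NA outside; out-of-ROI neighbours are
# ignored everywhere. GLCM and GLRLM use the 13 unique direction pairs at
# distance 1; GLSZM, GLDM and NGTDM use the 26-connected neighbourhood.

# the 13 unique 3D directions (each paired with its negation for symmetry)
.directions13 <- rbind(
  c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
  c(1L, 1L, 0L), c(1L, -1L, 0L), c(1L, 0L, 1L), c(1L, 0L, -1L),
  c(0L, 1L, 1L), c(0L, 1L, -1L),
  c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))

# all 26 neighbour offsets
.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(g == 0L) < 3L, , drop = FALSE]
})

# values of levels at position + offset, NA where the shift leaves the grid
.shift_levels <- function(levels, off) {
  d <- dim(levels)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    ifelse(i >= 1L & i <= d[ax], i, NA_integer_)
  })
  out <- array(NA_integer_, dim = d)
  okx <- !is.na(src[[1L]]); oky <- !is.na(src[[2L]]); okz <- !is.na(src[[3L]])
  out[okx, oky, okz] <- levels[src[[1L]][okx], src[[2L]][oky], src[[3L]][okz]]
  out
}

#' Texture matrices of a discretised ROI
#'
#' Builds the five standard 3D texture-matrix families from an integer
#' grey-level array (as produced by [discretise()]): the symmetric grey-level
#' co-occurrence matrix (GLCM) and the grey-level run-length matrix (GLRLM)
#' for each of the 13 unique directions at distance 1; and the size-zone
#' (GLSZM), dependence (GLDM, dependence threshold alpha = 0) and neighbouring
#' grey-tone difference (NGTDM) matrices with 26-connected neighbourhoods.
#'
#' @param levels 3D integer array of grey levels in `1..n_levels`, NA outside
#'   the ROI.
#' @param n_levels number of grey levels, >= 1.
#' @return A `texture_matrix_set`: list with `glcm` and `glrlm` (lists of 13
#'   count matrices, levels x levels and levels x max-run respectively),
#'   `glszm` (levels x max-zone counts), `gldm` (levels x (max dependence + 1)
#'   counts, column j = dependence j - 1), and `ngtdm` (list with per-level
#'   sums `s`, counts `n`, probabilities `p`, and `n_vp`), plus `n_levels` and
#'   `directions`.
#' @export
texture_matrices <- function(levels, n_levels) {
  stopifnot(length(dim(levels)) == 3L)
  if (n_levels < 1L) stop("n_levels must be at least 1")
  n_levels <- as.integer(n_levels)
  inside <- !is.na(levels)
  if (!any(inside)) stop("ROI is empty")
  if (any(levels[inside] < 1L | levels[inside] > n_levels)) {
    stop("grey levels must lie in 1..n_levels")
  }
  d <- dim(levels)
  n_dir <- nrow(.directions13)

  ## GLCM: co-occurrences at distance 1, symmetrised per direction
  glcm <- vector("list", n_dir)
  for (k in seq_len(n_dir)) {
    nb <- .shift_levels(levels, .directions13[k, ])
    ok <- inside & !is.na(nb)
    m <- matrix(0, n_levels, n_levels)
    if (any(ok)) {
      tab <- table(factor(levels[ok], levels = 1:n_levels),
                   factor(nb[ok], levels = 1:n_levels))
      m <- unclass(tab) + t(unclass(tab))
      dimnames(m) <- NULL
    }
    glcm[[k]] <- m
  }

  ## GLRLM: maximal runs of equal level along each direction; gaps in the ROI
  ## (NA voxels) break runs
  max_dim <- max(d)
  glrlm <- vector("list", n_dir)
  for (k in seq_len(n_dir)) {
    off <- .directions13[k, ]
    m <- matrix(0, n_levels, max_dim)
    # line starts: positions whose predecessor along -off is outside the grid
    idx <- arrayInd(seq_len(prod(d)), d)
    prev <- sweep(idx, 2L, off, `-`)
    is_start <- prev[, 1L] < 1L | prev[, 1L] > d[1L] |
      prev[, 2L] < 1L | prev[, 2L] > d[2L] |
      prev[, 3L] < 1L | prev[, 3L] > d[3L]
    starts <- idx[is_start, , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      p <- starts[s, ]
      run_level <- NA_integer_
      run_len <- 0L
      while (all(p >= 1L) && all(p <= d)) {
        v <- levels[p[1L], p[2L], p[3L]]
        if (!is.na(v) && !is.na(run_level) && v == run_level) {
          run_len <- run_len + 1L
        } else {
          if (run_len > 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
          run_level <- v
          run_len <- if (is.na(v)) 0L else 1L
        }
        p <- p + off
      }
      if (run_len > 0L) m[run_level, run_len] <- m[run_level, run_len] + 1
    }
    glrlm[[k]] <- m[, seq_len(max(1L, max(which(colSums(m) > 0), 1L))),
                    drop = FALSE]
  }

  ## GLSZM: 26-connected zones of constant grey level
  lin_off <- .offsets26[, 1L] + d[1L] * .offsets26[, 2L] +
    d[1L] * d[2L] * .offsets26[, 3L]
  visited <- array(FALSE, dim = d)
  zone_sizes <- list()
  roi_idx <- which(inside)
  coords <- arrayInd(roi_idx, d)
  for (ii in seq_along(roi_idx)) {
    v0 <- roi_idx[ii]
    if (visited[v0]) next
    lev <- levels[v0]
    queue <- v0
    visited[v0] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      ci <- arrayInd(cur, d)[1L, ]
      for (o in seq_len(nrow(.offsets26))) {
        nc <- ci + .offsets26[o, ]
        if (any(nc < 1L) || any(nc > d)) next
        ni <- nc[1L] + d[1L] * (nc[2L] - 1L) + d[1L] * d[2L] * (nc[3L] - 1L)
        if (!visited[ni] && !is.na(levels[ni]) && levels[ni] == lev) {
          visited[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
    zone_sizes[[length(zone_sizes) + 1L]] <- c(lev, size)
  }
  zs <- do.call(rbind, zone_sizes)
  glszm <- matrix(0, n_levels, max(zs[, 2L]))
  for (r in seq_len(nrow(zs))) {
    glszm[zs[r, 1L], zs[r, 2L]] <- glszm[zs[r, 1L], zs[r, 2L]] + 1
  }

  ## GLDM (alpha = 0): dependence = number of 26-neighbours in the ROI with
  ## the same grey level
  dep <- array(0L, dim = d)
  for (o in seq_len(nrow(.offsets26))) {
    nb <- .shift_levels(levels, .offsets26[o, ])
    dep <- dep + (inside & !is.na(nb) & nb == levels)
  }
  dep_in <- dep[inside]
  lev_in <- levels[inside]
  gldm <- matrix(0, n_levels, max(dep_in) + 1L)
  for (r in seq_along(dep_in)) {
    gldm[lev_in[r], dep_in[r] + 1L] <- gldm[lev_in[r], dep_in[r] + 1L] + 1
  }

  ## NGTDM: per-level counts and absolute differences from the mean of the
  ## in-ROI 26-neighbours
  nb_sum <- array(0, dim = d)
  nb_cnt <- array(0L, dim = d)
  for (o in seq_len(nrow(.offsets26))) {
    nb <- .shift_levels(levels, .offsets26[o, ])
    has <- !is.na(nb)
    nb_sum[has] <- nb_sum[has] + nb[has]
    nb_cnt <- nb_cnt + has
  }
  eligible <- inside & nb_cnt > 0L
  avg <- nb_sum[eligible] / nb_cnt[eligible]
  lev_e <- levels[eligible]
  s <- numeric(n_levels)
  n_i <- integer(n_levels)
  for (g in seq_len(n_levels)) {
    sel <- lev_e == g
    n_i[g] <- sum(sel)
    s[g] <- sum(abs(g - avg[sel]))
  }
  n_vp <- sum(n_i)
  ngtdm <- list(s = s, n = n_i, p = n_i / n_vp, n_vp = n_vp)

  structure(list(glcm = glcm, glrlm = glrlm, glszm = glszm, gldm = gldm,
                 ngtdm = ngtdm, n_levels = n_levels,
                 directions = .directions13),
            class = "texture_matrix_set")
}

# per-direction feature averaged over the 13 directions, skipping directions
# with an empty matrix
.mean_over_directions <- function(mats, fun) {
  vals <- vapply(mats, function(m) {
    if (sum(m) == 0) return(NA_real_)
    fun(m)
  }, numeric(1L))
  mean(vals, na.rm = TRUE)
}

#' Texture features from a texture-matrix set
#'
#' Evaluates the texture features analysed in the repeatability study from
#' precomputed matrices: GLCM inverse difference moment and cluster shade;
#' GLRLM grey-level and run-length non-uniformity; GLSZM small area emphasis,
#' size-zone non-uniformity (plain and normalised), grey-level non-uniformity
#' and large area low grey level emphasis; GLDM dependence and grey-level
#' non-uniformity; and NGTDM coarseness. Per-direction features (GLCM, GLRLM)
#' are averaged over the 13 directions. Coarseness is capped at 1e6 for a
#' perfectly homogeneous ROI (all s_i = 0).
#'
#' @param tm a [texture_matrices()] result.
#' @return Named numeric vector (features of an empty matrix are `NA`).
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix_set"))

  glcm_feat <- function(fun) .mean_over_directions(tm$glcm, fun)
  idm <- glcm_feat(function(m) {
    p <- m / sum(m)
    i <- row(p); j <- col(p)
    sum(p / (1 + (i - j)^2))
  })
  cluster_shade <- glcm_feat(function(m) {
    p <- m / sum(m)
    i <- row(p); j <- col(p)
    mu_x <- sum(i * p); mu_y <- sum(j * p)
    sum((i + j - mu_x - mu_y)^3 * p)
  })

  glrlm_feat <- function(fun) .mean_over_directions(tm$glrlm, fun)
  glrlm_gln <- glrlm_feat(function(m) sum(rowSums(m)^2) / sum(m))
  glrlm_rln <- glrlm_feat(function(m) sum(colSums(m)^2) / sum(m))

  z <- tm$glszm
  nz <- sum(z)
  if (nz > 0) {
    jz <- col(z); iz <- row(z)
    glszm_sae <- sum(z / jz^2) / nz
    glszm_szn <- sum(colSums(z)^2) / nz
    glszm_sznn <- glszm_szn / nz
    glszm_gln <- sum(rowSums(z)^2) / nz
    glszm_lalgle <- sum(z * jz^2 / iz^2) / nz
  } else {
    glszm_sae <- glszm_szn <- glszm_sznn <- glszm_gln <-
      glszm_lalgle <- NA_real_
  }

  dm <- tm$gldm
  nd <- sum(dm)
  gldm_dn <- if (nd > 0) sum(colSums(dm)^2) / nd else NA_real_
  gldm_gln <- if (nd > 0) sum(rowSums(dm)^2) / nd else NA_real_

  ng <- tm$ngtdm
  denom <- sum(ng$p * ng$s)
  coarseness <- if (ng$n_vp > 0) {
    if (denom > 0) min(1 / denom, 1e6) else 1e6
  } else NA_real_

  c(glcm_idm = idm,
    glcm_cluster_shade = cluster_shade,
    glrlm_gln = glrlm_gln,
    glrlm_rln = glrlm_rln,
    glszm_sae = glszm_sae,
    glszm_szn = glszm_szn,
    glszm_sznn = glszm_sznn,
    glszm_gln = glszm_gln,
    glszm_lalgle = glszm_lalgle,
    gldm_dn = gldm_dn,
    gldm_gln = gldm_gln,
    ngtdm_coarseness = coarseness)
}

#' Extract the full radiomic feature vector of one lesion
#'
#' Runs the extraction pipeline for a single ROI: optional linear intensity
#' normalisation ([normalise_image()]), fixed-bin-width discretisation
#' ([discretise()]), then shape, first-order, and texture features. Shape
#' features use only the mask; first-order features use the (possibly
#' normalised) continuous intensities; texture features use the discretised
#' grey levels.
#'
#' @param image 3D numeric array.
#' @param mask 3D 0/1 array.
#' @param voxel_size length-3 voxel edge lengths (mm).
#' @param bin_width discretisation bin width (intensity units), default 5.
#' @param normalise apply [normalise_image()] first (default `FALSE`).
#' @return Named numeric feature vector; attribute `n_bins` records the
#'   number of grey levels used for the texture matrices.
#' @export
extract_features <- function(image, mask, voxel_size = c(1, 1, 1),
                             bin_width = 5, normalise = FALSE) {
  img <- roi_image(image, mask, voxel_size)
  if (normalise) img <- normalise_image(img)
  disc <- discretise(img, bin_width = bin_width)
  tm <- texture_matrices(disc$levels, disc$n_bins)
  out <- c(shape_features(img$mask, voxel_size),
           first_order_features(img$image[img$mask == 1L],
                                voxel_volume = prod(voxel_size)),
           texture_features(tm))
  attr(out, "n_bins") <- disc$n_bins
  out
}
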