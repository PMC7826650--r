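# Independent brute-force oracles used across the test files. These are
# deliberately written as plain exhaustive loops over voxels/neighbours,
# sharing no code with the package internals.

.all_offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(g == 0L) < 3L, , drop = FALSE]
})

in_grid <- function(p, d) all(p >= 1L) && all(p <= d)

lin_index <- function(p, d) p[1L] + d[1L] * (p[2L] - 1L) + d[1L] * d[2L] * (p[3L] - 1L)

# symmetric co-occurrence counts for one direction
bf_glcm <- function(lev, n_levels, dir) {
  d <- dim(lev)
  m <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    q <- c(i, j, k) + dir
    if (!in_grid(q, d)) next
    b <- lev[q[1L], q[2L], q[3L]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# run-length counts for one direction; out-of-ROI voxels break runs
bf_glrlm <- function(lev, n_levels, dir) {
  d <- dim(lev)
  m <- matrix(0, n_levels, max(d))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    prev <- c(i, j, k) - dir
    if (in_grid(prev, d)) {
      pv <- lev[prev[1L], prev[2L], prev[3L]]
      if (!is.na(pv) && pv == a) next  # not a run start
    }
    len <- 0L
    p <- c(i, j, k)
    while (in_grid(p, d) && !is.na(lev[p[1L], p[2L], p[3L]]) &&
           lev[p[1L], p[2L], p[3L]] == a) {
      len <- len + 1L
      p <- p + dir
    }
    m[a, len] <- m[a, len] + 1
  }
  m[, seq_len(max(which(colSums(m) > 0))), drop = FALSE]
}

# 26-connected constant-level zones by iterative frontier expansion
bf_glszm <- function(lev, n_levels) {
  d <- dim(lev)
  visited <- array(FALSE, dim = d)
  zones <- list()
  for (start in which(!is.na(lev))) {
    if (visited[start]) next
    lv <- lev[start]
    visited[start] <- TRUE
    members <- start
    frontier <- start
    while (length(frontier) > 0L) {
      grown <- integer(0L)
      for (f in frontier) {
        cf <- arrayInd(f, d)[1L, ]
        for (r in seq_len(nrow(.all_offsets26))) {
          nb <- cf + .all_offsets26[r, ]
          if (!in_grid(nb, d)) next
          li <- lin_index(nb, d)
          if (!visited[li] && !is.na(lev[li]) && lev[li] == lv) {
            visited[li] <- TRUE
            grown <- c(grown, li)
          }
        }
      }
      members <- c(members, grown)
      frontier <- grown
    }
    zones[[length(zones) + 1L]] <- c(lv, length(members))
  }
  zs <- do.call(rbind, zones)
  m <- matrix(0, n_levels, max(zs[, 2L]))
  for (r in seq_len(nrow(zs))) m[zs[r, 1L], zs[r, 2L]] <- m[zs[r, 1L], zs[r, 2L]] + 1
  m
}

# dependence counts (alpha = 0): same-level 26-neighbours per voxel
bf_gldm <- function(lev, n_levels) {
  d <- dim(lev)
  recs <- list()
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    dep <- 0L
    for (r in seq_len(nrow(.all_offsets26))) {
      nb <- c(i, j, k) + .all_offsets26[r, ]
      if (!in_grid(nb, d)) next
      b <- lev[nb[1L], nb[2L], nb[3L]]
      if (!is.na(b) && b == a) dep <- dep + 1L
    }
    recs[[length(recs) + 1L]] <- c(a, dep)
  }
  rs <- do.call(rbind, recs)
  m <- matrix(0, n_levels, max(rs[, 2L]) + 1L)
  for (r in seq_len(nrow(rs))) {
    m[rs[r, 1L], rs[r, 2L] + 1L] <- m[rs[r, 1L], rs[r, 2L] + 1L] + 1
  }
  m
}

# per-level neighbourhood grey-tone difference sums and counts
bf_ngtdm <- function(lev, n_levels) {
  d <- dim(lev)
  s <- numeric(n_levels)
  n <- integer(n_levels)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    nbs <- c()
    for (r in seq_len(nrow(.all_offsets26))) {
      nb <- c(i, j, k) + .all_offsets26[r, ]
      if (!in_grid(nb, d)) next
      b <- lev[nb[1L], nb[2L], nb[3L]]
      if (!is.na(b)) nbs <- c(nbs, b)
    }
    if (length(nbs) == 0L) next
    n[a] <- n[a] + 1L
    s[a] <- s[a] + abs(a - mean(nbs))
  }
  list(s = s, n = n, p = n / sum(n), n_vp = sum(n))
}

# one-way ANOVA ICC via R's aov() decomposition - independent of the
# package's mean-square code path
bf_icc_aov <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(y ~ subj, data = df))[[1L]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# random labelled ROI with an irregular mask
gen_roi <- function(dim3 = c(4L, 4L, 4L), n_levels = 3L, p_mask = 0.8,
                    seed = 1L) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dim3), replace = TRUE), dim = dim3)
  mask <- array(stats::runif(prod(dim3)) < p_mask, dim = dim3)
  if (!any(mask)) mask[1L] <- TRUE
  lev[!mask] <- NA_integer_
  lev
}

# directions the texture code must cover: first non-zero component positive
dirs13 <- rbind(
  c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
  c(1L, 1L, 0L), c(1L, -1L, 0L), c(1L, 0L, 1L), c(1L, 0L, -1L),
  c(0L, 1L, 1L), c(0L, 1L, -1L),
  c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
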