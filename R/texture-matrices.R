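# Construction of the grey-level texture matrices on a 3D level grid.
#
# Conventions (IBSI 3D aggregation, simplest sanctioned scheme):
#  * GLCM and GLRLM are merged over the 13 unique 3D directions into a
#    single matrix (GLCM symmetric).
#  * GLSZM zones are 26-connected components of equal-level ROI voxels;
#    GLDZM reuses the same zones with zone distance = minimum over zone
#    voxels of the 6-connected city-block distance to the ROI border
#    (border voxels have distance 1).
#  * NGTDM/NGLDM use the full 26-neighbourhood restricted to ROI voxels;
#    NGLDM coarseness parameter alpha = 0 and dependence index j = k + 1
#    where k is the number of neighbours sharing the centre level.

# the 13 unique direction vectors of a 3D grid (one per axis pair)
directions13 <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# source/target index ranges for an offset d within dims
offset_ranges <- function(dims, d) {
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) {
    len <- dims[a] - abs(d[a])
    if (len <= 0) return(NULL)
    src[[a]] <- if (d[a] >= 0) seq_len(len) else seq_len(len) + abs(d[a])
    dst[[a]] <- src[[a]] + d[a]
  }
  list(src = src, dst = dst)
}

# crop the level grid to the mask bounding box; NA outside the mask
level_bbox <- function(level_grid, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  L <- array(NA_integer_, dim = rng[2, ] - rng[1, ] + 1L)
  sel <- sweep(idx, 2, rng[1, ] - 1L)
  L[sel] <- level_grid[idx]
  L
}

glcm_matrix <- function(L, Ng) {
  dims <- dim(L)
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(directions13()))) {
    d <- directions13()[r, ]
    rg <- offset_ranges(dims, d)
    if (is.null(rg)) next
    a <- L[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    b <- L[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]
    tab <- tabulate((ai - 1L) * Ng + bi, nbins = Ng * Ng)
    m <- matrix(tab, Ng, Ng, byrow = TRUE)
    counts <- counts + m + t(m)  # symmetric: count both orderings
  }
  counts
}

glrlm_matrix <- function(L, Ng) {
  dims <- dim(L)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  lv <- as.vector(L)  # column-major matches expand.grid order
  max_run <- max(dims)
  counts <- matrix(0, Ng, max_run)
  dirs <- directions13()
  big <- Ng + 1L
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    j <- which(d != 0)[1]
    t_along <- coords[, j] * d[j]
    # line key: start-of-line coordinates, constant along the direction
    k1 <- coords[, 1] - t_along * d[1]
    k2 <- coords[, 2] - t_along * d[2]
    k3 <- coords[, 3] - t_along * d[3]
    off <- max(dims) + 1L
    keycode <- (k1 + off) + (k2 + off) * (4L * off) + (k3 + off) * (16L * off^2)
    ord <- order(keycode, t_along)
    lvo <- lv[ord]
    w <- keycode[ord] * big + lvo
    nas <- is.na(lvo)
    w[nas] <- -seq_len(sum(nas))  # each masked-out cell breaks runs uniquely
    rl <- rle(w)
    keep <- rl$values > 0
    if (!any(keep)) next
    run_lv <- rl$values[keep] %% big
    run_ln <- rl$lengths[keep]
    idx <- (run_ln - 1L) * Ng + run_lv
    tab <- tabulate(idx, nbins = Ng * max_run)
    counts <- counts + matrix(tab, Ng, max_run)
  }
  # trim trailing all-zero run-length columns
  nz <- which(colSums(counts) > 0)
  counts[, seq_len(max(nz, 1L)), drop = FALSE]
}

# 26-connected equal-level zones; returns list(level, size, voxels) per zone
glszm_zones <- function(L) {
  dims <- dim(L)
  in_mask <- which(!is.na(L))
  n <- length(in_mask)
  vid <- array(NA_integer_, dim = dims)
  vid[in_mask] <- seq_len(n)
  dirs <- directions13()
  edges <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    rg <- offset_ranges(dims, d)
    if (is.null(rg)) next
    a <- L[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    b <- L[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]]
    ia <- vid[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    ib <- vid[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok)) edges[[r]] <- cbind(ia[ok], ib[ok])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  lv <- L[in_mask]
  lapply(seq_len(comp$no), function(k) {
    vox <- which(comp$membership == k)
    list(level = lv[vox[1]], size = length(vox), cells = in_mask[vox])
  })
}

zones_to_glszm <- function(zones, Ng) {
  sizes <- vapply(zones, `[[`, integer(1), "size")
  levels <- vapply(zones, `[[`, integer(1), "level")
  smat <- matrix(0, Ng, max(sizes))
  for (k in seq_along(zones))
    smat[levels[k], sizes[k]] <- smat[levels[k], sizes[k]] + 1
  smat
}

# city-block (6-connected) distance-to-border map; border voxels = 1
distance_map <- function(L) {
  dims <- dim(L)
  mask <- !is.na(L)
  dm <- array(Inf, dim = dims)
  dm[!mask] <- NA_real_
  # neighbour-outside test via 6 shifts; grid edge counts as outside
  shifts6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  neighbour_min <- function() {
    nm <- array(Inf, dim = dims)
    for (r in seq_len(6)) {
      d <- shifts6[r, ]
      rg <- offset_ranges(dims, d)
      if (is.null(rg)) next
      shifted <- array(Inf, dim = dims)
      shifted[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        dm[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      nm <- pmin(nm, shifted, na.rm = FALSE)
    }
    nm
  }
  # border voxels: any 6-neighbour outside the mask or outside the grid
  border <- array(FALSE, dim = dims)
  for (r in seq_len(6)) {
    d <- shifts6[r, ]
    rg <- offset_ranges(dims, d)
    nb_inside <- array(FALSE, dim = dims)
    if (!is.null(rg))
      nb_inside[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        mask[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
    border <- border | (mask & !nb_inside)
  }
  dm[border] <- 1
  while (any(is.infinite(dm[mask]))) {
    nm <- neighbour_min()
    upd <- mask & is.infinite(dm) & is.finite(nm)
    if (!any(upd)) break
    dm[upd] <- nm[upd] + 1
  }
  dm
}

zones_to_gldzm <- function(zones, dm, Ng) {
  zdist <- vapply(zones, function(z) min(dm[z$cells]), numeric(1))
  zdist <- as.integer(zdist)
  levels <- vapply(zones, `[[`, integer(1), "level")
  dmat <- matrix(0, Ng, max(zdist))
  for (k in seq_along(zones))
    dmat[levels[k], zdist[k]] <- dmat[levels[k], zdist[k]] + 1
  dmat
}

# neighbourhood sums/counts over the 26-neighbourhood, ROI voxels only
neighbour26 <- function(L) {
  dims <- dim(L)
  nsum <- array(0, dim = dims)
  ncnt <- array(0L, dim = dims)
  dirs <- directions13()
  Lz <- L; Lz[is.na(Lz)] <- 0L
  inm <- !is.na(L)
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- dirs[r, ] * sgn
      rg <- offset_ranges(dims, d)
      if (is.null(rg)) next
      add <- array(0, dim = dims)
      addc <- array(0L, dim = dims)
      add[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        Lz[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      addc[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        inm[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      nsum <- nsum + add * addc
      ncnt <- ncnt + addc
    }
  }
  list(sum = nsum, count = ncnt)
}

ngtdm_table <- function(L, Ng) {
  nb <- neighbour26(L)
  inm <- !is.na(L)
  has_nb <- inm & nb$count > 0
  lv <- L[has_nb]
  avg <- nb$sum[has_nb] / nb$count[has_nb]
  s_i <- vapply(seq_len(Ng), function(i) sum(abs(i - avg[lv == i])), numeric(1))
  n_i <- tabulate(lv, nbins = Ng)
  list(s = s_i, n = n_i)
}

ngldm_matrix <- function(L, Ng) {
  dims <- dim(L)
  dirs <- directions13()
  same <- array(0L, dim = dims)
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- dirs[r, ] * sgn
      rg <- offset_ranges(dims, d)
      if (is.null(rg)) next
      eq <- array(0L, dim = dims)
      a <- L[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]]
      b <- L[rg$src[[1]], rg$src[[2]], rg$src[[3]]]
      eq[rg$dst[[1]], rg$dst[[2]], rg$dst[[3]]] <-
        as.integer(!is.na(a) & !is.na(b) & a == b)
      same <- same + eq
    }
  }
  inm <- !is.na(L)
  lv <- L[inm]
  dep <- same[inm] + 1L  # dependence index j = count + 1
  smat <- matrix(0, Ng, max(dep))
  tab <- tabulate((dep - 1L) * Ng + lv, nbins = Ng * max(dep))
  smat + matrix(tab, Ng, max(dep))
}

#' Build all grey-level texture matrices for a lesion
#'
#' Computes the co-occurrence, run-length, size-zone, distance-zone,
#' neighbourhood grey-tone-difference and grey-level-dependence summaries of
#' a discretized lesion, under the package's 3D aggregation conventions
#' (see the methods vignette).
#'
#' @param level_grid 3D integer array of grey levels (values outside the
#'   mask are ignored; may be `NA` there).
#' @param mask 3D logical array of the same shape marking ROI voxels.
#' @param Ng Number of grey levels; defaults to the maximum level in the
#'   mask.
#' @return A `texture_matrices` list with elements `glcm`, `glrlm`, `glszm`,
#'   `gldzm`, `ngtdm` (list with `s`, `n`), `ngldm`, plus `Ng` and `n_voxels`.
#' @export
build_texture_matrices <- function(level_grid, mask, Ng = NULL) {
  if (!any(mask)) stopf("mask is empty")
  if (!all(dim(level_grid) == dim(mask))) stopf("grid/mask shape mismatch")
  L <- level_bbox(level_grid, mask)
  Ng <- as.integer(Ng %||% max(L, na.rm = TRUE))
  zones <- glszm_zones(L)
  dm <- distance_map(L)
  structure(list(
    glcm  = glcm_matrix(L, Ng),
    glrlm = glrlm_matrix(L, Ng),
    glszm = zones_to_glszm(zones, Ng),
    gldzm = zones_to_gldzm(zones, dm, Ng),
    ngtdm = ngtdm_table(L, Ng),
    ngldm = ngldm_matrix(L, Ng),
    Ng = Ng,
    n_voxels = sum(!is.na(L))
  ), class = "texture_matrices")
}
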