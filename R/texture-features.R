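# Feature formulas over the texture matrices. Shared structure: matrices are
# normalized to probabilities; "emphasis" features weight by powers of the
# grey level i and the run/zone/dependence index j. Zero denominators give 0.

entropy2 <- function(p) { p <- p[p > 0]; if (!length(p)) 0 else -sum(p * log2(p)) }

glcm_features <- function(P) {
  Ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(setNames(rep(0, 25), paste0("cm.", c(
    "joint.max", "joint.avg", "joint.var", "joint.entr", "diff.avg",
    "diff.var", "diff.entr", "sum.avg", "sum.var", "sum.entr", "energy",
    "contrast", "dissimilarity", "inv.diff", "inv.diff.norm", "inv.diff.mom",
    "inv.diff.mom.norm", "inv.var", "corr", "auto.corr", "clust.tend",
    "clust.shade", "clust.prom", "info.corr.1", "info.corr.2"))))
  p <- P / tot
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)            # symmetric matrix: row and column means equal
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  dif <- abs(i - j)
  pd <- vapply(0:(Ng - 1), function(k) sum(p[dif == k]), numeric(1))
  kd <- 0:(Ng - 1)
  da <- sum(kd * pd)
  sm <- i + j
  ps <- vapply(2:(2 * Ng), function(k) sum(p[sm == k]), numeric(1))
  ks <- 2:(2 * Ng)
  sa <- sum(ks * ps)
  hxy <- entropy2(p)
  pxy <- px[row(p)] * px[col(p)]
  sel <- p > 0
  hxy1 <- -sum(p[sel] * log2(pxy[sel]))
  hxy2 <- entropy2(as.vector(outer(px, px)))
  hx <- entropy2(px)
  ic2_arg <- 1 - 2^(-2 * (hxy2 - hxy))
  c(
    cm.joint.max = max(p),
    cm.joint.avg = mu,
    cm.joint.var = sum((i - mu)^2 * p),
    cm.joint.entr = hxy,
    cm.diff.avg = da,
    cm.diff.var = sum((kd - da)^2 * pd),
    cm.diff.entr = entropy2(pd),
    cm.sum.avg = sa,
    cm.sum.var = sum((ks - sa)^2 * ps),
    cm.sum.entr = entropy2(ps),
    cm.energy = sum(p^2),
    cm.contrast = sum((i - j)^2 * p),
    cm.dissimilarity = sum(dif * p),
    cm.inv.diff = sum(p / (1 + dif)),
    cm.inv.diff.norm = sum(p / (1 + dif / Ng)),
    cm.inv.diff.mom = sum(p / (1 + dif^2)),
    cm.inv.diff.mom.norm = sum(p / (1 + (dif / Ng)^2)),
    cm.inv.var = sum(p[dif > 0] / dif[dif > 0]^2),
    cm.corr = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0,
    cm.auto.corr = sum(i * j * p),
    cm.clust.tend = sum((i + j - 2 * mu)^2 * p),
    cm.clust.shade = sum((i + j - 2 * mu)^3 * p),
    cm.clust.prom = sum((i + j - 2 * mu)^4 * p),
    cm.info.corr.1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    cm.info.corr.2 = sqrt(max(ic2_arg, 0)),
    use.names = TRUE
  )[1:25]
}

# shared engine for GLRLM / GLSZM / GLDZM / NGLDM style matrices:
# rows = grey level i, cols = index j (run length / zone size / distance /
# dependence count). Returns the 16 standard members; prefix supplies names.
ij_matrix_features <- function(M, n_norm, prefix, j_names, n_voxels) {
  Ng <- nrow(M); Nj <- ncol(M)
  Ns <- sum(M)
  zero <- setNames(rep(0, 16), paste0(prefix, ".", j_names))
  if (Ns == 0) return(zero)
  i <- matrix(seq_len(Ng), Ng, Nj)
  j <- matrix(seq_len(Nj), Ng, Nj, byrow = TRUE)
  p <- M / Ns
  si <- rowSums(M)
  sj <- colSums(M)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(
    sum(M / j^2) / Ns,                 # short emphasis
    sum(M * j^2) / Ns,                 # long emphasis
    sum(M / i^2) / Ns,                 # low grey level
    sum(M * i^2) / Ns,                 # high grey level
    sum(M / (i^2 * j^2)) / Ns,         # short + low
    sum(M * i^2 / j^2) / Ns,           # short + high
    sum(M * j^2 / i^2) / Ns,           # long + low
    sum(M * i^2 * j^2) / Ns,           # long + high
    sum(si^2) / Ns,                    # grey level non-uniformity
    sum(si^2) / Ns^2,                  # ... normalised
    sum(sj^2) / Ns,                    # index non-uniformity
    sum(sj^2) / Ns^2,                  # ... normalised
    Ns / n_norm,                       # percentage
    sum((i - mu_i)^2 * p),             # grey level variance
    sum((j - mu_j)^2 * p),             # index variance
    entropy2(p)                        # entropy
  )
  setNames(vals, paste0(prefix, ".", j_names))
}

glrlm_features <- function(M, n_voxels, n_dirs = 13) {
  ij_matrix_features(M, n_norm = n_voxels * n_dirs, prefix = "rlm",
    j_names = c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
                "lrhge", "glnu", "glnu.norm", "rlnu", "rlnu.norm", "r.perc",
                "gl.var", "rl.var", "rl.entr"),
    n_voxels = n_voxels)
}

glszm_features <- function(M, n_voxels) {
  ij_matrix_features(M, n_norm = n_voxels, prefix = "szm",
    j_names = c("sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge",
                "lzhge", "glnu", "glnu.norm", "zsnu", "zsnu.norm", "z.perc",
                "gl.var", "zs.var", "zs.entr"),
    n_voxels = n_voxels)
}

gldzm_features <- function(M, n_voxels) {
  ij_matrix_features(M, n_norm = n_voxels, prefix = "dzm",
    j_names = c("sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge",
                "ldhge", "glnu", "glnu.norm", "zdnu", "zdnu.norm", "z.perc",
                "gl.var", "zd.var", "zd.entr"),
    n_voxels = n_voxels)
}

ngldm_features <- function(M, n_voxels) {
  base <- ij_matrix_features(M, n_norm = n_voxels, prefix = "ngl",
    j_names = c("lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge",
                "hdhge", "glnu", "glnu.norm", "dcnu", "dcnu.norm", "dc.perc",
                "gl.var", "dc.var", "dc.entr"),
    n_voxels = n_voxels)
  p <- M / sum(M)
  c(base, ngl.dc.energy = sum(p^2))
}

ngtdm_features <- function(tab, Ng) {
  s <- tab$s; n <- tab$n
  Nv <- sum(n)
  nm <- paste0("ngt.", c("coarseness", "contrast", "busyness", "complexity",
                         "strength"))
  if (Nv == 0) return(setNames(rep(0, 5), nm))
  p <- n / Nv
  present <- which(p > 0)
  Ngp <- length(present)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6  # IBSI cap
  contrast <- if (Ngp > 1) {
    (sum(outer(p[present], p[present]) *
           outer(present, present, function(a, b) (a - b)^2)) /
       (Ngp * (Ngp - 1))) * (sum(s) / Nv)
  } else 0
  ip <- present * p[present]
  bus_den <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (bus_den > 0) sum(p * s) / bus_den else 0
  pi_ <- p[present]; si_ <- s[present]
  dif <- abs(outer(present, present, "-"))
  psum <- outer(pi_, pi_, "+")
  pssum <- outer(pi_ * si_, pi_ * si_, "+")
  complexity <- sum(dif * pssum / psum) / Nv
  strength <- if (sum(s) > 0) sum(psum * dif^2) / sum(s) else 0
  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}

#' Texture features from prebuilt matrices
#'
#' Evaluates the 95 texture features (25 co-occurrence, 16 run length,
#' 16 size zone, 16 distance zone, 5 grey tone difference, 17 grey level
#' dependence) from a [build_texture_matrices()] result. All matrices are
#' normalized by their own totals; features with zero denominators are 0.
#'
#' @param matrices A `texture_matrices` object.
#' @return Named numeric vector of length 95.
#' @export
texture_features <- function(matrices) {
  if (!inherits(matrices, "texture_matrices"))
    stopf("`matrices` must come from build_texture_matrices()")
  nv <- matrices$n_voxels
  c(glcm_features(matrices$glcm),
    glrlm_features(matrices$glrlm, nv),
    glszm_features(matrices$glszm, nv),
    gldzm_features(matrices$gldzm, nv),
    ngtdm_features(matrices$ngtdm, matrices$Ng),
    ngldm_features(matrices$ngldm, nv))
}

# ---- local intensity and mesh-free morphology ------------------------------

# voxel-centre offsets within a 1 cm^3 sphere (radius ~6.204 mm)
peak_offsets <- function(spacing) {
  r <- (3 / (4 * pi) * 1000)^(1 / 3)
  h <- pmax(floor(r / spacing), 0)
  g <- as.matrix(expand.grid(dx = -h[1]:h[1], dy = -h[2]:h[2], dz = -h[3]:h[3]))
  dd <- sqrt((g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
               (g[, 3] * spacing[3])^2)
  g[dd <= r, , drop = FALSE]
}

sphere_mean_at <- function(vol, centre, offsets) {
  dims <- dim(vol)
  pts <- sweep(offsets, 2, centre, "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  mean(vol[pts[ok, , drop = FALSE]])
}

local_intensity_features <- function(vol, mask, spacing) {
  offs <- peak_offsets(spacing)
  idx <- which(mask, arr.ind = TRUE)
  vals <- vol[mask]
  means <- vapply(seq_len(nrow(idx)), function(r)
    sphere_mean_at(vol, idx[r, ], offs), numeric(1))
  peak_local <- max(means[vals == max(vals)])  # ties: highest sphere mean
  c(loc.peak.local = peak_local, loc.peak.global = max(means))
}

morphology_features <- function(vol, mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  vol_mm <- n * prod(spacing)
  # exposed-face surface area (6-connectivity)
  dims <- dim(mask)
  area <- 0
  exposed <- rep(FALSE, n)
  shifts6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  key <- (idx[, 1]) + (idx[, 2] - 1) * dims[1] + (idx[, 3] - 1) * dims[1] * dims[2]
  for (r in seq_len(6)) {
    d <- shifts6[r, ]
    nb <- sweep(idx, 2, d, "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_in_mask <- inside
    nb_in_mask[inside] <- mask[nb[inside, , drop = FALSE]]
    face_area <- prod(spacing) / spacing[which(d != 0)]
    area <- area + sum(!nb_in_mask) * face_area
    exposed <- exposed | !nb_in_mask
  }
  comp1 <- vol_mm / (pi^0.5 * area^1.5)
  comp2 <- 36 * pi * vol_mm^2 / area^3
  sphericity <- (36 * pi * vol_mm^2)^(1 / 3) / area
  asphericity <- (area^3 / (36 * pi * vol_mm^2))^(1 / 3) - 1
  mm <- sweep(idx, 2, spacing, "*")
  com_geom <- colMeans(mm)
  w <- vol[mask]
  com_w <- if (sum(w) > 0) colSums(mm * w) / sum(w) else com_geom
  com_shift <- sqrt(sum((com_geom - com_w)^2))
  surf_mm <- mm[exposed, , drop = FALSE]
  diam <- if (nrow(surf_mm) >= 2) {
    max(stats::dist(surf_mm))
  } else 0
  c(morph.vol.vox = vol_mm, morph.area.vox = area, morph.av = area / vol_mm,
    morph.comp.1 = comp1, morph.comp.2 = comp2,
    morph.sphericity = sphericity, morph.asphericity = asphericity,
    morph.com = com_shift, morph.diam = diam)
}
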