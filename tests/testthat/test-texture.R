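test_that("size zones follow 26-connected equal-level components", {
  # 2x2x1 grid, levels [[1,1],[2,2]]: two zones of size 2
  lv <- array(c(1L, 2L, 1L, 2L), dim = c(2, 2, 1))
  mask <- array(TRUE, dim = c(2, 2, 1))
  tm <- build_texture_matrices(lv, mask)
  expect_equal(tm$glszm[1, 2], 1)
  expect_equal(tm$glszm[2, 2], 1)
  expect_equal(sum(tm$glszm), 2)  # Ns = 2

  # single-voxel ROI at level 2: one zone at border distance 1
  lv2 <- array(2L, dim = c(1, 1, 1))
  tm2 <- build_texture_matrices(lv2, array(TRUE, dim = c(1, 1, 1)), Ng = 2)
  expect_equal(tm2$gldzm[2, 1], 1)
  expect_equal(sum(tm2$gldzm), 1)  # Nd = 1
})

test_that("run-length runs match explicit enumeration on a 1x3x1 strip", {
  lv <- array(c(1L, 1L, 2L), dim = c(1, 3, 1))
  mask <- array(TRUE, dim = c(1, 3, 1))
  # along the strip: one run (1,1) of length 2 and one run (2) of length 1;
  # the 12 off-axis directions see every voxel as a length-1 run
  oracle <- oracle_glrlm(lv, mask, Ng = 2)
  tm <- build_texture_matrices(lv, mask)
  expect_equal(unname(tm$glrlm), unname(oracle))
  expect_equal(tm$glrlm[1, 2], 1)          # the only length-2 run
  expect_equal(ncol(tm$glrlm), 2)          # no longer runs exist
  dir_y <- matrix(c(0L, 1L, 0L), 1)
  single <- oracle_glrlm(lv, mask, Ng = 2, dirs = dir_y)
  expect_equal(single[1, 2], 1)            # r(1,2) = 1 along the strip
  expect_equal(single[2, 1], 1)            # r(2,1) = 1
  expect_equal(sum(single), 2)
})

test_that("texture matrices equal brute-force enumeration on random grids", {
  withr::with_seed(11, {
    for (i in 1:30) {
      dims <- sample(2:5, 3, replace = TRUE)
      case <- random_level_case(dims, Ng = sample(2:4, 1))
      tm <- build_texture_matrices(case$levels, case$mask, Ng = case$Ng)
      expect_equal(unname(tm$glszm),
                   unname(oracle_glszm(case$levels, case$mask, case$Ng)),
                   info = sprintf("glszm case %d", i))
      expect_equal(unname(tm$gldzm),
                   unname(oracle_gldzm(case$levels, case$mask, case$Ng)),
                   info = sprintf("gldzm case %d", i))
      expect_equal(unname(tm$glrlm),
                   unname(oracle_glrlm(case$levels, case$mask, case$Ng)),
                   info = sprintf("glrlm case %d", i))
      expect_equal(unname(tm$glcm),
                   unname(oracle_glcm(case$levels, case$mask, case$Ng)),
                   info = sprintf("glcm case %d", i))
    }
  })
})

test_that("distance map equals the BFS oracle on irregular masks", {
  withr::with_seed(12, {
    for (i in 1:10) {
      dims <- sample(3:7, 3, replace = TRUE)
      mask <- array(runif(prod(dims)) < 0.6, dim = dims)
      if (!any(mask)) mask[1] <- TRUE
      lv <- array(1L, dim = dims)
      dm_pkg <- petrad:::distance_map(petrad:::level_bbox(lv, mask))
      # oracle works on the same bounding box
      idx <- which(mask, arr.ind = TRUE)
      rng <- apply(idx, 2, range)
      sub <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                  rng[1, 3]:rng[2, 3], drop = FALSE]
      dm_or <- oracle_distance_map(array(sub, dim = dim(sub)))
      expect_equal(dm_pkg[!is.na(dm_pkg)], dm_or[!is.na(dm_or)])
    }
  })
})

test_that("texture feature formulas evaluate the worked examples", {
  # GLSZM {s(1,2)=1, s(2,2)=1}, Ns = 2
  S <- matrix(0, 2, 2); S[1, 2] <- 1; S[2, 2] <- 1
  fs <- petrad:::glszm_features(S, n_voxels = 4)
  expect_equal(fs[["szm.lze"]], 4)
  expect_equal(fs[["szm.lzhge"]], 10)
  expect_equal(fs[["szm.glnu.norm"]], 0.5)
  expect_equal(fs[["szm.z.perc"]], 0.5)

  # GLRLM {r(1,2)=1, r(2,1)=1}, Nr = 2
  R <- matrix(0, 2, 2); R[1, 2] <- 1; R[2, 1] <- 1
  fr <- petrad:::ij_matrix_features(R, n_norm = 3 * 13, prefix = "rlm",
    j_names = c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
                "lrhge", "glnu", "glnu.norm", "rlnu", "rlnu.norm", "r.perc",
                "gl.var", "rl.var", "rl.entr"), n_voxels = 3)
  expect_equal(fr[["rlm.lrlge"]], 2.125)  # (1*4/1 + 1*1/4) / 2

  # GLDZM {d(2,1)=1}, Nd = 1
  D <- matrix(0, 2, 1); D[2, 1] <- 1
  fd <- petrad:::gldzm_features(D, n_voxels = 1)
  expect_equal(fd[["dzm.sdhge"]], 4)      # i^2 / j^2 = 4 / 1
})

test_that("co-occurrence features are coherent on a hand-checked matrix", {
  lv <- array(c(1L, 1L, 2L), dim = c(3, 1, 1))
  mask <- array(TRUE, dim = c(3, 1, 1))
  tm <- build_texture_matrices(lv, mask)
  # pairs along x: (1,1),(1,2) each counted in both orders
  expect_equal(sum(tm$glcm), 4)
  p <- tm$glcm / sum(tm$glcm)
  f <- petrad:::glcm_features(tm$glcm)
  expect_equal(f[["cm.joint.max"]], 0.5)
  expect_equal(f[["cm.contrast"]], sum(outer(1:2, 1:2, function(i, j)
    (i - j)^2) * p))
  expect_equal(f[["cm.energy"]], sum(p^2))
  # constant image: correlation degenerates to the documented 0
  lvc <- array(1L, dim = c(2, 2, 1))
  tmc <- build_texture_matrices(lvc, array(TRUE, dim = c(2, 2, 1)))
  fc <- petrad:::glcm_features(tmc$glcm)
  expect_equal(fc[["cm.corr"]], 0)
  expect_equal(fc[["cm.joint.max"]], 1)
})

test_that("neighbourhood grey tone table matches a manual computation", {
  # 1x3x1 strip [1,1,2]: neighbour averages 1, 1.5, 1
  lv <- array(c(1L, 1L, 2L), dim = c(1, 3, 1))
  tm <- build_texture_matrices(lv, array(TRUE, dim = c(1, 3, 1)))
  expect_equal(tm$ngtdm$n, c(2, 1))
  expect_equal(tm$ngtdm$s, c(abs(1 - 1) + abs(1 - 1.5), abs(2 - 1)))
})
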