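# Independent brute-force oracles used to cross-check the vectorized
# implementations. Everything here is deliberately written as plain loops
# over coordinate lists, sharing no code with the package internals.

sample_skewness <- function(x) {
  d <- x - mean(x)
  mean(d^3) / mean(d^2)^1.5
}

neighbours26 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# 26-connected equal-level zones by explicit flood fill
oracle_zones <- function(level_grid, mask) {
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  visited <- array(FALSE, dim = dims)
  nbs <- neighbours26()
  zones <- list()
  for (r in seq_len(nrow(coords))) {
    p0 <- coords[r, ]
    if (visited[matrix(p0, 1)]) next
    lev <- level_grid[matrix(p0, 1)]
    stack <- list(p0)
    visited[matrix(p0, 1)] <- TRUE
    members <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members[[length(members) + 1]] <- p
      for (k in seq_len(nrow(nbs))) {
        q <- p + nbs[k, ]
        if (!in_grid(q, dims)) next
        qm <- matrix(q, 1)
        if (mask[qm] && !visited[qm] && level_grid[qm] == lev) {
          visited[qm] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <-
      list(level = lev, size = length(members), members = members)
  }
  zones
}

oracle_glszm <- function(level_grid, mask, Ng) {
  zones <- oracle_zones(level_grid, mask)
  sizes <- vapply(zones, `[[`, numeric(1), "size")
  M <- matrix(0, Ng, max(sizes))
  for (z in zones) M[z$level, z$size] <- M[z$level, z$size] + 1
  M
}

# city-block distance to ROI border by breadth-first search (border = 1)
oracle_distance_map <- function(mask) {
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  dmap <- array(NA_real_, dim = dims)
  nbs6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  frontier <- list()
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    on_border <- FALSE
    for (k in seq_len(6)) {
      q <- p + nbs6[k, ]
      if (!in_grid(q, dims) || !mask[matrix(q, 1)]) { on_border <- TRUE; break }
    }
    if (on_border) {
      dmap[matrix(p, 1)] <- 1
      frontier[[length(frontier) + 1]] <- p
    }
  }
  d <- 1
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (k in seq_len(6)) {
        q <- p + nbs6[k, ]
        if (!in_grid(q, dims)) next
        qm <- matrix(q, 1)
        if (mask[qm] && is.na(dmap[qm])) {
          dmap[qm] <- d + 1
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    frontier <- nxt
    d <- d + 1
  }
  dmap
}

oracle_gldzm <- function(level_grid, mask, Ng) {
  zones <- oracle_zones(level_grid, mask)
  dmap <- oracle_distance_map(mask)
  dists <- vapply(zones, function(z)
    min(vapply(z$members, function(p) dmap[matrix(p, 1)], numeric(1))),
    numeric(1))
  M <- matrix(0, Ng, max(dists))
  for (i in seq_along(zones))
    M[zones[[i]]$level, dists[i]] <- M[zones[[i]]$level, dists[i]] + 1
  M
}

oracle_directions <- function() {
  d <- neighbours26()
  keep <- logical(nrow(d))
  for (r in seq_len(nrow(d))) {
    nz <- d[r, ][d[r, ] != 0]
    keep[r] <- nz[1] > 0
  }
  d[keep, , drop = FALSE]
}

# run enumeration: walk each direction from run-starting voxels
oracle_glrlm <- function(level_grid, mask, Ng, dirs = oracle_directions()) {
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  M <- matrix(0, Ng, max(dims))
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    for (i in seq_len(nrow(coords))) {
      p <- coords[i, ]
      lev <- level_grid[matrix(p, 1)]
      prev <- p - d
      starts <- !in_grid(prev, dims) || !mask[matrix(prev, 1)] ||
        level_grid[matrix(prev, 1)] != lev
      if (!starts) next
      len <- 1
      q <- p + d
      while (in_grid(q, dims) && mask[matrix(q, 1)] &&
             level_grid[matrix(q, 1)] == lev) {
        len <- len + 1
        q <- q + d
      }
      M[lev, len] <- M[lev, len] + 1
    }
  }
  nz <- which(colSums(M) > 0)
  M[, seq_len(max(nz, 1)), drop = FALSE]
}

# co-occurrence counts, symmetric, merged over the 13 directions
oracle_glcm <- function(level_grid, mask, Ng) {
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  M <- matrix(0, Ng, Ng)
  dirs <- oracle_directions()
  for (r in seq_len(nrow(dirs))) {
    for (sgn in c(1, -1)) {
      d <- dirs[r, ] * sgn
      for (i in seq_len(nrow(coords))) {
        p <- coords[i, ]
        q <- p + d
        if (!in_grid(q, dims) || !mask[matrix(q, 1)]) next
        a <- level_grid[matrix(p, 1)]
        b <- level_grid[matrix(q, 1)]
        M[a, b] <- M[a, b] + 1
      }
    }
  }
  M
}

# O(n^2) Tomek-link borderline score
oracle_tomek <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    s <- sd(X[, j])
    X[, j] <- if (s == 0) 0 else (X[, j] - mean(X[, j])) / s
  }
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; arg <- NA_integer_
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (dd < best) { best <- dd; arg <- j }
    }
    nn[i] <- arg
  }
  linked <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && y[i] != y[j]) linked[c(i, j)] <- TRUE
  }
  mean(linked)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  u_of <- function(ia) {
    av <- pool[ia]; bv <- pool[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(na + nb, na), 2, u_of)
  p1 <- if (u_obs > na * nb / 2) mean(all_u >= u_obs) else mean(all_u <= u_obs)
  min(2 * p1, 1)
}

# random level grid + mask for texture cross-checks
random_level_case <- function(dims, Ng, p_mask = 0.7) {
  mask <- array(runif(prod(dims)) < p_mask, dim = dims)
  if (!any(mask)) mask[1] <- TRUE
  lv <- array(sample.int(Ng, prod(dims), replace = TRUE), dim = dims)
  list(levels = lv, mask = mask, Ng = Ng)
}
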