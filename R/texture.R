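# Run-length, size-zone, dependence and gray-tone-difference texture
# families on a discretized 2D ROI. Matrix conventions follow the IBSI
# definitions: runs along the 4 unique 2D directions (features averaged
# over directions), 8-connected zones, 8-neighbour dependence counts and
# 8-neighbour gray-tone differences. Degenerate inputs (constant ROI,
# single pixel) return defined values rather than NaN.

# ---- line decomposition for run-length matrices ----

.lines_for_direction <- function(levels, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  switch(direction,
    horizontal = lapply(seq_len(nr), function(r) levels[r, ]),
    vertical = lapply(seq_len(nc), function(c) levels[, c]),
    diagonal = {
      idx <- row(levels) - col(levels)
      split(levels[order(idx, col(levels))], sort(idx))
    },
    antidiagonal = {
      idx <- row(levels) + col(levels)
      split(levels[order(idx, col(levels))], sort(idx))
    })
}

# Accumulate (gray level, run length) counts for one direction.
.glrlm_one <- function(levels, n_levels, direction) {
  lines <- .lines_for_direction(levels, direction)
  counts <- list()
  max_run <- 1L
  acc <- matrix(0, n_levels, sum(dim(levels)) + 2L)
  for (v in lines) {
    # NA (outside mask) breaks runs
    r <- rle(ifelse(is.na(v), -1L, v))
    keep <- r$values != -1L
    if (!any(keep)) next
    g <- r$values[keep]
    len <- r$lengths[keep]
    for (q in seq_along(g)) acc[g[q], len[q]] <- acc[g[q], len[q]] + 1
    max_run <- max(max_run, max(len))
  }
  acc[, seq_len(max_run), drop = FALSE]
}

.glrlm_features_one <- function(P, n_pixels) {
  if (sum(P) == 0) P <- matrix(1, 1, 1)
  nr_total <- sum(P)
  p <- P / nr_total
  i <- seq_len(nrow(P))
  r <- seq_len(ncol(P))
  pg <- rowSums(P)   # per gray level
  pl <- colSums(P)   # per run length
  mu_i <- sum(rowSums(p) * i)
  mu_r <- sum(colSums(p) * r)
  pr <- p[p > 0]
  ii <- matrix(i, nrow(P), ncol(P))
  rr <- t(matrix(r, ncol(P), nrow(P)))
  c(GrayLevelNonUniformity = sum(pg^2) / nr_total,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr_total^2,
    GrayLevelVariance = sum(p * (ii - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(P * ii^2) / nr_total,
    LongRunEmphasis = sum(P * rr^2) / nr_total,
    LongRunHighGrayLevelEmphasis = sum(P * ii^2 * rr^2) / nr_total,
    LongRunLowGrayLevelEmphasis = sum(P * rr^2 / ii^2) / nr_total,
    LowGrayLevelRunEmphasis = sum(P / ii^2) / nr_total,
    RunEntropy = -sum(pr * log2(pr)),
    RunLengthNonUniformity = sum(pl^2) / nr_total,
    RunLengthNonUniformityNormalized = sum(pl^2) / nr_total^2,
    RunPercentage = nr_total / n_pixels,
    RunVariance = sum(p * (rr - mu_r)^2),
    ShortRunEmphasis = sum(P / rr^2) / nr_total,
    ShortRunHighGrayLevelEmphasis = sum(P * ii^2 / rr^2) / nr_total,
    ShortRunLowGrayLevelEmphasis = sum(P / (ii^2 * rr^2)) / nr_total)
}

.glrlm_features <- function(droi) {
  n_pixels <- sum(droi$mask)
  dirs <- c("horizontal", "vertical", "diagonal", "antidiagonal")
  per_dir <- vapply(dirs, function(d)
    .glrlm_features_one(.glrlm_one(droi$levels, droi$n_levels, d),
                        n_pixels),
    numeric(16L))
  rowMeans(per_dir)
}

# ---- 8-connected zone labelling for the size-zone matrix ----

# Zone sizes of the TRUE pixels of a logical matrix, 8-connectivity.
.zone_sizes <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  nxt <- 0L
  idx <- which(bin)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    size <- 0L
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        p2 <- (c2 - 1L) * nr + r2
        if (bin[p2] && lab[p2] == 0L) {
          lab[p2] <- nxt
          stack <- c(stack, p2)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

.glszm_features <- function(droi) {
  n_pixels <- sum(droi$mask)
  zones <- list()
  for (g in seq_len(droi$n_levels)) {
    bin <- !is.na(droi$levels) & droi$levels == g
    if (!any(bin)) next
    sz <- .zone_sizes(bin)
    zones[[length(zones) + 1L]] <- cbind(g, sz)
  }
  z <- do.call(rbind, zones)
  i <- z[, 1L]
  s <- z[, 2L]
  nz <- nrow(z)
  tab <- table(factor(i), factor(s))
  p_iz <- tab / nz
  pg <- as.numeric(rowSums(tab))
  ps <- as.numeric(colSums(tab))
  mu_i <- mean(i)
  mu_s <- mean(s)
  pr <- as.numeric(p_iz[p_iz > 0])
  c(GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    GrayLevelVariance = mean((i - mu_i)^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    LargeAreaEmphasis = mean(s^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    SizeZoneNonUniformity = sum(ps^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    SmallAreaEmphasis = mean(1 / s^2),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    ZoneEntropy = -sum(pr * log2(pr)),
    ZonePercentage = nz / n_pixels,
    ZoneVariance = mean((s - mu_s)^2))
}

# ---- 8-neighbour helpers for gldm / ngtdm ----

# For each in-mask pixel: its level, the number of in-mask neighbours,
# the number of equal-level neighbours, and the neighbour level sum.
.neighbour_stats <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  inside <- !is.na(levels)
  n_nb <- matrix(0, nr, nc)
  eq_nb <- matrix(0, nr, nc)
  sum_nb <- matrix(0, nr, nc)
  lv0 <- ifelse(inside, levels, 0)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dc):min(nc, nc - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src, drop = FALSE]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_in <- shift(inside + 0, dr, dc)
    nb_lv <- shift(lv0, dr, dc)
    n_nb <- n_nb + nb_in
    sum_nb <- sum_nb + nb_lv
    eq_nb <- eq_nb + (nb_in == 1) * (nb_lv == levels & inside)
  }
  list(inside = inside, n_nb = n_nb, eq_nb = eq_nb, sum_nb = sum_nb)
}

.gldm_features <- function(droi) {
  st <- .neighbour_stats(droi$levels)
  inside <- st$inside
  g <- droi$levels[inside]
  # dependence = equal-level neighbours + the centre pixel itself
  j <- st$eq_nb[inside] + 1
  nz <- length(g)
  P <- table(factor(g, levels = seq_len(droi$n_levels)), factor(j))
  pg <- as.numeric(rowSums(P))
  pj <- as.numeric(colSums(P))
  p <- as.numeric(P) / nz
  pr <- p[p > 0]
  mu_i <- mean(g)
  mu_j <- mean(j)
  c(DependenceEntropy = -sum(pr * log2(pr)),
    DependenceNonUniformity = sum(pj^2) / nz,
    DependenceNonUniformityNormalized = sum(pj^2) / nz^2,
    DependenceVariance = mean((j - mu_j)^2),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelVariance = mean((g - mu_i)^2),
    HighGrayLevelEmphasis = mean(g^2),
    LargeDependenceEmphasis = mean(j^2),
    LargeDependenceHighGrayLevelEmphasis = mean(g^2 * j^2),
    LargeDependenceLowGrayLevelEmphasis = mean(j^2 / g^2),
    LowGrayLevelEmphasis = mean(1 / g^2),
    SmallDependenceEmphasis = mean(1 / j^2),
    SmallDependenceHighGrayLevelEmphasis = mean(g^2 / j^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (g^2 * j^2)))
}

.ngtdm_features <- function(droi) {
  st <- .neighbour_stats(droi$levels)
  valid <- st$inside & st$n_nb > 0
  g <- droi$levels[valid]
  a <- st$sum_nb[valid] / st$n_nb[valid]   # mean neighbour gray tone
  nvp <- length(g)
  lev <- sort(unique(g))
  n_i <- vapply(lev, function(l) sum(g == l), 0)
  s_i <- vapply(lev, function(l) sum(abs(l - a[g == l])), 0)
  p_i <- n_i / nvp
  ngp <- length(lev)

  dens <- sum(p_i * s_i)
  coarseness <- if (dens > 0) 1 / dens else 1e6

  contrast <- if (ngp > 1) {
    (sum(outer(p_i, p_i) * outer(lev, lev, "-")^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0

  # denominator sums |i p_i - j p_j| over all ordered level pairs
  busy_den <- sum(abs(outer(lev * p_i, lev * p_i, "-")))
  busyness <- if (busy_den > 0) dens / busy_den else 0

  complexity <- if (ngp > 1) {
    num <- outer(lev, lev, function(x, y) abs(x - y)) *
      (outer(p_i * s_i, p_i * s_i, "+") / outer(p_i, p_i, "+"))
    sum(num) / nvp
  } else 0

  strength <- if (sum(s_i) > 0 && ngp > 1) {
    sum(outer(p_i, p_i, "+") * outer(lev, lev, "-")^2) / sum(s_i)
  } else 0

  c(Busyness = busyness, Coarseness = coarseness,
    Complexity = complexity, Contrast = contrast, Strength = strength)
}

#' Texture-matrix features of a discretized ROI
#'
#' Dispatches to one of the four matrix families: run-length (`glrlm`,
#' 16 features, 4 directions averaged), size-zone (`glszm`, 16 features,
#' 8-connected zones), dependence (`gldm`, 14 features, 8-neighbour
#' equal-level counts) or gray-tone difference (`ngtdm`, 5 features,
#' 8-neighbour mean differences).
#'
#' @param droi a [discretize_roi()] result.
#' @param family one of `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param config unused placeholder for forward compatibility.
#' @return Named numeric vector.
#' @export
texture_matrix_features <- function(droi,
                                    family = c("glrlm", "glszm", "gldm",
                                               "ngtdm"),
                                    config = NULL) {
  stopifnot(inherits(droi, "discretized_roi"))
  family <- match.arg(family)
  switch(family,
         glrlm = .glrlm_features(droi),
         glszm = .glszm_features(droi),
         gldm = .gldm_features(droi),
         ngtdm = .ngtdm_features(droi))
}
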