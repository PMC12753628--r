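# Gray-level co-occurrence matrix features (2D, distance-d offsets along
# the 4 unique directions; per-direction normalization; features averaged
# over directions). Logarithms are base 2, matching the standard
# extractor's convention. Degenerate single-level ROIs return defined
# values (entropy 0, correlation 1) rather than NaN.

.glcm_offsets <- function(distance) {
  list(c(0L, distance), c(distance, distance),
       c(distance, 0L), c(distance, -distance))
}

# Raw co-occurrence count matrix for one offset.
.glcm_count <- function(levels, n_levels, dr, dc, symmetric) {
  nr <- nrow(levels); nc <- ncol(levels)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  m <- matrix(0, n_levels, n_levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                 factor(b[ok], levels = seq_len(n_levels)))
    m <- matrix(as.numeric(tab), n_levels, n_levels)
  }
  if (symmetric) m <- m + t(m)
  m
}

#' Gray-level co-occurrence matrices of a discretized ROI
#'
#' @param droi a [discretize_roi()] result.
#' @param distance offset distance in pixels.
#' @param symmetric count each pixel pair in both orders.
#' @return A list of per-direction normalized matrices (entries sum to 1).
#' @export
glcm_matrices <- function(droi, distance = 1L, symmetric = TRUE) {
  stopifnot(inherits(droi, "discretized_roi"))
  lapply(.glcm_offsets(as.integer(distance)), function(off) {
    m <- .glcm_count(droi$levels, droi$n_levels, off[1L], off[2L],
                     symmetric)
    s <- sum(m)
    if (s > 0) m / s else m
  })
}

# Features of one normalized co-occurrence matrix.
.glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  px <- rowSums(P)
  py <- colSums(P)
  ux <- sum(i * px)
  uy <- sum(i * py)
  sx <- sqrt(sum((i - ux)^2 * px))
  sy <- sqrt(sum((i - uy)^2 * py))

  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  psum <- vapply(2:(2 * ng), function(k) sum(P[ii + jj == k]), 0)
  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(ii - jj) == k]), 0)

  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- ent2(px)
  hy <- ent2(py)
  hxy <- ent2(as.vector(P))
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- ent2(as.vector(pxy))

  da <- sum(kd * pdiff)
  corr <- if (sx > 0 && sy > 0)
    (sum(ii * jj * P) - ux * uy) / (sx * sy) else 1

  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  # MCC: sqrt of the second-largest eigenvalue of Q.
  present <- which(px > 0)
  mcc <- if (length(present) < 2) 1 else {
    Ps <- P[present, present, drop = FALSE]
    pxs <- px[present]
    pys <- py[present]
    # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
    W <- sweep(Ps, 2L, pys, "/")
    Q <- sweep(Ps %*% t(W), 1L, pxs, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2L]))
  }

  c(Autocorrelation = sum(ii * jj * P),
    ClusterProminence = sum((ii + jj - ux - uy)^4 * P),
    ClusterShade = sum((ii + jj - ux - uy)^3 * P),
    ClusterTendency = sum((ii + jj - ux - uy)^2 * P),
    Contrast = sum((ii - jj)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent2(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(pdiff / (1 + kd)),
    Idm = sum(pdiff / (1 + kd^2)),
    Idmn = sum(pdiff / (1 + (kd / ng)^2)),
    Idn = sum(pdiff / (1 + kd / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pdiff[-1L] / kd[-1L]^2) else 0,
    JointAverage = ux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = ent2(psum),
    SumSquares = sum((ii - ux)^2 * P))
}

#' Co-occurrence features of a discretized ROI
#'
#' Computes the standard 24 features per direction and averages over the
#' 4 unique 2D directions.
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(droi, distance = 1L, symmetric = TRUE) {
  mats <- glcm_matrices(droi, distance, symmetric)
  mats <- mats[vapply(mats, function(m) sum(m) > 0, TRUE)]
  if (length(mats) == 0) {
    # single-pixel ROI: no pairs in any direction
    v <- .glcm_features_one(matrix(1, 1, 1))
    return(v)
  }
  per_dir <- vapply(mats, .glcm_features_one,
                    numeric(24L))
  rowMeans(per_dir)
}
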