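# Texture-matrix feature families. Conventions shared by all five families:
#  * gray levels are the 1..Ng output of discretize(); absent intermediate
#    levels keep their value in the formulas but carry zero probability;
#  * GLCM and GLRLM are built per direction over the 13 unique 3-D
#    neighbor directions at Chebyshev distance 1, and each feature is the
#    unweighted mean of its per-direction values (directions that produce
#    no pairs, e.g. along a singleton axis, are skipped);
#  * GLSZM zones and GLDM dependencies use 26-connectivity;
#  * machine epsilon guards every logarithm and division.

.eps <- 2.220446e-16

# ---------------------------------------------------------------------------
# GLCM
# ---------------------------------------------------------------------------

.glcm_features_one <- function(P) {
  # P: symmetric normalized co-occurrence matrix (sums to 1)
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # diagonal (i-j) and cross (i+j) marginal distributions
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  psum <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))

  HX <- -sum(px * log2(px + .eps))
  HY <- -sum(py * log2(py + .eps))
  HXY <- -sum(P * log2(P + .eps))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxy + .eps))
  HXY2 <- -sum(pxy * log2(pxy + .eps))

  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))

  da <- sum(kdiff * pdiff)

  # maximal correlation coefficient on the occupied levels
  pres <- which(px > 0)
  mcc <- if (length(pres) <= 1) 1 else {
    Pp <- P[pres, pres, drop = FALSE]
    pxp <- px[pres]; pyp <- py[pres]
    Q <- matrix(0, length(pres), length(pres))
    for (a in seq_along(pres))
      for (b in seq_along(pres))
        Q[a, b] <- sum(Pp[a, ] * Pp[b, ] / (pxp[a] * pyp + .eps))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }

  corr <- if (sigx * sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1

  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * log2(pdiff + .eps)),
    DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(P),
    SumAverage = sum(ksum * psum),
    SumEntropy = -sum(psum * log2(psum + .eps)),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc
  )
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Co-occurrence counts at distance 1 for the 13 unique 3-D directions,
#' symmetrized and normalized per direction; the 24 features are computed per
#' direction and averaged. Degenerate single-level ROIs follow fixed
#' conventions (`MCC = 1`, `ClusterShade = ClusterProminence = 0`).
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(droi) {
  counts <- cpp_glcm(droi$levels, droi$ng)
  vals <- NULL
  nd <- 0
  for (d in 1:13) {
    C <- counts[, , d, drop = TRUE]
    C <- matrix(C, droi$ng, droi$ng)
    tot <- sum(C)
    if (tot == 0) next
    f <- .glcm_features_one(C / tot)
    vals <- if (is.null(vals)) f else vals + f
    nd <- nd + 1
  }
  if (nd == 0) {
    # single-voxel ROI: act on the degenerate one-entry matrix
    P <- matrix(0, droi$ng, droi$ng)
    lv <- unique(droi$levels[droi$levels > 0])
    P[lv[1], lv[1]] <- 1
    return(.glcm_features_one(P))
  }
  vals / nd
}

# ---------------------------------------------------------------------------
# GLRLM
# ---------------------------------------------------------------------------

.glrlm_features_one <- function(P, np) {
  # P: run-length counts, rows = gray level, cols = run length
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  l <- t(matrix(seq_len(nl), nl, ng))
  p <- P / nr
  mu_i <- sum(p * i)
  mu_l <- sum(p * l)
  pg <- rowSums(P)  # per gray level
  pr <- colSums(P)  # per run length
  pnz <- p[p > 0]
  c(
    ShortRunEmphasis = sum(P / l^2) / nr,
    LongRunEmphasis = sum(P * l^2) / nr,
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (l - mu_l)^2),
    RunEntropy = -sum(pnz * log2(pnz + .eps)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * l^2) / nr
  )
}

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices over the 13 unique 3-D directions; the 16 features are
#' computed per direction and averaged.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi) {
  counts <- cpp_glrlm(droi$levels, droi$ng)
  maxrun <- dim(counts)[2]
  vals <- NULL
  nd <- 0
  for (d in 1:13) {
    P <- matrix(counts[, , d], droi$ng, maxrun)
    if (sum(P) == 0) next
    f <- .glrlm_features_one(P, droi$n_voxels)
    vals <- if (is.null(vals)) f else vals + f
    nd <- nd + 1
  }
  vals / nd
}

# ---------------------------------------------------------------------------
# GLSZM
# ---------------------------------------------------------------------------

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal gray level; a single matrix is
#' built for the whole ROI (no directionality). 16 features.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(droi) {
  z <- cpp_glszm_zones(droi$levels)
  i <- z[, 1]  # zone gray level
  s <- z[, 2]  # zone size
  nz <- nrow(z)
  np <- droi$n_voxels
  mu_i <- mean(i)
  mu_s <- mean(s)
  ni <- tapply(rep(1, nz), factor(i, levels = seq_len(droi$ng)), sum, default = 0)
  nsz <- table(s)
  key <- paste(i, s)
  pj <- as.numeric(table(key)) / nz
  c(
    SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(ni^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ni^2) / nz^2,
    SizeZoneNonUniformity = sum(as.numeric(nsz)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.numeric(nsz)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((i - mu_i)^2),
    ZoneVariance = mean((s - mu_s)^2),
    ZoneEntropy = -sum(pj * log2(pj + .eps)),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2)
  )
}

# ---------------------------------------------------------------------------
# GLDM
# ---------------------------------------------------------------------------

#' Gray-level dependence (GLDM) features
#'
#' The dependence of a voxel is 1 plus the number of its 26-neighbors inside
#' the ROI whose gray level differs by at most `alpha` (default 0). 14
#' features from the level x dependence count matrix.
#'
#' @param droi A [discretize()]d ROI.
#' @param alpha Gray-level similarity tolerance (default 0).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(droi, alpha = 0) {
  P <- cpp_gldm(droi$levels, droi$ng, as.integer(alpha))
  nz <- sum(P)
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(seq_len(ng), ng, nd)
  j <- t(matrix(seq_len(nd), nd, ng))
  p <- P / nz
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pg <- rowSums(P)
  pd <- colSums(P)
  pnz <- p[p > 0]
  c(
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(pnz * log2(pnz + .eps)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}

# ---------------------------------------------------------------------------
# NGTDM
# ---------------------------------------------------------------------------

#' Neighborhood gray-tone difference (NGTDM) features
#'
#' For every ROI voxel with at least one 26-neighbor inside the ROI, the
#' absolute difference between its level and the mean level of those
#' neighbors is accumulated per gray level (`s_i`); `p_i` is the occupancy
#' fraction. 5 features. A fully isolated ROI (no voxel has a neighbor)
#' returns the degenerate conventions `Coarseness = 1e6`, all others 0.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(droi) {
  m <- cpp_ngtdm(droi$levels, droi$ng)
  s <- m[, 1]
  n <- m[, 2]
  nvp <- sum(n)
  out <- c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0, Strength = 0)
  if (nvp == 0) return(out)
  p <- n / nvp
  pres <- which(p > 0)
  ngp <- length(pres)
  iv <- seq_len(droi$ng)

  dcoarse <- sum(p * s)
  out["Coarseness"] <- if (dcoarse > 0) min(1 / dcoarse, 1e6) else 1e6

  if (ngp > 1) {
    pi_ <- p[pres]; si <- s[pres]; ii <- iv[pres]
    ij2 <- outer(ii, ii, function(a, b) (a - b)^2)
    out["Contrast"] <- sum(outer(pi_, pi_) * ij2) / (ngp * (ngp - 1)) * sum(s) / nvp
    denom_busy <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
    out["Busyness"] <- if (denom_busy > 0) dcoarse / denom_busy else 0
    absdiff <- abs(outer(ii, ii, `-`))
    num <- outer(pi_ * si, pi_ * si, `+`) / outer(pi_, pi_, `+`)
    out["Complexity"] <- sum(absdiff * num) / nvp
    ssum <- sum(s)
    out["Strength"] <- if (ssum > 0) sum(outer(pi_, pi_, `+`) * ij2) / ssum else 0
  }
  out
}
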