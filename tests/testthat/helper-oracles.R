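# Independent naive reference implementations ("oracles") used to pin down
# the production code. Everything here is written as plain loops over voxels
# and matrix cells, kept deliberately separate from the package internals.

ORACLE_EPS <- 2.220446e-16

# one offset per +/- direction pair: first nonzero component positive
oracle_directions <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    nz <- d[d != 0]
    if (nz[1] > 0) out[[length(out) + 1]] <- d
  }
  out
}

oracle_in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_counts <- function(levels, ng, d) {
  dims <- dim(levels)
  C <- matrix(0, ng, ng)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    a <- levels[i, j, k]
    if (a == 0) next
    q <- c(i, j, k) + d
    if (!oracle_in_grid(q, dims)) next
    b <- levels[q[1], q[2], q[3]]
    if (b == 0) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  C
}

oracle_glcm_features_P <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- sqrt(sum(vapply(1:ng, function(i) (i - mux)^2 * px[i], 0)))
  sigy <- sqrt(sum(vapply(1:ng, function(i) (i - muy)^2 * py[i], 0)))
  pdiff <- numeric(ng); psum <- numeric(2 * ng - 1)  # |i-j| in 0..ng-1 ; i+j in 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
  }
  acc <- autoc <- shade <- prom <- tend <- contrast <- 0
  id <- idm <- idmn <- idn <- invvar <- ssq <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    autoc <- autoc + i * j * p
    shade <- shade + (i + j - mux - muy)^3 * p
    prom <- prom + (i + j - mux - muy)^4 * p
    tend <- tend + (i + j - mux - muy)^2 * p
    contrast <- contrast + (i - j)^2 * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + p / (i - j)^2
    ssq <- ssq + (i - mux)^2 * p
  }
  HX <- -sum(px * log2(px + ORACLE_EPS))
  HY <- -sum(py * log2(py + ORACLE_EPS))
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    HXY <- HXY - P[i, j] * log2(P[i, j] + ORACLE_EPS)
    HXY1 <- HXY1 - P[i, j] * log2(px[i] * py[j] + ORACLE_EPS)
    HXY2 <- HXY2 - px[i] * py[j] * log2(px[i] * py[j] + ORACLE_EPS)
  }
  da <- sum((0:(ng - 1)) * pdiff)
  dvar <- sum(((0:(ng - 1)) - da)^2 * pdiff)
  dent <- -sum(pdiff * log2(pdiff + ORACLE_EPS))
  sa <- sum((2:(2 * ng)) * psum)
  sent <- -sum(psum * log2(psum + ORACLE_EPS))
  pres <- which(px > 0)
  if (length(pres) <= 1) {
    mcc <- 1
  } else {
    np <- length(pres)
    Q <- matrix(0, np, np)
    for (a in seq_len(np)) for (b in seq_len(np)) {
      s <- 0
      for (kk in seq_len(np))
        s <- s + P[pres[a], pres[kk]] * P[pres[b], pres[kk]] /
          (px[pres[a]] * py[pres[kk]] + ORACLE_EPS)
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = autoc,
    JointAverage = mux,
    ClusterProminence = prom,
    ClusterShade = shade,
    ClusterTendency = tend,
    Contrast = contrast,
    Correlation = if (sigx * sigy > 0) (autoc - mux * muy) / (sigx * sigy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = dent,
    DifferenceVariance = dvar,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    Imc2 = sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0)),
    Idm = idm, Idmn = idmn, Id = id, Idn = idn,
    InverseVariance = invvar,
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = sent,
    SumSquares = ssq,
    MCC = mcc)
}

oracle_glcm_features <- function(levels, ng) {
  acc <- NULL; nd <- 0
  for (d in oracle_directions()) {
    C <- oracle_glcm_counts(levels, ng, d)
    if (sum(C) == 0) next
    f <- oracle_glcm_features_P(C / sum(C))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {
    lv <- unique(levels[levels > 0])
    P <- matrix(0, ng, ng); P[lv[1], lv[1]] <- 1
    return(oracle_glcm_features_P(P))
  }
  acc / nd
}

# ---- GLRLM -----------------------------------------------------------------

oracle_glrlm_matrix <- function(levels, ng, d) {
  dims <- dim(levels)
  P <- matrix(0, ng, max(dims))
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    v <- levels[i, j, k]
    if (v == 0) next
    p <- c(i, j, k) - d
    if (oracle_in_grid(p, dims) && levels[p[1], p[2], p[3]] == v) next
    len <- 1
    q <- c(i, j, k) + d
    while (oracle_in_grid(q, dims) && levels[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + d
    }
    P[v, len] <- P[v, len] + 1
  }
  P
}

oracle_glrlm_features_P <- function(P, np) {
  nr <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  sre <- lre <- lglre <- hglre <- srl <- srh <- lrl <- lrh <- 0
  mu_i <- mu_l <- 0
  for (i in 1:ng) for (l in 1:nl) {
    p <- P[i, l]
    sre <- sre + p / l^2; lre <- lre + p * l^2
    lglre <- lglre + p / i^2; hglre <- hglre + p * i^2
    srl <- srl + p / (i^2 * l^2); srh <- srh + p * i^2 / l^2
    lrl <- lrl + p * l^2 / i^2; lrh <- lrh + p * i^2 * l^2
    mu_i <- mu_i + p / nr * i; mu_l <- mu_l + p / nr * l
  }
  glv <- rv <- rent <- 0
  for (i in 1:ng) for (l in 1:nl) {
    p <- P[i, l] / nr
    glv <- glv + p * (i - mu_i)^2
    rv <- rv + p * (l - mu_l)^2
    if (p > 0) rent <- rent - p * log2(p + ORACLE_EPS)
  }
  c(ShortRunEmphasis = sre / nr,
    LongRunEmphasis = lre / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = glv,
    RunVariance = rv,
    RunEntropy = rent,
    LowGrayLevelRunEmphasis = lglre / nr,
    HighGrayLevelRunEmphasis = hglre / nr,
    ShortRunLowGrayLevelEmphasis = srl / nr,
    ShortRunHighGrayLevelEmphasis = srh / nr,
    LongRunLowGrayLevelEmphasis = lrl / nr,
    LongRunHighGrayLevelEmphasis = lrh / nr)
}

oracle_glrlm_features <- function(levels, ng) {
  np <- sum(levels > 0)
  acc <- NULL; nd <- 0
  for (d in oracle_directions()) {
    P <- oracle_glrlm_matrix(levels, ng, d)
    if (sum(P) == 0) next
    f <- oracle_glrlm_features_P(P, np)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- GLSZM -----------------------------------------------------------------

oracle_zones <- function(levels) {
  dims <- dim(levels)
  seen <- array(FALSE, dims)
  zones <- list()
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (seen[i, j, k] || levels[i, j, k] == 0) next
    v <- levels[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!oracle_in_grid(q, dims)) next
        if (!seen[q[1], q[2], q[3]] && levels[q[1], q[2], q[3]] == v) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(levels, ng) {
  z <- oracle_zones(levels)
  np <- sum(levels > 0)
  nz <- nrow(z)
  i <- z[, 1]; s <- z[, 2]
  ni <- numeric(ng)
  for (a in seq_len(nz)) ni[i[a]] <- ni[i[a]] + 1
  ns <- numeric(max(s))
  for (a in seq_len(nz)) ns[s[a]] <- ns[s[a]] + 1
  pj <- as.numeric(table(paste(i, s))) / nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(ni^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ni^2) / nz^2,
    SizeZoneNonUniformity = sum(ns^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ns^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((i - mean(i))^2),
    ZoneVariance = mean((s - mean(s))^2),
    ZoneEntropy = -sum(pj * log2(pj + ORACLE_EPS)),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

# ---- GLDM ------------------------------------------------------------------

oracle_gldm_features <- function(levels, ng, alpha = 0) {
  dims <- dim(levels)
  P <- matrix(0, ng, 27)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    v <- levels[i, j, k]
    if (v == 0) next
    dep <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(i + dx, j + dy, k + dz)
      if (!oracle_in_grid(q, dims)) next
      w <- levels[q[1], q[2], q[3]]
      if (w != 0 && abs(w - v) <= alpha) dep <- dep + 1
    }
    P[v, dep + 1] <- P[v, dep + 1] + 1
  }
  nz <- sum(P)
  sde <- lde <- lgle <- hgle <- sdl <- sdh <- ldl <- ldh <- 0
  mu_i <- mu_j <- 0
  for (i in 1:ng) for (j in 1:27) {
    p <- P[i, j]
    sde <- sde + p / j^2; lde <- lde + p * j^2
    lgle <- lgle + p / i^2; hgle <- hgle + p * i^2
    sdl <- sdl + p / (i^2 * j^2); sdh <- sdh + p * i^2 / j^2
    ldl <- ldl + p * j^2 / i^2; ldh <- ldh + p * i^2 * j^2
    mu_i <- mu_i + p / nz * i; mu_j <- mu_j + p / nz * j
  }
  glv <- dv <- dent <- 0
  for (i in 1:ng) for (j in 1:27) {
    p <- P[i, j] / nz
    glv <- glv + p * (i - mu_i)^2
    dv <- dv + p * (j - mu_j)^2
    if (p > 0) dent <- dent - p * log2(p + ORACLE_EPS)
  }
  c(SmallDependenceEmphasis = sde / nz,
    LargeDependenceEmphasis = lde / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = glv,
    DependenceVariance = dv,
    DependenceEntropy = dent,
    LowGrayLevelEmphasis = lgle / nz,
    HighGrayLevelEmphasis = hgle / nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / nz)
}

# ---- NGTDM -----------------------------------------------------------------

oracle_ngtdm_features <- function(levels, ng) {
  dims <- dim(levels)
  s <- numeric(ng); n <- numeric(ng)
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    v <- levels[i, j, k]
    if (v == 0) next
    acc <- 0; cnt <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(i + dx, j + dy, k + dz)
      if (!oracle_in_grid(q, dims)) next
      w <- levels[q[1], q[2], q[3]]
      if (w != 0) { acc <- acc + w; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    s[v] <- s[v] + abs(v - acc / cnt)
    n[v] <- n[v] + 1
  }
  nvp <- sum(n)
  out <- c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
           Strength = 0)
  if (nvp == 0) return(out)
  p <- n / nvp
  pres <- which(p > 0)
  dcoarse <- sum(p * s)
  out["Coarseness"] <- if (dcoarse > 0) min(1 / dcoarse, 1e6) else 1e6
  if (length(pres) > 1) {
    contr <- busy_d <- cplx <- strg <- 0
    for (a in pres) for (b in pres) {
      contr <- contr + p[a] * p[b] * (a - b)^2
      busy_d <- busy_d + abs(a * p[a] - b * p[b])
      cplx <- cplx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
      strg <- strg + (p[a] + p[b]) * (a - b)^2
    }
    ngp <- length(pres)
    out["Contrast"] <- contr / (ngp * (ngp - 1)) * sum(s) / nvp
    out["Busyness"] <- if (busy_d > 0) dcoarse / busy_d else 0
    out["Complexity"] <- cplx / nvp
    out["Strength"] <- if (sum(s) > 0) strg / sum(s) else 0
  }
  out
}

# ---- geometric metrics -----------------------------------------------------

oracle_boundary_coords <- function(mask) {
  v <- mask$voxels
  dims <- dim(v)
  out <- list()
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (v[i, j, k] == 0) next
    edge <- FALSE
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      q <- c(i, j, k) + d
      if (!oracle_in_grid(q, dims) || v[q[1], q[2], q[3]] == 0) { edge <- TRUE; break }
    }
    if (edge)
      out[[length(out) + 1]] <- (c(i, j, k) - 1) * mask$spacing + mask$origin
  }
  do.call(rbind, out)
}

oracle_surface_metrics <- function(a, b, tolerance_mm) {
  pa <- oracle_boundary_coords(a)
  pb <- oracle_boundary_coords(b)
  dmat <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb))
  dmat[dmat < 0 | is.nan(dmat)] <- 0
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  tol <- tolerance_mm + 1e-9
  list(
    sdsc = (sum(d_ab <= tol) + sum(d_ba <= tol)) / (length(d_ab) + length(d_ba)),
    hd = max(max(d_ab), max(d_ba)))
}

oracle_dice <- function(a, b) {
  2 * sum(a$voxels == 1 & b$voxels == 1) / (sum(a$voxels) + sum(b$voxels))
}

# ---- ICC -------------------------------------------------------------------

# mean squares through stats::aov rather than closed-form sums
oracle_icc_a1 <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- tab["subj", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  list(icc = icc,
       lower = n * (MSR - FL * MSE) /
         (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
       upper = n * (FU * MSR - MSE) /
         (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
}

# ---- small fixture builders ------------------------------------------------

random_levels <- function(dims, ng, fill = 1) {
  # levels array with a random ROI occupying about `fill` of the grid
  lv <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  if (fill < 1) {
    roi <- array(runif(prod(dims)) < fill, dims)
    if (!any(roi)) roi[1] <- TRUE
    lv[!roi] <- 0L
  }
  storage.mode(lv) <- "integer"
  lv
}

random_mask <- function(dims, spacing = c(1, 1, 1), p = 0.4) {
  v <- array(as.integer(runif(prod(dims)) < p), dims)
  if (sum(v) == 0) v[ceiling(prod(dims) / 2)] <- 1L
  label_mask(v, spacing)
}

# a discretized_roi-like object built from a plain level array
droi_from_levels <- function(levels) {
  structure(list(levels = levels, ng = max(levels), bin_width = 1,
                 bin_origin = 0, n_voxels = sum(levels > 0)),
            class = "discretized_roi")
}
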