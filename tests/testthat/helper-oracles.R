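# Independent brute-force oracles, written against the definitions only --
# no code shared with the package internals.

# symmetric normalised co-occurrence matrix by exhaustive voxel enumeration
oracleGLCM <- function(levels, nLevels, d) {
  dims <- dim(levels)
  M <- matrix(0, nLevels, nLevels)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      nx <- x + d[1]; ny <- y + d[2]; nz <- z + d[3]
      if (nx < 1 || nx > dims[1] || ny < 1 || ny > dims[2] ||
          nz < 1 || nz > dims[3]) next
      b <- levels[nx, ny, nz]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracleGLCMStats <- function(P) {
  n <- nrow(P)
  en <- 0; ent <- 0; idm <- 0; inert <- 0; mux <- 0; muy <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    en <- en + p^2
    if (p > 0) ent <- ent - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    inert <- inert + (i - j)^2 * p
    mux <- mux + i * p
    muy <- muy + j * p
  }
  cs <- 0; cp <- 0
  for (i in 1:n) for (j in 1:n) {
    cs <- cs + (i + j - mux - muy)^3 * P[i, j]
    cp <- cp + (i + j - mux - muy)^4 * P[i, j]
  }
  c(Energy = en, Entropy = ent, InverseDifferenceMoment = idm,
    Inertia = inert, ClusterShade = cs, ClusterProminence = cp)
}

# run counts by walking every line of the volume voxel by voxel
oracleGLRLM <- function(levels, nLevels, d) {
  dims <- dim(levels)
  runs <- list()
  inVol <- function(p) all(p >= 1) && all(p <= dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      p <- c(x, y, z)
      if (inVol(p - d)) next  # not a line start
      seqLv <- integer(0)
      while (inVol(p)) {
        v <- levels[p[1], p[2], p[3]]
        seqLv <- c(seqLv, if (is.na(v)) -1L else v)
        p <- p + d
      }
      cur <- -1L; len <- 0L
      for (v in c(seqLv, -1L)) {
        if (v == cur && v > 0) {
          len <- len + 1L
        } else {
          if (cur > 0) runs[[length(runs) + 1L]] <- c(cur, len)
          cur <- v; len <- 1L
        }
      }
    }
  if (length(runs) == 0) return(NULL)
  maxLen <- max(vapply(runs, `[`, integer(1), 2L))
  R <- matrix(0L, nLevels, maxLen)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1L
  R
}

oracleGLRLMStats <- function(R) {
  Nr <- sum(R)
  out <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, LGLRE = 0, HGLRE = 0,
           SRLGLE = 0, SRHGLE = 0, LRLGLE = 0, LRHGLE = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    out["SRE"] <- out["SRE"] + r / j^2
    out["LRE"] <- out["LRE"] + r * j^2
    out["LGLRE"] <- out["LGLRE"] + r / i^2
    out["HGLRE"] <- out["HGLRE"] + r * i^2
    out["SRLGLE"] <- out["SRLGLE"] + r / (i^2 * j^2)
    out["SRHGLE"] <- out["SRHGLE"] + r * i^2 / j^2
    out["LRLGLE"] <- out["LRLGLE"] + r * j^2 / i^2
    out["LRHGLE"] <- out["LRHGLE"] + r * i^2 * j^2
  }
  for (i in seq_len(nrow(R))) out["GLN"] <- out["GLN"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) out["RLN"] <- out["RLN"] + sum(R[, j])^2
  out / Nr
}

# random quantized ROI: levels array with NA outside a random mask
randomROI <- function(dims, nLevels, pMask = 0.7) {
  repeat {
    mask <- array(runif(prod(dims)) < pMask, dim = dims)
    if (sum(mask) >= 3) break
  }
  levels <- array(NA_integer_, dim = dims)
  levels[mask] <- sample.int(nLevels, sum(mask), replace = TRUE)
  list(levels = levels, mask = mask, nLevels = nLevels)
}

asQuantized <- function(roi, spacing = c(1, 1, 1)) {
  new("QuantizedROI", levels = roi$levels, nLevels = as.integer(roi$nLevels),
      mask = roi$mask, spacing = spacing)
}

# 3-NN majority vote by direct enumeration (own z-scoring, own distances)
oracleKnnVotes <- function(trainX, trainY, queryX, positive, k = 3) {
  mu <- colMeans(trainX)
  sg <- apply(trainX, 2, sd)
  keep <- sg > 0
  zt <- sweep(sweep(trainX[, keep, drop = FALSE], 2, mu[keep]), 2,
              sg[keep], "/")
  zq <- sweep(sweep(queryX[, keep, drop = FALSE], 2, mu[keep]), 2,
              sg[keep], "/")
  apply(zq, 1, function(q) {
    d <- sqrt(colSums((t(zt) - q)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    sum(trainY[nb] == positive)
  })
}

# tie-corrected rank-statistic AUC: (concordant + half ties) / (n+ n-)
oracleAUC <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# 6-connected single-component check by flood fill
isSingleComponent <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2], idx[1, 3]] <- TRUE
  nbs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(nbs))) {
      q <- p + nbs[r, ]
      if (any(q < 1) || any(q > dims)) next
      if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  sum(seen) == sum(mask)
}

# smooth textured test slice (for registration tests)
smoothSlice <- function(n = 32, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * n), n, n)
  for (i in 1:6) {
    f <- (f + f[c(1, seq_len(n - 1)), ] + f[c(seq_len(n - 1) + 1, n), ] +
            f[, c(1, seq_len(n - 1))] + f[, c(seq_len(n - 1) + 1, n)]) / 5
  }
  60 + 8 * f / sd(f)
}

# feature table with planted informative features (class shift in SD units)
plantedTable <- function(nPerClass = 30, nInformative = 3, nNoise = 50,
                         effectSize = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  labels <- rep(c("benign", "malignant"), each = nPerClass)
  X <- matrix(rnorm(n * (nInformative + nNoise)), n)
  X[labels == "malignant", seq_len(nInformative)] <-
    X[labels == "malignant", seq_len(nInformative)] + effectSize
  colnames(X) <- c(paste0("inf", seq_len(nInformative)),
                   paste0("noise", seq_len(nNoise)))
  FeatureTable(X, labels)
}

# small well-separated feature table (two Gaussian clusters)
separableTable <- function(nPerClass = 10, nFeatures = 4, seed = 1) {
  set.seed(seed)
  labels <- rep(c("benign", "malignant"), each = nPerClass)
  X <- matrix(rnorm(2 * nPerClass * nFeatures, sd = 0.3), ncol = nFeatures)
  X[labels == "malignant", ] <- X[labels == "malignant", ] + 5
  colnames(X) <- paste0("f", seq_len(nFeatures))
  FeatureTable(X, labels)
}

smallCohortConfig <- function(volumeShape = c(24, 24, 10), ..., seed = 1) {
  cohortConfig(nBenign = 4, nMalignant = 4, volumeShape = volumeShape,
               lesionDiameterRange = list(benign = c(3, 5),
                                          malignant = c(3, 5)),
               seed = seed, ...)
}
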