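# Independent brute-force oracles, written directly from the defining
# formulas. They share no code with the package internals.

oracle_offsets <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
       c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1),
       c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))
}

in_bounds <- function(v, d) all(v >= 1) && all(v <= d)

# GLCM difference entropy: enumerate every voxel pair per offset
oracle_glcm_de <- function(gray) {
  d <- dim(gray)
  diffs <- integer(0)
  for (off in oracle_offsets()) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v2 <- c(x, y, z) + off
      if (!in_bounds(v2, d)) next
      g1 <- gray[x, y, z]
      g2 <- gray[v2[1], v2[2], v2[3]]
      if (g1 > 0 && g2 > 0) diffs <- c(diffs, abs(g1 - g2))
    }
  }
  if (length(diffs) == 0) return(NA_real_)
  p <- table(diffs) / length(diffs)
  -sum(p * log2(p))
}

# GLRLM run entropy: walk every line per direction, break runs at 0
oracle_glrlm_re <- function(gray) {
  d <- dim(gray)
  runs <- list()
  for (off in oracle_offsets()) {
    starts <- list()
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!in_bounds(c(x, y, z) - off, d)) starts <- c(starts, list(c(x, y, z)))
    }
    for (s in starts) {
      v <- s
      line <- integer(0)
      while (in_bounds(v, d)) {
        line <- c(line, gray[v[1], v[2], v[3]])
        v <- v + off
      }
      lev <- 0L; len <- 0L
      for (g in c(line, -1L)) {
        if (g == lev && g > 0) {
          len <- len + 1L
        } else {
          if (lev > 0) runs <- c(runs, list(c(lev, len)))
          lev <- if (g > 0) g else 0L
          len <- if (g > 0) 1L else 0L
        }
      }
    }
  }
  if (length(runs) == 0) return(NA_real_)
  keys <- vapply(runs, function(r) paste(r, collapse = ","), "")
  p <- table(keys) / length(keys)
  -sum(p * log2(p))
}

# NGTDM complexity and strength, term by term from the IBSI formulas
oracle_ngtdm <- function(gray) {
  d <- dim(gray)
  ng <- max(gray)
  nvec <- numeric(ng); svec <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- gray[x, y, z]
    if (g <= 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(v, d)) next
      g2 <- gray[v[1], v[2], v[3]]
      if (g2 > 0) nb <- c(nb, g2)
    }
    if (length(nb) > 0) {
      nvec[g] <- nvec[g] + 1
      svec[g] <- svec[g] + abs(g - mean(nb))
    }
  }
  nv <- sum(nvec)
  lev <- which(nvec > 0)
  p <- nvec[lev] / nv
  s <- svec[lev]
  cx <- 0; stn <- 0
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    cx <- cx + abs(lev[a] - lev[b]) * (p[a] * s[a] + p[b] * s[b]) /
      (p[a] + p[b])
    stn <- stn + (p[a] + p[b]) * (lev[a] - lev[b])^2
  }
  list(complexity = cx / nv,
       strength = if (sum(s) > 0) stn / sum(s) else 0)
}

# Harrell concordance by exhaustive pair enumeration
oracle_ci <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    earlier <- NA
    if (time[i] < time[j] && event[i] == 1) earlier <- i
    if (time[j] < time[i] && event[j] == 1) earlier <- j
    if (time[i] == time[j]) {
      if (event[i] == 1 && event[j] == 0) earlier <- i
      if (event[j] == 1 && event[i] == 0) earlier <- j
    }
    if (is.na(earlier)) next
    other <- if (earlier == i) j else i
    den <- den + 1
    if (risk[earlier] > risk[other]) num <- num + 1
    if (risk[earlier] == risk[other]) num <- num + 0.5
  }
  num / den
}

# random small gray-level volume with a random mask (0 = outside)
random_gray_volume <- function(d = c(5, 5, 5), ng = 4, p_mask = 0.7) {
  g <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
  keep <- array(runif(prod(d)) < p_mask, dim = d)
  g[!keep] <- 0L
  if (all(g == 0)) g[1, 1, 1] <- 1L
  storage.mode(g) <- "integer"
  g
}

# random connected-ish blob mask via thresholded smooth noise
random_blob_mask <- function(d, spacing, seed) {
  set.seed(seed)
  f <- array(rnorm(prod(d)), dim = d)
  # smooth by averaging shifted copies (independent of the package's kernels)
  a <- array(0, dim = d)
  cnt <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(1:d[1] + dx, 1), d[1])
    ys <- pmin(pmax(1:d[2] + dy, 1), d[2])
    zs <- pmin(pmax(1:d[3] + dz, 1), d[3])
    a <- a + f[xs, ys, zs]
    cnt <- cnt + 1
  }
  a <- a / cnt
  m <- a > quantile(a, 0.93)
  m[c(1, d[1]), , ] <- FALSE
  m[, c(1, d[2]), ] <- FALSE
  m[, , c(1, d[3])] <- FALSE
  if (!any(m)) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  m
}

# exact distances from every voxel to the nearest mask voxel (brute force)
brute_distance <- function(mask, spacing) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    dd <- sqrt(((x - pts[, 1]) * spacing[1])^2 +
                 ((y - pts[, 2]) * spacing[2])^2 +
                 ((z - pts[, 3]) * spacing[3])^2)
    out[x, y, z] <- min(dd)
  }
  out
}

random_censored_data <- function(n, tie_prob = 0.2) {
  tm <- rexp(n, 0.1)
  if (tie_prob > 0) tm <- round(tm * 4) / 4 + 0.25  # induce time ties, keep > 0
  ev <- rbinom(n, 1, 0.6)
  risk <- sample(rep_len(rnorm(ceiling(n * 0.8)), n))  # some tied risks
  list(risk = risk, time = tm, event = ev)
}

# clinical covariate table with all columns the outcome model expects
sample_clinical_table <- function(n) {
  cl <- periomics:::sample_clinical(n)
  cl$tumor_size_mm <- runif(n, 10, 22)
  cl
}
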