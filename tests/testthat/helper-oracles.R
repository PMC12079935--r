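# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and textbook formulas only.

# Exhaustive triple-loop SUVmax scan, lexicographic (i,j,k) tie-break,
# 0-based result.
brute_hotspot <- function(vals) {
  dm <- dim(vals)
  best <- -Inf; best_idx <- NULL
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- vals[i, j, k]
    if (v > best) { best <- v; best_idx <- c(i, j, k) - 1L }
  }
  as.integer(best_idx)
}

# Queue-based 26-connected flood fill over `eligible` from a 0-based seed
# (preallocated queue so large components stay tractable).
brute_flood_fill <- function(eligible, seed0) {
  dm <- dim(eligible)
  comp <- array(FALSE, dm)
  qi <- qj <- qk <- integer(prod(dm))
  head <- 1L; tail <- 1L
  qi[1] <- seed0[1] + 1L; qj[1] <- seed0[2] + 1L; qk[1] <- seed0[3] + 1L
  comp[qi[1], qj[1], qk[1]] <- TRUE
  while (head <= tail) {
    ci <- qi[head]; cj <- qj[head]; ck <- qk[head]; head <- head + 1L
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      pi <- ci + di; pj <- cj + dj; pk <- ck + dk
      if (pi < 1 || pj < 1 || pk < 1 || pi > dm[1] || pj > dm[2] || pk > dm[3]) next
      if (eligible[pi, pj, pk] && !comp[pi, pj, pk]) {
        comp[pi, pj, pk] <- TRUE
        tail <- tail + 1L
        qi[tail] <- pi; qj[tail] <- pj; qk[tail] <- pk
      }
    }
  }
  comp
}

# Per-voxel 6-neighbor perimeter scan; 0-based index matrix, same row
# order convention as which() on the array (column-major).
brute_perimeter <- function(mask) {
  dm <- dim(mask)
  out <- NULL
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!mask[i, j, k]) next
    boundary <- FALSE
    for (r in 1:6) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > dm) || !mask[p[1], p[2], p[3]]) {
        boundary <- TRUE; break
      }
    }
    if (boundary) out <- rbind(out, c(i, j, k) - 1L)
  }
  out
}

# All-pairs minimum center-to-center distance, mm.
brute_min_dist <- function(hotspot0, perimeter0, spacing) {
  best <- Inf
  for (r in seq_len(nrow(perimeter0))) {
    d <- sqrt(sum(((perimeter0[r, ] - hotspot0) * spacing)^2))
    if (d < best) best <- d
  }
  best
}

# Pairwise-concordance AUC, ties count one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden search over observed values; smallest cutoff on ties.
brute_youden <- function(scores, labels, orientation) {
  best_j <- -Inf; best <- NULL
  for (c0 in sort(unique(scores))) {
    pred <- if (orientation == "higher_predicts_event") scores >= c0 else scores <= c0
    sens <- mean(pred[labels == 1]); spec <- mean(!pred[labels == 0])
    j <- sens + spec - 1
    if (j > best_j + 1e-15) { best_j <- j; best <- c(cutoff = c0, sens = sens, spec = spec) }
  }
  best
}

# Hand-written Cox log partial likelihood (no ties expected in inputs).
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 0) next
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-group log-rank chi-square by per-event-time risk-set tabulation.
brute_logrank <- function(time, event, grp) {
  g1 <- levels(factor(grp))[1]
  oe <- 0; v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    n <- sum(at_risk); n1 <- sum(at_risk & grp == g1)
    d <- sum(event == 1 & time == t0)
    d1 <- sum(event == 1 & time == t0 & grp == g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Rank-then-Pearson Spearman correlation.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random connected-ish test masks: union of a few random balls on a grid,
# guaranteed nonempty.
random_mask <- function(dm, seed, n_blobs = 3) {
  set.seed(seed)
  m <- array(FALSE, dm)
  ax <- lapply(dm, function(n) seq_len(n) - 1)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dm, function(n) runif(1, 0, n - 1))
    rad <- runif(1, 1.5, max(dm) / 3)
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                (ax[[3]] - ctr[3])^2, `+`)
    m <- m | (d2 <= rad^2)
  }
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

# Smooth random SUV volume for segmentation oracles.
random_volume <- function(dm, seed) {
  set.seed(seed)
  vals <- array(runif(prod(dm), 0, 10), dm)
  hotspotpet::pet_volume(vals, 3)
}

digitized_ball <- function(R_mm, spacing_mm, margin_vox = 2L) {
  n <- 2L * (ceiling(R_mm / spacing_mm) + margin_vox) + 1L
  ctr <- (n - 1) / 2 * spacing_mm
  ax <- (seq_len(n) - 1) * spacing_mm
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  array(d2 <= R_mm^2, c(n, n, n))
}
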