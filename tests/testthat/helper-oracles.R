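# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

# half-sample symmetric reflection of index i (1-based) into 1..n
reflect1 <- function(i, n) {
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  if (i >= n) i <- period - 1L - i
  i + 1L
}

# local mean over an odd window with reflective borders, nested loops
oracle_local_mean <- function(img, window) {
  H <- nrow(img); W <- ncol(img); r <- window %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + img[reflect1(i + di, H), reflect1(j + dj, W)]
    out[i, j] <- acc / window^2
  }
  out
}

# connected components by BFS flood fill; returns list(labels, areas)
oracle_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 8)
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  else cbind(c(-1,0,0,1), c(0,-1,1,0))
  lab <- matrix(0L, H, W)
  areas <- integer(0)
  k <- 0L
  for (ii in seq_len(H)) for (jj in seq_len(W)) {
    if (!mask[ii, jj] || lab[ii, jj] != 0L) next
    k <- k + 1L
    queue <- list(c(ii, jj))
    lab[ii, jj] <- k
    area <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      area <- area + 1L
      for (t in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[t, 1]; c2 <- p[2] + nb[t, 2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
    areas <- c(areas, area)
  }
  list(labels = lab, areas = areas)
}

# the nine CFZ biomarkers by raw pixel enumeration + flood fill,
# including the <= 2 px exclusion on counts/means
oracle_features <- function(map, connectivity = 8) {
  m <- unclass(map)
  a <- sapply(0:4, function(k) sum(m == k))
  div <- function(x, y) if (y > 0) x / y else NA_real_
  keep <- function(areas) areas[areas > 2]
  pa <- keep(oracle_components(m == 3L, connectivity)$areas)
  pv <- keep(oracle_components(m == 4L, connectivity)$areas)
  tt <- keep(oracle_components(m == 3L | m == 4L, connectivity)$areas)
  c(Ra = div(a[4], a[2]), Rv = div(a[5], a[3]),
    Rt = div(a[4] + a[5], a[2] + a[3]),
    Na = length(pa), Nv = length(pv), Nt = length(tt),
    Ma = if (length(pa)) mean(pa) else NA_real_,
    Mv = if (length(pv)) mean(pv) else NA_real_,
    Mt = if (length(tt)) mean(tt) else NA_real_)
}

# multiclass Jaccard loss by nested loops over items, classes
# and pixels (s, g arrays C x N x B)
oracle_iou_loss <- function(s, g) {
  eps <- 1e-7
  num <- 0; den <- 0
  d <- dim(s)
  for (b in seq_len(d[3])) for (cc in seq_len(d[1])) for (i in seq_len(d[2])) {
    num <- num + g[cc, i, b] * s[cc, i, b]
    den <- den + g[cc, i, b] + s[cc, i, b] - g[cc, i, b] * s[cc, i, b]
  }
  1 - (num + eps) / (den + eps)
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
oracle_u_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_of <- function(idx) sum(ranks[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# random five-class label map with blobby CFZ structure
random_label_map <- function(h = 64, w = 64, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:4, h * w, replace = TRUE,
                     prob = c(0.75, 0.07, 0.07, 0.055, 0.055)), h, w)
  label_map(m)
}

# random softmax-normalised batch with one-hot truth (C x N x B)
random_batch <- function(C, N, B, seed) {
  set.seed(seed)
  s <- array(runif(C * N * B), c(C, N, B))
  for (b in seq_len(B)) s[, , b] <- sweep(s[, , b], 2, colSums(s[, , b]), "/")
  g <- array(0, c(C, N, B))
  for (b in seq_len(B)) for (i in seq_len(N))
    g[sample(C, 1), i, b] <- 1
  list(s = s, g = g)
}
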