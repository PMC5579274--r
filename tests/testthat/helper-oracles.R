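# Independent brute-force oracles for the texture matrices and ranking
# metrics. Deliberately naive (nested loops over voxels / pairs) so they
# share no code with the package implementations.

dirs13 <- local({
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d[apply(d, 1, function(v) v[v != 0][1] > 0), ]
})

make_q <- function(lev, n_gray, spacing = c(1, 1, 1)) {
  structure(list(levels = lev, n_gray = as.integer(n_gray), spacing = spacing),
            class = "quantized_roi")
}

vol_from <- function(values, dims, spacing = c(1, 1, 1), modality = "PET") {
  image_volume(array(values, dims), spacing, modality)
}

mask_from <- function(flags, dims, spacing = c(1, 1, 1)) {
  roi_mask(array(flags, dims), spacing)
}

oracle_glcm <- function(lev, n_gray, wts = c(1, 1 / sqrt(2), 1 / sqrt(3))) {
  d <- dim(lev)
  m <- matrix(0, n_gray, n_gray)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g1 <- lev[x, y, z]
    if (g1 == 0) next
    for (k in 1:13) {
      o <- dirs13[k, ]
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      g2 <- lev[x2, y2, z2]
      if (g2 == 0) next
      w <- wts[sum(abs(o))]
      m[g1, g2] <- m[g1, g2] + w
      m[g2, g1] <- m[g2, g1] + w
    }
  }
  if (sum(m) > 0) m / sum(m) else m
}

oracle_ngtdm <- function(lev, n_gray, wts = c(1, 1 / sqrt(2), 1 / sqrt(3))) {
  d <- dim(lev)
  s <- numeric(n_gray); n <- numeric(n_gray)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lev[x, y, z]
    if (g == 0) next
    ws <- 0; acc <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      g2 <- lev[x2, y2, z2]
      if (g2 == 0) next
      w <- wts[abs(dx) + abs(dy) + abs(dz)]
      ws <- ws + w; acc <- acc + w * g2
    }
    if (ws > 0) { s[g] <- s[g] + abs(g - acc / ws); n[g] <- n[g] + 1 }
  }
  list(s = s, n = n)
}

# returns a named list "level runlength" -> count
oracle_glrlm <- function(lev, n_gray, weighted = TRUE) {
  d <- dim(lev)
  res <- list()
  add <- function(g, len) {
    key <- paste(g, len)
    res[[key]] <<- (if (is.null(res[[key]])) 0 else res[[key]]) + 1
  }
  for (k in 1:13) {
    o <- dirs13[k, ]
    step <- if (weighted) sqrt(sum(o^2)) else 1
    starts <- which(array(TRUE, d), arr.ind = TRUE)
    prev <- sweep(starts, 2, o, `-`)
    is_start <- prev[, 1] < 1 | prev[, 1] > d[1] | prev[, 2] < 1 |
      prev[, 2] > d[2] | prev[, 3] < 1 | prev[, 3] > d[3]
    starts <- starts[is_start, , drop = FALSE]
    for (r in seq_len(nrow(starts))) {
      p <- starts[r, ]; cur <- 0; cnt <- 0
      while (all(p >= 1) && all(p <= d)) {
        g <- lev[p[1], p[2], p[3]]
        if (g == cur && g != 0) cnt <- cnt + 1
        else {
          if (cur != 0) add(cur, round(1 + (cnt - 1) * step))
          cur <- g; cnt <- if (g != 0) 1 else 0
        }
        p <- p + o
      }
      if (cur != 0) add(cur, round(1 + (cnt - 1) * step))
    }
  }
  res
}

glrlm_as_pairs <- function(m) {
  res <- list()
  for (g in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (m[g, j] > 0) res[[paste(g, j)]] <- unname(m[g, j])
  res
}

# flood-fill zones; returns list of c(level, size)
oracle_glszm <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x0 in 1:d[1]) for (y0 in 1:d[2]) for (z0 in 1:d[3]) {
    if (seen[x0, y0, z0] || lev[x0, y0, z0] == 0) next
    g <- lev[x0, y0, z0]
    stack <- list(c(x0, y0, z0)); seen[x0, y0, z0] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zones
}

random_quantized_roi <- function(max_dim = 4, max_gray = 4) {
  d <- sample(seq_len(max_dim), 3, replace = TRUE)
  ng <- sample(2:max_gray, 1)
  lev <- array(sample(0:ng, prod(d), replace = TRUE), d)
  if (all(lev == 0)) lev[1] <- 1L
  make_q(lev, ng)
}

expect_matches_oracles <- function(q) {
  lev <- q$levels; ng <- q$n_gray
  glcm <- build_glcm(q)
  if (!glcm$degenerate)
    expect_equal(glcm$m, oracle_glcm(lev, ng), tolerance = 1e-12,
                 ignore_attr = TRUE)
  ngt <- build_ngtdm(q)
  o <- oracle_ngtdm(lev, ng)
  expect_equal(ngt$s, o$s, tolerance = 1e-12)
  expect_equal(ngt$p, if (sum(o$n) > 0) o$n / sum(o$n) else o$n,
               tolerance = 1e-12)
  prl <- glrlm_as_pairs(build_glrlm(q)$m)
  orl <- oracle_glrlm(lev, ng)
  expect_equal(prl[order(names(prl))], orl[order(names(orl))])
  sz <- build_glszm(q)$m
  zm <- matrix(0, ng, max(1, vapply(oracle_glszm(lev), `[`, 0, 2)))
  for (zz in oracle_glszm(lev)) zm[zz[1], zz[2]] <- zm[zz[1], zz[2]] + 1
  expect_equal(sz[, seq_len(ncol(zm)), drop = FALSE], zm, ignore_attr = TRUE)
  if (ncol(sz) > ncol(zm)) expect_true(all(sz[, -seq_len(ncol(zm))] == 0))
}

# pair-counting AUC oracle (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# permissible-pair concordance oracle
oracle_cindex <- function(risk, time, event) {
  n <- length(risk); num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
    }
  }
  num / den
}

# exhaustive step-up BH oracle
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(ks)) flags[o[seq_len(max(ks))]] <- TRUE
  flags
}
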