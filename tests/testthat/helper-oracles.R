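# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (double loops, direct enumeration) and never share code
# with the implementation paths they check.

rand_cloud <- function(n, seed, xmax = 20, ymax = 16, zmax = 22) {
  set.seed(seed)
  point_cloud(runif(n, 0, xmax), runif(n, 0, ymax), runif(n, 0, zmax))
}

# per-cell maximum by an explicit double loop over cells
bf_chm <- function(pc, gsd) {
  ox <- floor(min(pc$x) / gsd) * gsd
  oy <- floor(min(pc$y) / gsd) * gsd
  nc <- floor((max(pc$x) - ox) / gsd) + 1
  nr <- floor((max(pc$y) - oy) / gsd) + 1
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    sel <- pc$x >= ox + (j - 1) * gsd & pc$x < ox + j * gsd &
      pc$y >= oy + (i - 1) * gsd & pc$y < oy + i * gsd
    if (any(sel)) m[i, j] <- max(pc$z[sel])
  }
  list(values = m, origin = c(ox, oy))
}

# brute-force voxel occupancy, counts and per-column top points
bf_voxelize <- function(pc, dx, dy, dz) {
  ox <- floor(min(pc$x) / dx) * dx
  oy <- floor(min(pc$y) / dy) * dy
  i <- as.integer(floor((pc$x - ox) / dx))
  j <- as.integer(floor((pc$y - oy) / dy))
  k <- as.integer(floor(pc$z / dz))
  key <- paste(i, j, k)
  counts <- table(key)
  vox <- unique(data.frame(i = i, j = j, k = k, key = key))
  vox$count <- as.integer(counts[vox$key])
  vox <- vox[order(vox$i, vox$j, vox$k), c("i", "j", "k", "count")]
  rownames(vox) <- NULL
  cols <- do.call(rbind, lapply(split(seq_along(i), paste(i, j)), function(idx) {
    best <- idx[order(-pc$z[idx], idx)][1]
    data.frame(i = i[best], j = j[best], top_x = pc$x[best],
               top_y = pc$y[best], top_z = pc$z[best])
  }))
  cols <- cols[order(cols$i, cols$j), ]
  rownames(cols) <- NULL
  list(voxels = vox, columns = cols, origin = c(ox, oy))
}

bf_r2_rmse <- function(y, yhat) {
  n <- length(y)
  sse <- 0
  for (t in seq_len(n)) sse <- sse + (y[t] - yhat[t])^2
  ybar <- sum(y) / n
  sst <- 0
  for (t in seq_len(n)) sst <- sst + (y[t] - ybar)^2
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / n))
}

# Duncan decisions by direct enumeration: a sorted pair (i, j) is
# non-significant iff SOME containing span's extreme difference lies inside
# that span's critical range.
bf_duncan_nonsig <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  ns <- tapply(values, groups, length)[names(means)]
  g <- length(means)
  fit <- stats::lm(values ~ groups)
  msw <- stats::anova(fit)$`Mean Sq`[2]
  df2 <- stats::anova(fit)$Df[2]
  n_h <- g / sum(1 / ns)
  crit <- function(p) stats::qtukey((1 - alpha)^(p - 1), p, df2) *
    sqrt(msw / n_h)
  out <- matrix(FALSE, g, g, dimnames = list(names(means), names(means)))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    ns_pair <- FALSE
    for (a in 1:i) for (b in j:g) {
      if (means[a] - means[b] <= crit(b - a + 1)) ns_pair <- TRUE
    }
    out[i, j] <- out[j, i] <- ns_pair
  }
  out
}

letters_share <- function(duncan_table) {
  g <- nrow(duncan_table)
  share <- matrix(FALSE, g, g,
                  dimnames = list(duncan_table$group, duncan_table$group))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    li <- strsplit(duncan_table$letters[i], "")[[1]]
    lj <- strsplit(duncan_table$letters[j], "")[[1]]
    share[i, j] <- length(intersect(li, lj)) > 0
  }
  share
}

# one shared small end-to-end run, built once per test session
demo_run_cache <- new.env(parent = emptyenv())
get_demo_run <- function() {
  if (is.null(demo_run_cache$cfg)) {
    cfg <- run_config(out_dir = file.path(tempdir(), "voxfpar-demo-run"),
                      seed = 42)
    run_pipeline(cfg)
    demo_run_cache$cfg <- cfg
  }
  demo_run_cache$cfg
}
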