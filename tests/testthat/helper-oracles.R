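# Independent oracles used to check the package implementations. These are
# deliberately naive (double loops, exhaustive enumeration) and share no
# code with the implementation paths they verify.

# Brute-force pixel scan for the nonperfusion index numerator.
npi_bruteforce <- function(pixels, threshold = 45, inclusive = FALSE) {
  count <- 0L
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      v <- pixels[i, j]
      if ((inclusive && v <= threshold) || (!inclusive && v < threshold)) {
        count <- count + 1L
      }
    }
  }
  count
}

# Breadth-first 4-connected flood fill with an explicit queue.
bfs_flood_count <- function(mask, seed_x, seed_y) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!mask[seed_y + 1L, seed_x + 1L]) return(0L)
  visited <- matrix(FALSE, nr, nc)
  queue <- list(c(seed_y + 1L, seed_x + 1L))
  visited[seed_y + 1L, seed_x + 1L] <- TRUE
  count <- 0L
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    count <- count + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- cur[1L] + d[1L]; c <- cur[2L] + d[2L]
      if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
          mask[r, c] && !visited[r, c]) {
        visited[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  count
}

# Kruskal-Wallis H from the rank formula, with midranks and tie correction,
# computed from first principles (no rank()).
kw_H_oracle <- function(x, g) {
  N <- length(x)
  ord <- order(x)
  rk <- numeric(N)
  i <- 1L
  pos <- 1L
  ties <- integer()
  while (i <= N) {
    j <- i
    while (j < N && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    rk[ord[i:j]] <- mean(pos:(pos + (j - i)))
    ties <- c(ties, j - i + 1L)
    pos <- pos + (j - i + 1L)
    i <- j + 1L
  }
  H <- 0
  for (lv in unique(g)) {
    ri <- rk[g == lv]
    H <- H + length(ri) * (mean(ri) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(length(pooled), nx)
  W <- apply(cmb, 2L, function(ix) sum(rk[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exact two-sided Spearman p by full permutation of y.
spearman_exact_p <- function(x, y) {
  r_obs <- cor(x, y, method = "spearman")
  rs <- vapply(all_permutations(y), function(p) cor(x, p, method = "spearman"),
               numeric(1L))
  min(1, 2 * min(mean(rs <= r_obs + 1e-12), mean(rs >= r_obs - 1e-12)))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of the probabilities of all tables (with the observed margins) no
# more likely than the observed one.
fisher_2x2_exact_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(i) {
    choose(m, i) * choose(n, k - i) / choose(m + n, k)
  }, numeric(1L))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo polygon area by rejection sampling (even-odd rule re-derived
# per point, independent of the shoelace path).
mc_polygon_area <- function(v, n_points = 1e6, seed = 99) {
  set.seed(seed)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  px <- runif(n_points, xr[1L], xr[2L])
  py <- runif(n_points, yr[1L], yr[2L])
  inside <- rep(FALSE, n_points)
  n <- nrow(v); j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    cr <- ((yi > py) != (yj > py)) & (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Deterministic 58-eye / 35-patient cohort with a 19/24/15 stage split,
# 22 men and 29 insulin users.
reference_cohort_table <- function() {
  pat <- c(rep(1:23, each = 2), 24:35)
  side <- unlist(lapply(table(pat), function(k) c("OD", "OS")[seq_len(k)]))
  data.frame(
    patient_id = sprintf("P%02d", pat),
    eye_side = side,
    stage = factor(rep(c("mild", "moderate", "severe"), times = c(19, 24, 15)),
                   levels = npdr_stages()),
    sex_male = as.integer(pat <= 22),
    insulin = as.integer(pat <= 29)
  )
}

# Small, fast scene for image tests.
small_scene <- function(seed = 1, size = 128, ...) {
  generate_angiogram(vascular_scene_params(image_size_px = size, seed = seed, ...))
}
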