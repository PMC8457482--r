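# Shared fixture builders. Everything is generated in code; no data files.

# small continuous raster with reproducible values
toy_raster <- function(nr = 6, nc = 5, cell = 50, origin = c(0, nr * cell),
                       seed = 1, kind = "continuous") {
  set.seed(seed)
  v <- matrix(round(stats::rnorm(nr * nc), 3), nr, nc)
  grid_raster(v, cell, origin, kind = "continuous")
}

# boolean raster from a logical matrix
mask_raster <- function(m, cell = 50, origin = c(0, nrow(m) * cell)) {
  grid_raster(m + 0, cell, origin)
}

# aligned two-layer stack
toy_stack <- function(nr = 6, nc = 5, cell = 50, seed = 1) {
  set.seed(seed)
  org <- c(0, nr * cell)
  a <- grid_raster(matrix(stats::rnorm(nr * nc), nr, nc), cell, org)
  b <- grid_raster(matrix(stats::rnorm(nr * nc, 10, 2), nr, nc), cell, org)
  raster_stack(list(a = a, b = b))
}

# empirical lag-1 Moran's I (rook neighbours) of a matrix
moran_lag1 <- function(m) {
  z <- m - mean(m)
  num <- sum(z[-1, ] * z[-nrow(m), ]) + sum(z[, -1] * z[, -ncol(m)])
  n_pairs <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  (num / n_pairs) / (sum(z^2) / length(z))
}

# brute-force all-pairs distance-to-feature oracle (cell centres)
brute_distance <- function(fmat, cell) {
  idx <- which(fmat != 0, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(fmat), ncol(fmat))
  for (i in seq_len(nrow(fmat))) for (j in seq_len(ncol(fmat))) {
    out[i, j] <- cell * sqrt(min((i - idx[, 1])^2 + (j - idx[, 2])^2))
  }
  out
}

# exhaustive maximum-independent-set size of the < min_dist proximity graph
mis_size <- function(x, y, min_dist) {
  n <- length(x)
  adj <- as.matrix(stats::dist(cbind(x, y))) < min_dist
  diag(adj) <- FALSE
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    if (!any(adj[members, members])) best <- length(members)
  }
  best
}

# naive two-loop use-availability log-likelihood oracle
naive_loglik <- function(beta, x_used, x_avail) {
  wfun <- function(xrow) {
    eta <- beta[1] + sum(beta[-1] * xrow)
    exp(eta) / (1 + exp(eta))
  }
  total <- 0
  for (i in seq_len(nrow(x_used))) {
    s <- 0
    for (j in seq_len(nrow(x_avail))) s <- s + wfun(x_avail[j, ])
    total <- total + log(wfun(x_used[i, ])) - log(s / nrow(x_avail))
  }
  total
}

# small labelled design with a single informative covariate on a bounded
# lattice of landscape values (used and available share support, so the
# use-availability likelihood has a well-posed interior maximum)
toy_design <- function(n_used = 60, n_avail = 180, beta0 = -1, b1 = 1.5,
                       seed = 1) {
  set.seed(seed)
  cells <- seq(-2, 2, length.out = 64)
  xa <- sample(cells, n_avail, replace = TRUE)
  xu <- numeric(0)
  while (length(xu) < n_used) {
    prop <- sample(cells, 500, replace = TRUE)
    xu <- c(xu, prop[stats::runif(500) < stats::plogis(beta0 + b1 * prop)])
  }
  x <- matrix(c(xu[seq_len(n_used)], xa), ncol = 1,
              dimnames = list(NULL, "x1"))
  structure(list(x = x, y = c(rep(1L, n_used), rep(0L, n_avail)),
                 terms = "x1", continuous = "x1", categorical = NULL,
                 reference_class = NULL, term_columns = list(x1 = 1L)),
            class = "rspf_data")
}
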