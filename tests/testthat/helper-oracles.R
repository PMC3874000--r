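# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and EBImage), trading speed for
# obviousness.

# Connected-component labeling by explicit flood fill (BFS).
flood_fill_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8L) {
    nbrs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nbrs <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  next_lab <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    next_lab <- next_lab + 1L
    queue <- list(c(i, j)); lab[i, j] <- next_lab
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        ni <- p[1] + nbrs[k, 1]; nj <- p[2] + nbrs[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- next_lab
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Multisets of component areas under a labeling (order-free comparison).
component_areas <- function(lab) sort(as.vector(table(lab[lab > 0])))

# Otsu by direct maximization of the between-class variance over every cut.
otsu_brute <- function(v, max_level) {
  best_t <- NA_integer_; best <- -Inf
  n <- length(v)
  for (t in 0:(max_level - 1L)) {
    in0 <- v <= t
    w0 <- mean(in0)
    if (w0 == 0 || w0 == 1) next
    sb2 <- w0 * (1 - w0) * (mean(v[in0]) - mean(v[!in0]))^2
    if (sb2 > best + 1e-12) { best <- sb2; best_t <- t }
  }
  best_t
}

# Empirical AUC by enumerating every (negative, positive) pair.
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Logistic MLE by direct minimization of the negative log-likelihood.
logistic_mle_direct <- function(x1, x2, y) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x1 + beta[3] * x2
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  }
  fit <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  fit$par
}

# A small RGB core_image from explicit channel matrices.
rgb_image <- function(r, g, b, core_id = NULL) {
  core_image(array(c(r, g, b), dim = c(nrow(r), ncol(r), 3)),
             bit_depth = 8L, core_id = core_id)
}

# Fixed threshold isolating the generator's dark stain class (gray ~60 vs
# tissue ~183): the synthetic analogue of the manually chosen cuts of the
# original protocol.
synthetic_dab_config <- function(...) {
  quant_config(dab_threshold = list(method = "fixed", lo = 0, hi = 120), ...)
}
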