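# Independent oracles used to check the package implementations. These are
# deliberately naive (loops, enumeration, grids) and share no code with the
# package internals.

# pair-counting AUC: explicit double loop over (positive, negative) pairs
auc_enum <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Youden operating point by brute force over every observed cut-point
youden_enum <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- list(j = -Inf, sens = -Inf, thr = Inf)
  for (t in sort(unique(scores))) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    j <- sens + spec - 1
    better <- (j > best$j + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         t < best$thr)
    if (better) best <- list(j = j, sens = sens, spec = spec, thr = t)
  }
  best
}

# hand-computed two-class Gaussian LDA posterior (pooled covariance,
# proportion priors), written from the textbook formulas
lda_posterior_enum <- function(x_train, y_train, x_new) {
  x_train <- as.matrix(x_train)
  y <- as.logical(y_train)
  n1 <- sum(y); n0 <- sum(!y)
  mu1 <- colMeans(x_train[y, , drop = FALSE])
  mu0 <- colMeans(x_train[!y, , drop = FALSE])
  W <- matrix(0, ncol(x_train), ncol(x_train))
  for (i in which(y)) W <- W + tcrossprod(x_train[i, ] - mu1)
  for (i in which(!y)) W <- W + tcrossprod(x_train[i, ] - mu0)
  W <- W / (n1 + n0 - 2)
  post <- numeric(nrow(as.matrix(x_new)))
  for (i in seq_along(post)) {
    x <- as.matrix(x_new)[i, ]
    d1 <- -0.5 * drop(t(x - mu1) %*% solve(W, x - mu1)) + log(n1 / (n1 + n0))
    d0 <- -0.5 * drop(t(x - mu0) %*% solve(W, x - mu0)) + log(n0 / (n1 + n0))
    post[i] <- exp(d1) / (exp(d1) + exp(d0))
  }
  post
}

# explicit leave-one-out enumeration of pooled LDA scores
loocv_enum <- function(features, labels, n_pcs) {
  X <- as.matrix(features)[, seq_len(n_pcs), drop = FALSE]
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X)))
    out[i] <- lda_posterior_enum(X[-i, , drop = FALSE], labels[-i],
                                 X[i, , drop = FALSE])
  out
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# minimal full-Procrustes distance by brute-force search over SO(3):
# both configurations centred and scaled to unit centroid size first, then
# ||a R - b|| minimised over a coarse Euler-angle grid whose best candidates
# are each refined by nested local grids (multi-start, so a shallow coarse
# basin cannot trap the search)
opa_grid_distance <- function(a, b, n_starts = 12L, levels = 5L) {
  norm1 <- function(x) {
    xc <- sweep(as.matrix(x), 2L, colMeans(x))
    xc / sqrt(sum(xc^2))
  }
  an <- norm1(a); bn <- norm1(b)
  M <- crossprod(an, bn)                 # ||anR - bn||^2 = 2 - 2 tr(R'M)
  step0 <- pi / 18
  coarse <- expand.grid(a = seq(-pi, pi, by = step0),
                        b = seq(0, pi, by = step0),
                        c = seq(-pi, pi, by = step0))
  tr <- mapply(function(aa, bb, cc) sum(euler_rotation(aa, bb, cc) * M),
               coarse$a, coarse$b, coarse$c)
  starts <- coarse[order(-tr)[seq_len(n_starts)], ]
  best_tr <- max(tr)
  for (k in seq_len(n_starts)) {
    centre <- as.numeric(starts[k, ])
    step <- step0
    for (lev in seq_len(levels)) {
      gr <- expand.grid(a = seq(centre[1] - 6 * step, centre[1] + 6 * step,
                                by = step),
                        b = seq(centre[2] - 6 * step, centre[2] + 6 * step,
                                by = step),
                        c = seq(centre[3] - 6 * step, centre[3] + 6 * step,
                                by = step))
      trs <- mapply(function(aa, bb, cc)
        sum(euler_rotation(aa, bb, cc) * M), gr$a, gr$b, gr$c)
      i <- which.max(trs)
      centre <- as.numeric(gr[i, ])
      best_tr <- max(best_tr, trs[i])
      step <- step / 4
    }
  }
  sqrt(max(0, 2 - 2 * best_tr))
}

# least-squares similarity residual by brute force over rotations: for each
# grid rotation the optimal scale and translation have closed forms
similarity_residual_grid <- function(x, y, levels = 4L) {
  x <- as.matrix(x); y <- as.matrix(y)
  xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
  rss_for <- function(R) {
    xr <- xc %*% t(R)
    s <- sum(xr * yc) / sum(xr^2)
    sum((s * xr - yc)^2)
  }
  best <- c(0, 0, 0); step <- pi / 18; best_rss <- Inf
  for (lev in seq_len(levels)) {
    half_a <- if (lev == 1L) 18 else 5
    half_b <- if (lev == 1L) 9 else 5
    as_grid <- seq(best[1L] - half_a * step, best[1L] + half_a * step, by = step)
    bs_grid <- seq((if (lev == 1L) pi / 2 else best[2L]) - half_b * step,
                   (if (lev == 1L) pi / 2 else best[2L]) + half_b * step,
                   by = step)
    cs_grid <- seq(best[3L] - half_a * step, best[3L] + half_a * step, by = step)
    for (aa in as_grid) for (bb in bs_grid) for (cc in cs_grid) {
      r <- rss_for(euler_rotation(aa, bb, cc))
      if (r < best_rss) { best_rss <- r; best <- c(aa, bb, cc) }
    }
    step <- step / 5
  }
  sqrt(best_rss)
}
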