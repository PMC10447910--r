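# Shape-space PCA of Procrustes-aligned coordinates, group mean shapes and
# per-vertex distance maps between mean shapes.

flatten_configs <- function(x) {
  if (inherits(x, "gpa_fit")) x <- x$aligned
  if (is.list(x) && !is.array(x)) {
    n <- length(x)
    x <- array(unlist(lapply(x, as.matrix)), c(nrow(x[[1L]]), 3L, n))
    x <- aperm(x, c(3L, 1L, 2L))
  }
  x <- unclass(x)
  n <- dim(x)[1L]; K <- dim(x)[2L]
  # row i = (x1, y1, z1, x2, ...) of sample i
  flat <- matrix(aperm(x, c(1L, 3L, 2L)), n, 3L * K)
  colnames(flat) <- paste0(rep(c("x", "y", "z"), K),
                           rep(seq_len(K), each = 3L))
  attr(flat, "K") <- K
  flat
}

#' Principal component analysis of aligned shapes
#'
#' Covariance PCA of the flattened (x1, y1, z1, ...) Procrustes-aligned
#' coordinates. Components are capped at `min(n - 1, 3K)` (the maximal rank)
#' and each component's sign is fixed so its largest-magnitude coordinate is
#' positive, making the decomposition deterministic. Variance fractions are
#' eigenvalues over total variance and sum to one across the retained
#' components.
#'
#' @param aligned a `gpa_fit`, an n x K x 3 array, or a list of K x 3
#'   matrices (n >= 2).
#' @return A `shape_space`: list with `mean_vector` (3K), `components`
#'   (3K x m orthonormal), `eigenvalues` (descending), `scores` (n x m),
#'   `variance_fraction`, `K`, `n`.
#' @export
fit_pca <- function(aligned) {
  flat <- flatten_configs(aligned)
  n <- nrow(flat)
  if (n < 2L) stop("PCA needs at least 2 samples")
  K <- attr(flat, "K")
  mu <- colMeans(flat)
  Xc <- sweep(flat, 2L, mu)
  sv <- svd(Xc, nu = 0)
  m <- min(n - 1L, ncol(flat))
  V <- sv$v[, seq_len(m), drop = FALSE]
  ev <- sv$d[seq_len(m)]^2 / (n - 1L)
  # deterministic sign: largest-|loading| coordinate positive
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(m))
  colnames(V) <- paste0("PC", seq_len(m))
  rownames(scores) <- rownames(flat)
  structure(list(mean_vector = mu, components = V, eigenvalues = ev,
                 scores = scores, variance_fraction = ev / sum(ev),
                 K = K, n = n),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cum <- cumsum(x$variance_fraction)
  cat("<shape_space> ", x$n, " samples, ", x$K, " landmarks, ",
      length(x$eigenvalues), " components\n", sep = "")
  cat(sprintf("  first 3 PCs: %.2f%% of variance; %d PCs reach 75%%\n",
              100 * cum[min(3L, length(cum))],
              which(cum >= 0.75)[1L]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.shape_space <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fraction,
                 cumulative = cumsum(x$variance_fraction))
}

#' @exportS3Method generics::glance
glance.shape_space <- function(x, ...) {
  cum <- cumsum(x$variance_fraction)
  tibble::tibble(n = x$n, k_landmarks = x$K,
                 n_components = length(x$eigenvalues),
                 var_first3 = cum[min(3L, length(cum))],
                 n_pcs_75 = as.integer(which(cum >= 0.75)[1L]))
}

#' PC score table
#'
#' @param space a `shape_space`.
#' @param n_pcs how many leading components to keep.
#' @return Tibble `sample_id, PC1..PCm`.
#' @export
score_table <- function(space, n_pcs = ncol(space$scores)) {
  n_pcs <- min(n_pcs, ncol(space$scores))
  s <- space$scores[, seq_len(n_pcs), drop = FALSE]
  tibble::as_tibble(cbind(
    tibble::tibble(sample_id = rownames(s) %||% as.character(seq_len(nrow(s)))),
    tibble::as_tibble(s)))
}

#' Reconstruct configurations from PC scores
#'
#' @param space a `shape_space`.
#' @param scores score matrix (defaults to the fitted scores).
#' @return n x K x 3 array.
#' @export
reconstruct_shapes <- function(space, scores = space$scores) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  flat <- sweep(scores %*% t(space$components[, seq_len(m), drop = FALSE]),
                2L, space$mean_vector, `+`)
  aperm(array(flat, c(nrow(flat), 3L, space$K)), c(1L, 3L, 2L))
}

#' Group mean shapes
#'
#' Arithmetic per-group mean of aligned coordinates, for comparing the DMV
#' and easy-ventilation groups.
#'
#' @param aligned a `gpa_fit`, n x K x 3 array, or list of K x 3 matrices.
#' @param labels logical (or two-level) vector of length n.
#' @return List with `positive` and `negative` K x 3 mean shapes.
#' @export
group_mean_shapes <- function(aligned, labels) {
  if (inherits(aligned, "gpa_fit")) aligned <- aligned$aligned
  a <- unclass(aligned)
  labels <- as.logical(labels)
  if (length(labels) != dim(a)[1L]) stop("labels length must match samples")
  if (!any(labels) || all(labels))
    stop("both groups must be non-empty")
  list(positive = apply(a[labels, , , drop = FALSE], c(2L, 3L), mean),
       negative = apply(a[!labels, , , drop = FALSE], c(2L, 3L), mean))
}

#' Per-vertex distance map between two mean shapes
#'
#' Euclidean distance of each corresponding vertex pair; symmetric in its
#' arguments. Exportable as a scalar field on the reference mesh for
#' heat-map style rendering.
#'
#' @param shape_a,shape_b K x 3 matrices with equal K.
#' @return Numeric vector of K distances.
#' @export
distance_map <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a); shape_b <- as.matrix(shape_b)
  if (!all(dim(shape_a) == dim(shape_b)))
    stop("shapes must have matching K")
  sqrt(rowSums((shape_a - shape_b)^2))
}
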