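# Full Procrustes superimposition of quasi-landmark configurations:
# translation removed by centring, size by scaling to unit centroid size,
# orientation by proper least-squares rotation. GPA iterates alignment to an
# evolving mean until the mean stabilises.

#' Centroid size of a configuration
#'
#' Root summed squared distances of the K points from their centroid, the
#' size measure removed by full Procrustes scaling.
#'
#' @param x K x 3 matrix.
#' @return Positive scalar (mm).
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  sqrt(sum(scale(x, scale = FALSE)^2))
}

# centre and scale to unit centroid size
normalize_config <- function(x) {
  x <- as.matrix(x)
  cs <- centroid_size(x)
  if (cs < 1e-12) stop("zero centroid size: degenerate configuration")
  xc <- scale(x, scale = FALSE)
  attr(xc, "scaled:center") <- NULL
  structure(xc / cs, centroid_size = cs)
}

# proper rotation R minimising ||a %*% R - b||_F
optimal_rotation <- function(a, b) {
  sv <- svd(crossprod(a, b))
  D <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
  sv$u %*% D %*% t(sv$v)
}

#' Ordinary (pairwise) Procrustes superimposition
#'
#' Centres both configurations, scales each to unit centroid size, and
#' rotates `a` by the proper rotation minimising the summed squared
#' differences to `b`. The returned distance is the residual
#' root-sum-of-squares (the full Procrustes distance between the shapes).
#'
#' @param a,b K x 3 configurations with equal K.
#' @return List with `aligned_a`, `aligned_b` (normalised b), `rotation`,
#'   and `distance`.
#' @export
ordinary_procrustes <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("configurations must have equal K")
  an <- normalize_config(a)
  bn <- normalize_config(b)
  R <- optimal_rotation(an, bn)
  ar <- an %*% R
  list(aligned_a = ar, aligned_b = bn, rotation = R,
       distance = sqrt(sum((ar - bn)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Iteratively aligns every configuration to the current mean shape,
#' recomputes the mean, and renormalises it to unit centroid size, until the
#' RMS change of the mean's coordinates falls below `tol`. The global
#' orientation (which GPA leaves arbitrary) is fixed by rotating the final
#' mean onto the first sample's normalised configuration, so results are
#' deterministic and order-stable up to that gauge.
#'
#' @param configs n x K x 3 array (e.g. a `landmark_array`) or list of K x 3
#'   matrices, n >= 2.
#' @param tol convergence tolerance on mean-coordinate RMS change.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   best result so far.
#' @return A `gpa_fit`: list with `aligned` (n x K x 3, unit centroid size,
#'   centred), `mean_shape` (K x 3, unit centroid size), `centroid_sizes`
#'   (mm), `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100L) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    ids <- dimnames(configs)[[1L]]
    configs <- lapply(seq_len(dim(configs)[1L]),
                      function(i) unclass(configs)[i, , ])
  } else ids <- names(configs)
  n <- length(configs)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  K <- nrow(configs[[1L]])
  if (any(vapply(configs, nrow, 0L) != K)) stop("configurations differ in K")

  norm <- lapply(configs, normalize_config)
  sizes <- vapply(norm, attr, 0, "centroid_size")
  mean_shape <- norm[[1L]]
  aligned <- norm
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(norm, function(x) x %*% optimal_rotation(x, mean_shape))
    new_mean <- Reduce(`+`, aligned) / n
    new_mean <- normalize_config(new_mean)
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations; returning current state")
  # orientation gauge: mean rotated onto the first normalised sample
  gauge <- optimal_rotation(mean_shape, norm[[1L]])
  mean_shape <- mean_shape %*% gauge
  aligned <- lapply(norm, function(x) x %*% optimal_rotation(x, mean_shape))

  arr <- array(NA_real_, c(n, K, 3L),
               dimnames = list(ids, NULL, c("x", "y", "z")))
  for (i in seq_len(n)) arr[i, , ] <- aligned[[i]]
  structure(list(aligned = arr,
                 mean_shape = structure(mean_shape, centroid_size = NULL),
                 centroid_sizes = sizes, iterations = it,
                 converged = converged),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("<gpa_fit> ", dim(x$aligned)[1L], " configurations of ",
      dim(x$aligned)[2L], " landmarks; ", x$iterations, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gpa_fit <- function(x, ...) {
  res <- sweep(unclass(x$aligned), c(2L, 3L), x$mean_shape)
  tibble::tibble(n = dim(x$aligned)[1L], k_landmarks = dim(x$aligned)[2L],
                 iterations = x$iterations, converged = x$converged,
                 mean_centroid_size = mean(x$centroid_sizes),
                 rss_to_mean = sum(res^2))
}

#' Export a mean shape as a mesh
#'
#' Scales the unit-size mean shape back to a physical size (by default the
#' cohort's mean centroid size) and attaches the reference faces, so the
#' mean face can be written as OBJ.
#'
#' @param fit a `gpa_fit`, or a K x 3 mean shape matrix.
#' @param reference a [mesh3] whose faces to reuse (K must match).
#' @param size target centroid size in mm.
#' @return A [mesh3].
#' @export
mean_shape_mesh <- function(fit, reference, size = NULL) {
  shape <- if (inherits(fit, "gpa_fit")) fit$mean_shape else as.matrix(fit)
  if (is.null(size))
    size <- if (inherits(fit, "gpa_fit")) mean(fit$centroid_sizes) else 1
  if (nrow(shape) != nrow(reference$vertices))
    stop("mean shape K does not match the reference mesh")
  mesh3(shape * size, reference$faces)
}
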