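# Anchor-initialised similarity alignment, rigid ICP and smoothed non-rigid
# registration of a reference mesh onto target scans. The output of the
# non-rigid stage is a quasi-landmark configuration: the reference vertices
# deformed onto the scan surface, so vertex i means the same anatomical
# location on every scan registered with the same reference.

#' Similarity transform container
#'
#' `x_new = scale * x %*% t(rotation) + translation`, rotation always proper
#' (determinant +1; reflections are never produced).
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param scale positive scalar.
#' @param translation length-3 vector.
#' @return An object of class `similarity3`.
#' @export
similarity3 <- function(rotation = diag(3), scale = 1,
                        translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            scale > 0)
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity3")
}

#' Apply a similarity transform to points
#' @param tf a [similarity3].
#' @param x n x 3 matrix of points.
#' @return Transformed n x 3 matrix.
#' @export
apply_similarity <- function(tf, x) {
  stopifnot(inherits(tf, "similarity3"))
  x <- as.matrix(x)
  tf$scale * x %*% t(tf$rotation) +
    matrix(tf$translation, nrow(x), 3L, byrow = TRUE)
}

#' @export
print.similarity3 <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<similarity3> scale %.4f, rotation %.2f deg, |t| %.2f mm\n",
              x$scale, ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

# weighted least-squares similarity (Umeyama): maps x onto y
fit_similarity <- function(x, y, w = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  if (sw <= 0) stop("no correspondences with positive weight")
  mx <- colSums(x * w) / sw
  my <- colSums(y * w) / sw
  xc <- sweep(x, 2L, mx); yc <- sweep(y, 2L, my)
  S <- crossprod(yc * w, xc) / sw           # 3x3 cross-covariance
  sv <- svd(S)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    stop("degenerate point set (collinear or coincident anchors)")
  D <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- sum(w * rowSums(xc^2)) / sw
  s <- sum(diag(D) * sv$d) / var_x
  similarity3(R, s, my - s * drop(R %*% mx))
}

#' Least-squares similarity initialisation from anchor landmarks
#'
#' Computes the similarity transform (proper rotation, uniform scale,
#' translation) minimising the sum of squared distances between the
#' reference anchors mapped into the target and the target anchors.
#'
#' @param ref_anchors,target_anchors anchor tables ([anchor_set()]) or 8 x 3
#'   matrices in the fixed anchor order.
#' @return A [similarity3].
#' @export
initialize_similarity <- function(ref_anchors, target_anchors) {
  fit_similarity(anchor_matrix(ref_anchors), anchor_matrix(target_anchors))
}

#' Registration parameters
#'
#' Defaults follow a MeshMonk-like schedule: 30 rigid ICP iterations, 80
#' non-rigid iterations with stiffness annealed linearly from 100 to 1,
#' 3-neighbour correspondence search, outliers beyond 3x the median
#' correspondence distance downweighted to zero, convergence at 0.01 mm mean
#' displacement.
#'
#' @param rigid_iterations,nonrigid_iterations iteration budgets (>= 1).
#' @param k_neighbors nearest target vertices shortlisted before exact
#'   point-to-triangle projection.
#' @param stiffness_start,stiffness_end dimensionless smoothing weights,
#'   `start >= end > 0`.
#' @param inlier_kappa multiplier of the median distance beyond which a
#'   correspondence gets zero weight.
#' @param convergence_tol mean displacement (mm) under which iteration stops.
#' @return A `registration_params` list.
#' @export
registration_params <- function(rigid_iterations = 30L,
                                nonrigid_iterations = 80L,
                                k_neighbors = 3L,
                                stiffness_start = 100,
                                stiffness_end = 1,
                                inlier_kappa = 3,
                                convergence_tol = 0.01) {
  stopifnot(rigid_iterations >= 1, nonrigid_iterations >= 1, k_neighbors >= 1,
            stiffness_start >= stiffness_end, stiffness_end > 0,
            inlier_kappa > 0, convergence_tol > 0)
  structure(list(rigid_iterations = as.integer(rigid_iterations),
                 nonrigid_iterations = as.integer(nonrigid_iterations),
                 k_neighbors = as.integer(k_neighbors),
                 stiffness_start = stiffness_start,
                 stiffness_end = stiffness_end,
                 inlier_kappa = inlier_kappa,
                 convergence_tol = convergence_tol),
            class = "registration_params")
}

# closest points on a batch of triangles to a single point p
# (Ericson's region classification, vectorised over triangles)
closest_on_triangles <- function(p, A, B, C) {
  t <- nrow(A)
  P <- matrix(p, t, 3L, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B; d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C; d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, t, 3L)
  done <- rep(FALSE, t)
  setrows <- function(cond, val) {
    sel <- cond & !done
    if (any(sel)) out[sel, ] <<- val[sel, , drop = FALSE]
    done <<- done | cond
  }
  setrows(d1 <= 0 & d2 <= 0, A)
  setrows(d3 >= 0 & d4 <= d3, B)
  w_ab <- d1 / (d1 - d3)
  setrows(vc <= 0 & d1 >= 0 & d3 <= 0, A + w_ab * ab)
  setrows(d6 >= 0 & d5 <= d6, C)
  w_ac <- d2 / (d2 - d6)
  setrows(vb <= 0 & d2 >= 0 & d6 <= 0, A + w_ac * ac)
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  setrows(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + w_bc * (C - B))
  denom <- va + vb + vc
  inner <- A + (vb / denom) * ab + (vc / denom) * ac
  setrows(!done, inner)
  out
}

#' Closest surface points on a mesh
#'
#' For each query point, shortlists the `k` nearest mesh vertices, then
#' projects onto every triangle incident to them and keeps the nearest
#' projection. Falls back to nearest vertices when the mesh has no faces.
#'
#' @param points n x 3 query matrix.
#' @param mesh a [mesh3].
#' @param k shortlist size.
#' @return List with `points` (n x 3 closest surface points) and `distance`.
#' @export
closest_point_on_mesh <- function(points, mesh, k = 3L) {
  points <- as.matrix(points)
  V <- mesh$vertices
  n <- nrow(points)
  # brute-force squared distances in one BLAS call
  D2 <- outer(rowSums(points^2), rowSums(V^2), `+`) - 2 * tcrossprod(points, V)
  if (nrow(mesh$faces) == 0L) {
    j <- max.col(-D2, ties.method = "first")
    cp <- V[j, , drop = FALSE]
    return(list(points = cp, distance = sqrt(rowSums((cp - points)^2))))
  }
  F <- mesh$faces
  vert_faces <- split(rep(seq_len(nrow(F)), 3L), as.vector(F))
  k <- min(k, nrow(V))
  cp <- matrix(NA_real_, n, 3L)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    nn <- order(D2[i, ])[seq_len(k)]
    fids <- unique(unlist(vert_faces[as.character(nn)], use.names = FALSE))
    if (length(fids) == 0L) {           # isolated vertices only
      j <- nn[1L]
      cp[i, ] <- V[j, ]
      dist[i] <- sqrt(max(D2[i, j], 0))
      next
    }
    tri <- F[fids, , drop = FALSE]
    cand <- closest_on_triangles(points[i, ],
                                 V[tri[, 1L], , drop = FALSE],
                                 V[tri[, 2L], , drop = FALSE],
                                 V[tri[, 3L], , drop = FALSE])
    d2 <- rowSums(sweep(cand, 2L, points[i, ])^2)
    b <- which.min(d2)
    cp[i, ] <- cand[b, ]
    dist[i] <- sqrt(d2[b])
  }
  list(points = cp, distance = dist)
}

#' Rigid (similarity) ICP refinement
#'
#' Iterates closest-surface-point correspondence, outlier downweighting
#' (zero weight beyond `inlier_kappa` times the median distance), and a
#' weighted least-squares similarity fit. Returns the iterate with the
#' smallest mean correspondence distance, so the result is never worse than
#' the initial transform.
#'
#' @param ref,target [mesh3] reference and target.
#' @param init initial [similarity3], e.g. from [initialize_similarity()].
#' @param params a [registration_params()].
#' @return A [similarity3] with attribute `mean_distance`.
#' @export
rigid_icp <- function(ref, target, init = similarity3(),
                      params = registration_params()) {
  tf <- init
  X0 <- ref$vertices
  best <- NULL; best_d <- Inf; prev_d <- Inf
  for (it in seq_len(params$rigid_iterations + 1L)) {
    X <- apply_similarity(tf, X0)
    cp <- closest_point_on_mesh(X, target, params$k_neighbors)
    d <- mean(cp$distance)
    if (d < best_d) { best_d <- d; best <- tf }
    if (it > params$rigid_iterations ||
        abs(prev_d - d) < params$convergence_tol) break
    prev_d <- d
    w <- as.numeric(cp$distance <= params$inlier_kappa *
                      max(stats::median(cp$distance), 1e-12))
    if (!any(w > 0)) stop("no inlier correspondences found")
    tf <- fit_similarity(X0, cp$points, w)
  }
  attr(best, "mean_distance") <- best_d
  best
}

# uniform graph Laplacian of the mesh's vertex neighbourhood graph
mesh_laplacian <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(1L, 3L)])
  e <- unique(rbind(e, e[, 2:1]))
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = 1, dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Non-rigid registration producing quasi-landmarks
#'
#' Starting from the rigidly aligned reference, each iteration pulls every
#' reference vertex toward its closest point on the target surface and
#' smooths the pull field over the reference's vertex neighbourhood graph by
#' solving `(I + lambda L) U_s = U`, with the stiffness `lambda` annealed
#' linearly from `stiffness_start` to `stiffness_end`. High stiffness moves
#' the surface near-rigidly (in the limit only the mean translation of the
#' pull survives); low stiffness lets it track local detail. Correspondences
#' beyond `inlier_kappa` times the median distance contribute nothing.
#'
#' @param ref,target [mesh3] reference and target.
#' @param rigid the rigid-stage [similarity3].
#' @param params a [registration_params()].
#' @return A `quasi_landmarks` K x 3 matrix (K = reference vertex count) with
#'   attributes `mean_distance` and `iterations`.
#' @export
nonrigid_register <- function(ref, target, rigid = similarity3(),
                              params = registration_params()) {
  X <- apply_similarity(rigid, ref$vertices)
  L <- mesh_laplacian(ref)
  n_it <- params$nonrigid_iterations
  lam <- if (n_it == 1L) params$stiffness_end else
    seq(params$stiffness_start, params$stiffness_end, length.out = n_it)
  I <- Matrix::Diagonal(nrow(X))
  TV <- target$vertices
  dmin <- Inf; grow <- 0L; iters <- 0L
  for (it in seq_len(n_it)) {
    # forward pull: each reference vertex toward its closest surface point
    cp <- closest_point_on_mesh(X, target, params$k_neighbors)
    d <- mean(cp$distance)
    # diverged: far above the best fit seen, repeatedly (transient rises
    # while the stiffness anneals and the pulls rebalance are tolerated)
    if (d > 1.5 * dmin) {
      grow <- grow + 1L
      if (grow >= 3L)
        stop(sprintf(paste0("non-rigid registration diverged at iteration ",
                            "%d (mean distance %.4f mm, rising)"), it, d))
    } else grow <- 0L
    dmin <- min(dmin, d)
    U <- cp$points - X
    w <- as.numeric(cp$distance <= params$inlier_kappa *
                      max(stats::median(cp$distance), 1e-12))
    U <- U * w
    # symmetric (backward) pull: each target vertex drags its nearest
    # deformed-reference vertex, so target regions not yet covered by the
    # reference still attract it instead of being skipped over
    D2 <- outer(rowSums(TV^2), rowSums(X^2), `+`) - 2 * tcrossprod(TV, X)
    nn <- max.col(-D2, ties.method = "first")
    bd <- sqrt(pmax(D2[cbind(seq_len(nrow(TV)), nn)], 0))
    keep <- bd <= params$inlier_kappa * max(stats::median(bd), 1e-12)
    pulls <- rowsum((TV - X[nn, , drop = FALSE]) * keep, nn)
    cnt <- rowsum(as.numeric(keep), nn)
    Ub <- matrix(0, nrow(X), 3L)
    ridx <- as.integer(rownames(pulls))          # aligned with cnt rows
    Ub[ridx, ] <- pulls / pmax(cnt[, 1L], 1)
    has_b <- ridx[cnt[, 1L] > 0]
    U[has_b, ] <- 0.5 * (U[has_b, , drop = FALSE] +
                           Ub[has_b, , drop = FALSE])
    Us <- as.matrix(Matrix::solve(I + lam[it] * L, U))
    X <- X + Us
    iters <- it
    if (mean(sqrt(rowSums(Us^2))) < params$convergence_tol) break
  }
  cp <- closest_point_on_mesh(X, target, params$k_neighbors)
  structure(X, class = c("quasi_landmarks", "matrix"),
            mean_distance = mean(cp$distance), iterations = iters)
}

#' Register a reference onto every scan of a cohort
#'
#' In `"full"` mode each scan goes through anchor-initialised similarity,
#' rigid ICP and non-rigid registration. In `"corresponded"` mode the scans
#' are taken to be already in vertex-wise correspondence with the reference
#' (as synthetic cohorts with `resample = FALSE` are by construction) and the
#' scan vertices are used directly; this is the fast path for simulation
#' studies, where registration would only re-estimate a known correspondence.
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `scans` and
#'   `anchors`.
#' @param reference reference [mesh3]; defaults to the cohort template mesh.
#' @param ref_anchors reference anchor table; defaults to template anchors.
#' @param params a [registration_params()].
#' @param mode `"full"` or `"corresponded"`.
#' @return n x K x 3 array of quasi-landmark configurations (class
#'   `landmark_array`), dimnames carrying subject ids when available.
#' @export
register_cohort <- function(cohort, reference = NULL, ref_anchors = NULL,
                            params = registration_params(),
                            mode = c("full", "corresponded")) {
  mode <- match.arg(mode)
  if (inherits(cohort, "synthetic_cohort")) {
    if (is.null(reference)) reference <- cohort$template$mesh
    if (is.null(ref_anchors))
      ref_anchors <- anchor_set(
        reference$vertices[cohort$template$anchor_idx, , drop = FALSE])
  }
  scans <- cohort$scans
  anchors <- cohort$anchors
  n <- length(scans)
  ids <- if (!is.null(cohort$covariates$subject)) cohort$covariates$subject
         else sprintf("S%04d", seq_len(n))
  if (mode == "corresponded") {
    K <- nrow(scans[[1L]]$vertices)
    bad <- which(vapply(scans, function(s) nrow(s$vertices), 0L) != K)
    if (length(bad))
      stop("corresponded mode needs equal vertex counts; scan ", bad[1L],
           " differs")
    out <- array(NA_real_, c(n, K, 3L), dimnames = list(ids, NULL, c("x", "y", "z")))
    for (i in seq_len(n)) out[i, , ] <- scans[[i]]$vertices
    class(out) <- "landmark_array"
    return(out)
  }
  stopifnot(!is.null(reference), !is.null(ref_anchors))
  K <- nrow(reference$vertices)
  out <- array(NA_real_, c(n, K, 3L), dimnames = list(ids, NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    init <- initialize_similarity(ref_anchors, anchors[[i]])
    rig <- rigid_icp(reference, scans[[i]], init, params)
    out[i, , ] <- nonrigid_register(reference, scans[[i]], rig, params)
  }
  class(out) <- "landmark_array"
  out
}

#' Write / read a cohort landmark array as CSV
#'
#' One row per scan, columns `x1,y1,z1,...` in reference vertex order.
#'
#' @param configs an n x K x 3 `landmark_array`.
#' @param path CSV path.
#' @return `path` invisibly; [read_configs()] returns the array.
#' @export
write_configs <- function(configs, path) {
  n <- dim(configs)[1L]; K <- dim(configs)[2L]
  flat <- matrix(aperm(unclass(configs), c(1L, 3L, 2L)), n, 3L * K)
  colnames(flat) <- paste0(rep(c("x", "y", "z"), K), rep(seq_len(K), each = 3L))
  df <- data.frame(subject = dimnames(configs)[[1L]] %||% sprintf("S%04d", 1:n),
                   flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_configs
#' @export
read_configs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  K <- ncol(m) / 3L
  stopifnot(K == round(K))
  out <- aperm(array(m, c(nrow(m), 3L, K)), c(1L, 3L, 2L))
  dimnames(out) <- list(ids, NULL, c("x", "y", "z"))
  class(out) <- "landmark_array"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
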