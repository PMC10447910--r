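# Programmatic fixtures: tiny meshes, random configurations, and a
# synthetic stand-in reference mesh with a prescribed vertex count.

tetra_mesh <- function() {
  mesh3(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
        rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

rand_config <- function(k, seed = NULL, scale = 10) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(3 * k, sd = scale), k, 3L)
}

rand_rotation <- function() {
  qr_r <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

apply_rand_similarity <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- rand_rotation()
  s <- exp(stats::runif(1, -0.3, 0.3))
  t <- stats::rnorm(3, sd = 20)
  s * as.matrix(x) %*% t(R) + rep(t, each = nrow(x))
}

# synthetic stand-in for a cleaned facial reference mesh with an exact
# vertex count: an ellipsoidal grid patch trimmed to n vertices
synth_reference_mesh <- function(n_vertices = 9578L) {
  r <- as.integer(ceiling(sqrt(n_vertices)))
  g <- seq(-1, 1, length.out = r)
  u <- rep(g, times = r); v <- rep(g, each = r)
  verts <- cbind(60 * u, 85 * v, 45 * sqrt(pmax(0, 1 - 0.8 * u^2 - 0.5 * v^2)))
  i <- rep(seq_len(r - 1L), times = r - 1L)
  j <- rep(seq_len(r - 1L), each = r - 1L)
  a <- (j - 1L) * r + i; b <- a + 1L; cc <- a + r; d <- cc + 1L
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))
  keep_f <- faces[, 1L] <= n_vertices & faces[, 2L] <= n_vertices &
    faces[, 3L] <= n_vertices
  mesh3(verts[seq_len(n_vertices), , drop = FALSE],
        faces[keep_f, , drop = FALSE])
}

write_obj_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obj",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small cohort used by several registration and shape tests
small_cohort <- function(n = 8L, seed = 7L, resolution = 14L, ...) {
  tmpl <- make_template(resolution)
  spec <- population_spec(n_subjects = n, seed = seed, ...)
  list(template = tmpl, cohort = sample_cohort(tmpl, spec))
}
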