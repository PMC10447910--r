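fast_params <- registration_params(rigid_iterations = 15L,
                                   nonrigid_iterations = 40L)

test_that("anchor similarity initialisation recovers exact transforms", {
  a <- anchor_set(rand_config(8, seed = 1))
  expect_s3_class(initialize_similarity(a, a), "similarity3")
  id <- initialize_similarity(a, a)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$scale, 1, tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-8)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  b <- anchor_set(as.matrix(a[, c("x", "y", "z")]) %*% t(R) +
                    rep(c(5, 0, 0), each = 8))
  tf <- initialize_similarity(a, b)
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$scale, 1, tolerance = 1e-9)
  expect_equal(tf$translation, c(5, 0, 0), tolerance = 1e-9)
  am <- function(x) cbind(x$x, x$y, x$z)
  expect_equal(apply_similarity(tf, am(a)), am(b),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("anchor initialisation matches a rotation-grid least-squares search", {
  for (s in 1:3) {
    x <- rand_config(8, seed = s)
    y <- apply_rand_similarity(x, seed = s + 100) +
      matrix(stats::rnorm(24, sd = 0.5), 8)
    tf <- initialize_similarity(anchor_set(x), anchor_set(y))
    res <- sqrt(sum((apply_similarity(tf, x) - y)^2))
    res_grid <- similarity_residual_grid(x, y)
    expect_lte(res, res_grid + 1e-3)
    expect_equal(res, res_grid, tolerance = 1e-2)
  }
})

test_that("degenerate anchors are rejected", {
  line <- cbind(1:8, 0, 0)
  expect_error(initialize_similarity(anchor_set(line), anchor_set(line)),
               "degenerate")
})

test_that("closest_point_on_mesh projects onto the surface exactly", {
  m <- tetra_mesh()
  # a point on a face centroid maps to itself
  cen <- colMeans(m$vertices[c(1, 2, 3), ])
  got <- closest_point_on_mesh(rbind(cen), m)
  expect_equal(got$distance, 0, tolerance = 1e-12)
  # a point above a face projects orthogonally (face z = 0)
  got2 <- closest_point_on_mesh(rbind(c(0.2, 0.2, -1)), m)
  expect_equal(got2$points[1, ], c(0.2, 0.2, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(got2$distance, 1, tolerance = 1e-12)
  # beyond a vertex the vertex is closest
  got3 <- closest_point_on_mesh(rbind(c(-1, -1, -1)), m)
  expect_equal(got3$points[1, ], c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rigid ICP is a fixed point on an exact copy", {
  m <- make_template(12L)$mesh
  tf <- rigid_icp(m, m, similarity3(), fast_params)
  expect_lt(attr(tf, "mean_distance"), 1e-8)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-8)
})

test_that("rigid ICP recovers a known similarity transform", {
  tmpl <- make_template(14L)
  m <- tmpl$mesh
  set.seed(21)
  R <- rand_rotation()
  s <- 1.05; tr <- c(8, -5, 12)
  target <- mesh3(s * m$vertices %*% t(R) + rep(tr, each = nrow(m$vertices)),
                  m$faces)
  a_ref <- anchor_set(m$vertices[tmpl$anchor_idx, ])
  a_tgt <- anchor_set(apply_similarity(similarity3(R, s, tr),
                                       m$vertices[tmpl$anchor_idx, ]))
  tf <- rigid_icp(m, target, initialize_similarity(a_ref, a_tgt), fast_params)
  expect_equal(tf$rotation, R, tolerance = 1e-3)
  expect_equal(tf$scale, s, tolerance = 1e-3)
  expect_lt(mean(sqrt(rowSums(
    (apply_similarity(tf, m$vertices) - target$vertices)^2))), 1e-2)
})

test_that("outlier downweighting improves transform recovery", {
  tmpl <- make_template(12L)
  m <- tmpl$mesh
  set.seed(33)
  th <- 20 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  target <- mesh3(m$vertices %*% t(R), m$faces)
  # corrupt 5% of the *reference* vertices: their nearest surface points sit
  # ~50 mm away and drag an unweighted fit, but are gated by the inlier rule
  ref_v <- m$vertices
  out_idx <- sample(nrow(ref_v), round(0.05 * nrow(ref_v)))
  ref_v[out_idx, ] <- ref_v[out_idx, ] + 50
  ref <- mesh3(ref_v, m$faces)
  clean <- setdiff(seq_len(nrow(ref_v)), out_idx)
  truth <- m$vertices[clean, ] %*% t(R)
  err_for <- function(kap) {
    tf <- rigid_icp(ref, target, similarity3(),
                    registration_params(rigid_iterations = 15L,
                                        inlier_kappa = kap))
    mean(sqrt(rowSums((apply_similarity(tf, m$vertices[clean, ]) -
                         truth)^2)))
  }
  expect_lt(err_for(3), 0.5 * err_for(1e9))
})

test_that("non-rigid registration of a mesh to itself is a fixed point", {
  m <- make_template(12L)$mesh
  q <- nonrigid_register(m, m, similarity3(), fast_params)
  expect_equal(unclass(q)[, ], m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("non-rigid registration recovers known smooth deformations", {
  tmpl <- make_template(14L)
  spec <- population_spec(n_subjects = 2L, noise_sd = 0.5,
                          rigid_jitter = list(rot_deg = 10, trans_mm = 10,
                                              log_scale = c(0, 0)),
                          seed = 9L)
  co <- sample_cohort(tmpl, spec)
  for (i in 1:2) {
    scan <- co$scans[[i]]
    init <- initialize_similarity(
      anchor_set(tmpl$mesh$vertices[tmpl$anchor_idx, ]), co$anchors[[i]])
    rig <- rigid_icp(tmpl$mesh, scan, init, fast_params)
    q <- nonrigid_register(tmpl$mesh, scan, rig, fast_params)
    gt <- co$configs[i, , ]
    # the surface itself is matched at the noise scale ...
    expect_lt(attr(q, "mean_distance"), 2 * spec$noise_sd)
    # ... and the recovered correspondence is sub-cell: tangential position
    # is only identifiable up to a fraction of the vertex spacing from
    # geometry alone
    e1 <- sqrt(rowSums((scan$vertices[scan$faces[, 1L], ] -
                          scan$vertices[scan$faces[, 2L], ])^2))
    rms <- sqrt(mean(rowSums((unclass(q) - gt)^2)))
    expect_lt(rms, 0.35 * stats::median(e1))
    # non-rigid fits the surface at least as well as rigid alone
    expect_lte(attr(q, "mean_distance"),
               attr(rig, "mean_distance") + 1e-9)
    expect_equal(nrow(q), nrow(tmpl$mesh$vertices))
  }
})

test_that("an infinitely stiff non-rigid stage stays at the rigid result", {
  tmpl <- make_template(12L)
  m <- tmpl$mesh
  set.seed(4)
  R <- rand_rotation()
  target <- mesh3(m$vertices %*% t(R), m$faces)
  rig <- rigid_icp(m, target, similarity3(R), fast_params)
  stiff <- registration_params(nonrigid_iterations = 10L,
                               stiffness_start = 1e9, stiffness_end = 1e9)
  q <- nonrigid_register(m, target, rig, stiff)
  rigid_only <- apply_similarity(rig, m$vertices)
  # identical up to (at most) a tiny global translation
  drift <- sweep(unclass(q), 2L, colMeans(unclass(q) - rigid_only)) -
    rigid_only
  expect_lt(max(abs(drift)), 1e-4)
  expect_lt(sqrt(sum(colMeans(unclass(q) - rigid_only)^2)), 0.1)
})

test_that("cohort registration conserves K and correspondence", {
  sc <- small_cohort(n = 4L, resolution = 12L)
  configs <- register_cohort(sc$cohort, mode = "corresponded")
  expect_equal(dim(configs), c(4L, 12L^2, 3L))
  # corresponded mode returns the scans' own vertices
  expect_equal(unclass(configs)[2L, , ], sc$cohort$scans[[2L]]$vertices,
               ignore_attr = TRUE)
})

test_that("configuration CSVs round-trip", {
  sc <- small_cohort(n = 3L, resolution = 10L)
  configs <- register_cohort(sc$cohort, mode = "corresponded")
  p <- withr::local_tempfile(fileext = ".csv")
  write_configs(configs, p)
  back <- read_configs(p)
  expect_equal(unclass(back), unclass(configs), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the choice of reference template barely moves downstream AUC", {
  tmpl_a <- make_template(13L)
  tmpl_b <- make_template(14L)
  spec <- population_spec(n_subjects = 60L, prevalence = 0.35,
                          effect_size = 3, seed = 17L)
  co <- sample_cohort(tmpl_a, spec)
  params <- registration_params(rigid_iterations = 10L,
                                nonrigid_iterations = 30L)
  auc_for <- function(tmpl) {
    ra <- anchor_set(tmpl$mesh$vertices[tmpl$anchor_idx, ])
    n <- length(co$scans)
    arr <- array(NA_real_, c(n, nrow(tmpl$mesh$vertices), 3L))
    for (i in seq_len(n)) {
      init <- initialize_similarity(ra, co$anchors[[i]])
      rig <- rigid_icp(tmpl$mesh, co$scans[[i]], init, params)
      arr[i, , ] <- nonrigid_register(tmpl$mesh, co$scans[[i]], rig, params)
    }
    space <- fit_pca(gpa(arr))
    roc_auc(loocv_lda_scores(space$scores, co$labels, 3L), co$labels)
  }
  expect_lt(abs(auc_for(tmpl_a) - auc_for(tmpl_b)), 0.05)
})
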