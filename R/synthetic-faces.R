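# Synthetic facial surfaces with known low-rank shape structure.
#
# The face is a closed-form parametric surface over (u, v) in [-1, 1]^2:
# a half-ellipsoid depth field with a nose bump and a protruding lower
# ("mandibular") lobe. Shape variation enters as smooth z-displacement
# fields evaluated at any (u, v), so scans can be resampled on jittered
# grids while the underlying subject shape stays well defined.

# base geometry in mm: x lateral (+x = subject's left), y vertical, z anterior
face_surface <- function(u, v) {
  x <- 60 * u
  y <- 85 * v
  z <- 45 * sqrt(pmax(0, 1 - 0.85 * u^2 - 0.55 * v^2))
  z <- z + 12 * exp(-((u / 0.12)^2 + ((v - 0.05) / 0.18)^2))     # nose
  z <- z + 14 * exp(-((u / 0.45)^2 + ((v + 0.75) / 0.18)^2))     # jaw lobe
  cbind(x = x, y = y, z = z)
}

# membership predicate and displacement field of the mandibular region;
# the field is windowed to the mask so a group effect is strictly local
mandible_mask_uv <- function(u, v) v < -0.45 & abs(u) < 0.62

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

mandible_field <- function(u, v) {
  # a region-wide displacement plateau: the case-control contrast moves the
  # whole mandibular region, rolling smoothly to zero at the mask edges so
  # the field is continuous and supported exactly on the mask
  smoothstep((0.62 - abs(u)) / 0.18) * smoothstep((-0.45 - v) / 0.18)
}

# smooth variation modes, unit peak amplitude; mode 3 is the mandibular field
# so that a case-control displacement there lives inside the span of the
# population modes (and hence of the leading principal components)
mode_field <- function(k, u, v) {
  switch(as.character(k),
    "1" = exp(-((u / 0.9)^2 + (v / 0.9)^2)),
    "2" = exp(-((u / 0.5)^2 + ((v - 0.45) / 0.3)^2)),
    "3" = mandible_field(u, v),
    {
      extra <- matrix(c(-0.5, 0.2, 0.5, 0.2, -0.35, -0.25, 0.35, -0.25,
                        0, 0.7), ncol = 2L, byrow = TRUE)
      j <- k - 3L
      if (j > nrow(extra)) stop("at most ", nrow(extra) + 3L, " modes supported")
      exp(-(((u - extra[j, 1L]) / 0.3)^2 + ((v - extra[j, 2L]) / 0.3)^2))
    }
  )
}

# anchor targets in (u, v), fixed digitisation order; right = -x
anchor_uv_targets <- function() {
  matrix(c(0, 0.05,      # pronasale
           -1, 0.05,     # right earlobe
           1, 0.05,      # left earlobe
           -0.28, -0.42, # right cheilion
           0.28, -0.42,  # left cheilion
           0, -0.68,     # tip of chin
           0, -0.85,     # hyoid bone
           0, -0.97),    # thyroid notch
         ncol = 2L, byrow = TRUE)
}

grid_uv <- function(r) {
  g <- seq(-1, 1, length.out = r)
  list(u = rep(g, times = r), v = rep(g, each = r))
}

grid_faces <- function(r) {
  # two triangles per grid cell; vertex (i, j) has index (j-1)*r + i
  i <- rep(seq_len(r - 1L), times = r - 1L)
  j <- rep(seq_len(r - 1L), each = r - 1L)
  a <- (j - 1L) * r + i
  b <- a + 1L
  c <- a + r
  d <- c + 1L
  rbind(cbind(a, b, d), cbind(a, d, c))
}

#' Build the synthetic face template
#'
#' Samples the parametric face surface on an `r x r` grid, yielding `r^2`
#' vertices and `2 (r-1)^2` triangles, and designates the eight anchor
#' vertices (nearest distinct grid nodes to fixed anatomical targets; the
#' pronasale analogue sits at the most anterior point of the surface) and the
#' mandibular vertex mask used to plant and later localise group effects.
#'
#' @param grid_resolution grid points per side; at least 8.
#' @return A `face_template`: list with elements `mesh` ([mesh3]), `anchor_idx`
#'   (named integer vector of 8 distinct vertex indices), `mandible_idx`
#'   (integer vector), and the `u`, `v` parameter values per vertex.
#' @export
make_template <- function(grid_resolution = 24L) {
  r <- as.integer(grid_resolution)
  if (r < 8L) stop("grid_resolution must be at least 8")
  g <- grid_uv(r)
  verts <- face_surface(g$u, g$v)
  mesh <- mesh3(verts, grid_faces(r))

  targets <- anchor_uv_targets()
  anchor_idx <- integer(8L)
  for (a in seq_len(8L)) {
    d2 <- (g$u - targets[a, 1L])^2 + (g$v - targets[a, 2L])^2
    d2[anchor_idx[seq_len(a - 1L)]] <- Inf   # greedy distinctness
    anchor_idx[a] <- which.min(d2)
  }
  if (anyDuplicated(anchor_idx))
    stop("grid too small to host 8 distinct anchors")
  names(anchor_idx) <- anchor_names()

  mand <- which(mandible_mask_uv(g$u, g$v))
  structure(list(mesh = mesh, anchor_idx = anchor_idx, mandible_idx = mand,
                 u = g$u, v = g$v),
            class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat("<face_template> ", nrow(x$mesh$vertices), " vertices, ",
      length(x$mandible_idx), " mandibular, 8 anchors\n", sep = "")
  invisible(x)
}

#' Population specification for synthetic cohorts
#'
#' Defaults encode the study conditions the package targets: 600 subjects at
#' 5.23% DMV prevalence, three smooth shape modes with score standard
#' deviations 4, 3 and 2 mm, a 3 mm localised mandibular displacement in DMV
#' cases, 0.5 mm per-vertex scanner noise, and nuisance similarity transforms
#' up to 20 degrees rotation, 30 mm translation and scale in [0.9, 1.1].
#'
#' @param n_subjects number of scans.
#' @param prevalence DMV probability per subject, in (0, 1).
#' @param n_modes number of smooth variation modes (0 allowed).
#' @param mode_sd numeric vector of per-mode score SDs (mm), recycled/truncated
#'   to `n_modes`.
#' @param effect_size peak mandibular displacement (mm) added to DMV cases.
#' @param noise_sd iid per-vertex coordinate noise SD (mm).
#' @param rigid_jitter list with `rot_deg`, `trans_mm`, `log_scale` (length-2
#'   range); set all zero to disable nuisance transforms.
#' @param resample if `TRUE`, each scan is evaluated on its own jittered grid
#'   (vertex counts and positions differ across scans, destroying trivial
#'   correspondence); if `FALSE`, scan vertices correspond to template
#'   vertices one-to-one.
#' @param seed integer RNG seed.
#' @return A validated `population_spec` list.
#' @export
population_spec <- function(n_subjects = 600L, prevalence = 0.0523,
                            n_modes = 3L, mode_sd = c(4, 3, 2),
                            effect_size = 3, noise_sd = 0.5,
                            rigid_jitter = list(rot_deg = 20, trans_mm = 30,
                                                log_scale = log(c(0.9, 1.1))),
                            resample = FALSE, seed = 1L) {
  stopifnot(n_subjects >= 1, prevalence > 0, prevalence < 1, n_modes >= 0,
            effect_size >= 0, noise_sd >= 0)
  mode_sd <- rep_len(as.numeric(mode_sd), max(n_modes, 1L))[seq_len(n_modes)]
  if (any(mode_sd < 0)) stop("mode_sd must be non-negative")
  jit <- utils::modifyList(list(rot_deg = 0, trans_mm = 0,
                                log_scale = c(0, 0)), rigid_jitter)
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 n_modes = as.integer(n_modes), mode_sd = mode_sd,
                 effect_size = effect_size, noise_sd = noise_sd,
                 rigid_jitter = jit, resample = isTRUE(resample),
                 seed = as.integer(seed)),
            class = "population_spec")
}

random_rotation <- function(max_deg) {
  if (max_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# label-conditional clinical covariates; continuous shifts and male/snoring
# probabilities follow the cohort's published baseline table
sample_covariates <- function(labels) {
  n <- length(labels)
  dmv <- labels
  age <- ifelse(dmv, stats::rnorm(n, 40.94, 12.61), stats::rnorm(n, 34.32, 11.38))
  bmi <- ifelse(dmv, stats::rnorm(n, 27.30, 3.64), stats::rnorm(n, 21.90, 3.16))
  male <- stats::runif(n) < ifelse(dmv, 0.743, 0.423)
  snoring <- stats::runif(n) < ifelse(dmv, 0.743, 0.404)
  tmd <- ifelse(dmv, stats::rnorm(n, 9.76, 1.13), stats::rnorm(n, 9.50, 1.36))
  mmt_p_easy <- c(0.229, 0.334, 0.391, 0.046)
  mmt_p_dmv <- c(0.200, 0.314, 0.400, 0.086)
  mmt <- integer(n)
  mmt[!dmv] <- sample.int(4L, sum(!dmv), replace = TRUE, prob = mmt_p_easy)
  mmt[dmv] <- sample.int(4L, sum(dmv), replace = TRUE, prob = mmt_p_dmv)
  neck_radiation <- stats::runif(n) < ifelse(dmv, 0.029, 0)
  difficult_intubation_history <- stats::runif(n) < ifelse(dmv, 0.029, 0)
  sleep_apnea <- stats::runif(n) < ifelse(dmv, 0, 0.0016)
  tibble::tibble(
    subject = sprintf("S%04d", seq_len(n)),
    age = pmax(18, age),
    gender = ifelse(male, "male", "female"),
    bmi = pmax(14, bmi),
    tmd = pmax(4.5, tmd),
    mmt = mmt,
    snoring = snoring,
    neck_radiation = neck_radiation,
    difficult_intubation_history = difficult_intubation_history,
    sleep_apnea = sleep_apnea,
    beard = rep(FALSE, n),
    dmv = dmv
  )
}

#' Sample a synthetic cohort of facial scans
#'
#' Each subject's surface is the template plus a sum of smooth z-displacement
#' modes with Gaussian scores, plus (for DMV cases) the localised mandibular
#' effect field scaled to `effect_size`, plus iid vertex noise. The finished
#' shape is then pushed through a random similarity transform (nuisance
#' rotation/translation/scale) to emulate arbitrary scanner pose. Anchors are
#' evaluated on the same subject surface (noise-free) and transformed
#' identically. Covariates are drawn with label-conditional shifts.
#'
#' Fully reproducible: the same `spec$seed` yields a bitwise-identical cohort.
#'
#' @param template a [make_template()] result.
#' @param spec a [population_spec()].
#' @return A `synthetic_cohort`: list with `scans` (list of [mesh3]),
#'   `anchors` (list of anchor tibbles), `configs` (n x K x 3 array of
#'   ground-truth quasi-landmarks in scan coordinates when `resample` is off,
#'   else `NULL`), `labels` (logical), `covariates` (tibble), `template`,
#'   `spec`.
#' @export
sample_cohort <- function(template, spec = population_spec()) {
  stopifnot(inherits(template, "face_template"),
            inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  labels <- stats::runif(n) < spec$prevalence
  scores <- matrix(stats::rnorm(n * max(spec$n_modes, 1L)), n)
  scores <- sweep(scores, 2L, c(spec$mode_sd, 1)[seq_len(ncol(scores))], `*`)
  if (spec$n_modes == 0L) scores <- matrix(0, n, 0L)

  r0 <- as.integer(round(sqrt(nrow(template$mesh$vertices))))
  scans <- vector("list", n)
  anchors <- vector("list", n)
  configs <- if (!spec$resample)
    array(NA_real_, c(n, nrow(template$mesh$vertices), 3L)) else NULL

  targets <- anchor_uv_targets()
  jit <- spec$rigid_jitter
  for (i in seq_len(n)) {
    if (spec$resample) {
      ri <- r0 + sample(-2:2, 1L)
      g <- grid_uv(ri)
      cell <- 2 / (ri - 1)
      interior <- g$u > -1 & g$u < 1
      u <- g$u + ifelse(interior, stats::runif(ri^2, -0.3, 0.3) * cell, 0)
      interior_v <- g$v > -1 & g$v < 1
      v <- g$v + ifelse(interior_v, stats::runif(ri^2, -0.3, 0.3) * cell, 0)
      faces <- grid_faces(ri)
    } else {
      u <- template$u; v <- template$v
      faces <- template$mesh$faces
    }
    verts <- face_surface(u, v)
    if (spec$n_modes > 0L)
      for (k in seq_len(spec$n_modes))
        verts[, 3L] <- verts[, 3L] + scores[i, k] * mode_field(k, u, v)
    if (labels[i] && spec$effect_size > 0)
      verts[, 3L] <- verts[, 3L] + spec$effect_size * mandible_field(u, v)

    auv <- targets
    averts <- face_surface(auv[, 1L], auv[, 2L])
    if (spec$n_modes > 0L)
      for (k in seq_len(spec$n_modes))
        averts[, 3L] <- averts[, 3L] +
          scores[i, k] * mode_field(k, auv[, 1L], auv[, 2L])
    if (labels[i] && spec$effect_size > 0)
      averts[, 3L] <- averts[, 3L] +
        spec$effect_size * mandible_field(auv[, 1L], auv[, 2L])

    if (spec$noise_sd > 0)
      verts <- verts + matrix(stats::rnorm(length(verts), 0, spec$noise_sd),
                              nrow(verts))

    R <- random_rotation(jit$rot_deg)
    s <- exp(stats::runif(1, jit$log_scale[1L], jit$log_scale[2L]))
    t <- stats::runif(3, -jit$trans_mm, jit$trans_mm)
    verts <- s * verts %*% t(R) + rep(t, each = nrow(verts))
    averts <- s * averts %*% t(R) + rep(t, each = nrow(averts))

    scans[[i]] <- mesh3(verts, faces)
    anchors[[i]] <- anchor_set(averts)
    if (!spec$resample) configs[i, , ] <- verts
  }

  covariates <- sample_covariates(labels)
  structure(list(scans = scans, anchors = anchors, configs = configs,
                 labels = labels, covariates = covariates,
                 template = template, spec = spec, mode_scores = scores),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$scans), " scans, ",
      sum(x$labels), " DMV (", sprintf("%.2f%%", 100 * mean(x$labels)),
      "), resample=", x$spec$resample, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one OBJ and one anchor CSV per scan, a cohort covariate CSV with a
#' `dmv` label column, and the population spec as YAML.
#'
#' @param cohort a [sample_cohort()] result.
#' @param dir output directory, created if needed.
#' @param scans whether to write the (possibly many) OBJ scan files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, scans = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$covariates$subject
  if (scans) {
    for (i in seq_along(cohort$scans)) {
      write_obj(cohort$scans[[i]], file.path(dir, paste0(ids[i], ".obj")))
      write_anchors(cohort$anchors[[i]],
                    file.path(dir, paste0(ids[i], "_anchors.csv")))
    }
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  sp <- unclass(cohort$spec)
  yaml::write_yaml(sp, file.path(dir, "population_spec.yaml"))
  invisible(dir)
}
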