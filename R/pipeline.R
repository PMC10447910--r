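# End-to-end orchestration: simulate -> register -> gpa -> pca ->
# select_pcs -> train -> diffmask -> visualize, with a JSON run manifest
# (config snapshot, artifact hashes, per-stage wall time, derived seeds).

#' Build a pipeline run configuration
#'
#' All stages read their parameters from this one list; unspecified entries
#' fall back to the package defaults shown here. Per-stage seeds are derived
#' deterministically from the master `seed`, so any stage can be re-run in
#' isolation and reproduce its output bit for bit.
#'
#' @param out_dir artifact directory (created on run).
#' @param seed master seed.
#' @param simulate list: `grid_resolution` plus any [population_spec()]
#'   arguments; `write_scans` controls whether OBJ scans are written.
#' @param register list: `mode` (`"corresponded"` or `"full"`), `params`
#'   ([registration_params()]), `write_configs`.
#' @param gpa list: `tol`, `max_iter`.
#' @param select_pcs list: `pc_range`.
#' @param train list: `algorithms`, `folds`, `n_pcs` (`NULL` = use the sweep
#'   winner).
#' @param diffmask list: `weights_file` (`NULL` = packaged default),
#'   `cutoff`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("maskshape_run_"), seed = 1L,
                       simulate = list(), register = list(), gpa = list(),
                       select_pcs = list(), train = list(),
                       diffmask = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = utils::modifyList(
      list(grid_resolution = 24L, write_scans = FALSE), simulate),
    register = utils::modifyList(
      list(mode = "corresponded", params = registration_params(),
           write_configs = FALSE), register),
    gpa = utils::modifyList(list(tol = 1e-8, max_iter = 100L), gpa),
    pca = list(),
    select_pcs = utils::modifyList(list(pc_range = 1:50), select_pcs),
    train = utils::modifyList(
      list(algorithms = "all", folds = 10L, n_pcs = NULL), train),
    diffmask = utils::modifyList(
      list(weights_file = NULL, cutoff = 4L), diffmask),
    visualize = list()
  )
  if (!is.null(cfg$diffmask$weights_file) &&
      !file.exists(cfg$diffmask$weights_file))
    stop("diffmask weights_file does not exist: ",
         cfg$diffmask$weights_file)
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(seed, i) (seed + 1000L * i) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the eight stages in order, writes each stage's artifacts under
#' `config$out_dir`, and returns (and writes) a manifest recording the
#' config snapshot, artifact MD5 hashes, per-stage wall times and derived
#' seeds. A failure aborts with the stage name; artifacts of completed
#' stages are retained. Re-running with the same config reproduces all
#' artifacts bit for bit.
#'
#' @param config a [run_config()].
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = serializable_config(config),
                   package_version = as.character(utils::packageVersion("maskshape")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  stages <- c("simulate", "register", "gpa", "pca", "select_pcs", "train",
              "diffmask", "visualize")
  for (i in seq_along(stages)) {
    nm <- stages[i]
    sseed <- stage_seed(config$seed, i)
    t0 <- proc.time()[["elapsed"]]
    arts <- tryCatch(
      run_stage(nm, config, state, sseed),
      error = function(e) stop("pipeline stage '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest$stages[[nm]] <- list(
      seed = sseed,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      artifacts = as.list(artifact_hashes(arts)))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

serializable_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.function(x)) paste(deparse(x), collapse = " ")
    else x
  }
  strip(config)
}

artifact_hashes <- function(paths) {
  if (length(paths) == 0L) return(list())
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  as.list(h)
}

run_stage <- function(name, config, state, sseed) {
  out <- config$out_dir
  switch(name,
    simulate = {
      sim <- config$simulate
      state$template <- make_template(sim$grid_resolution)
      spec_args <- sim[setdiff(names(sim), c("grid_resolution", "write_scans"))]
      spec_args$seed <- sseed
      state$spec <- do.call(population_spec, spec_args)
      state$cohort <- sample_cohort(state$template, state$spec)
      dir <- file.path(out, "cohort")
      write_cohort(state$cohort, dir, scans = isTRUE(sim$write_scans))
      file.path(dir, c("covariates.csv", "population_spec.yaml"))
    },
    register = {
      state$configs <- register_cohort(state$cohort,
                                       params = config$register$params,
                                       mode = config$register$mode)
      if (isTRUE(config$register$write_configs)) {
        p <- file.path(out, "configs.csv")
        write_configs(state$configs, p)
        p
      } else character()
    },
    gpa = {
      state$gpa <- gpa(state$configs, tol = config$gpa$tol,
                       max_iter = config$gpa$max_iter)
      p <- file.path(out, "mean_shape.obj")
      write_obj(mean_shape_mesh(state$gpa, state$template$mesh), p)
      p
    },
    pca = {
      state$space <- fit_pca(state$gpa)
      p <- file.path(out, "scores.csv")
      utils::write.csv(score_table(state$space), p, row.names = FALSE,
                       quote = FALSE)
      p2 <- file.path(out, "variance.csv")
      utils::write.csv(tidy(state$space), p2, row.names = FALSE,
                       quote = FALSE)
      c(p, p2)
    },
    select_pcs = {
      state$sweep <- loocv_sweep(state$space$scores, state$cohort$labels,
                                 config$select_pcs$pc_range)
      p <- file.path(out, "pc_sweep.csv")
      utils::write.csv(as.data.frame(state$sweep), p, row.names = FALSE,
                       quote = FALSE)
      p
    },
    train = {
      n_pcs <- config$train$n_pcs %||% best_n_pcs(state$sweep)
      state$n_pcs <- n_pcs
      state$bank <- crossval_bank(
        state$space$scores[, seq_len(n_pcs), drop = FALSE],
        state$cohort$labels, algorithms = config$train$algorithms,
        k = config$train$folds, seed = sseed)
      p <- file.path(out, "cv_report.csv")
      utils::write.csv(as.data.frame(state$bank), p, row.names = FALSE,
                       quote = FALSE)
      pj <- file.path(out, "cv_report.json")
      jsonlite::write_json(list(n_pcs = n_pcs,
                                report = as.data.frame(state$bank)),
                           pj, auto_unbox = TRUE, digits = NA)
      c(p, pj)
    },
    diffmask = {
      w <- if (is.null(config$diffmask$weights_file))
        diffmask_default_weights()
      else read_diffmask_weights(config$diffmask$weights_file)
      scored <- diffmask_score(state$cohort$covariates, w,
                               cutoff = config$diffmask$cutoff)
      cmp <- dplyr::bind_rows(
        state$bank,
        score_report(scored$diffmask, state$cohort$labels,
                     name = "diffmask", seed = sseed))
      state$comparison <- cmp
      p <- file.path(out, "diffmask_scores.csv")
      utils::write.csv(scored, p, row.names = FALSE, quote = FALSE)
      p2 <- file.path(out, "model_vs_diffmask.csv")
      utils::write.csv(as.data.frame(cmp), p2, row.names = FALSE,
                       quote = FALSE)
      c(p, p2)
    },
    visualize = {
      gm <- group_mean_shapes(state$gpa, state$cohort$labels)
      dm <- distance_map(gm$positive, gm$negative)
      tmpl <- state$template
      df <- tibble::tibble(
        vertex = seq_along(dm),
        x = state$gpa$mean_shape[, 1L], y = state$gpa$mean_shape[, 2L],
        z = state$gpa$mean_shape[, 3L],
        distance = dm,
        in_mandible = seq_along(dm) %in% tmpl$mandible_idx)
      p <- file.path(out, "distance_map.csv")
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      sz <- mean(state$gpa$centroid_sizes)
      p2 <- file.path(out, "mean_shape_dmv.obj")
      write_obj(mean_shape_mesh(gm$positive, tmpl$mesh, sz), p2)
      p3 <- file.path(out, "mean_shape_easy.obj")
      write_obj(mean_shape_mesh(gm$negative, tmpl$mesh, sz), p3)
      c(p, p2, p3)
    },
    stop("unknown stage ", name)
  )
}
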