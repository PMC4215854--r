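#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. The defaults
#' carry the reference study conditions (fitted passive sets, the
#' production conductance grid with the five-value h list, +/-90 pA 1 s
#' steps, -74 mV holding target); `mini_config()` is a desk-scale preset
#' with a reduced grid (3 values for each of 7 conductances, 2,187
#' models) and coarser numerics for single-CPU ensemble runs.
#'
#' @param seed Master seed.
#' @param grid An `olm_grid_design`.
#' @param cohort An `olm_cohort_config`.
#' @param target_rin Surrogate morphology calibration target (MOhm).
#' @param passive_morph Which fitted passive set to use (1 or 2).
#' @param lambda_fraction,dt,dt_save Discretization settings.
#' @param pre,step_dur,post,amps Step protocol (ms, pA).
#' @param target_vm,bias_window Bias-fit settings (mV, pA).
#' @param sensitivity,persistence,spike_floor Subset cutoff settings.
#' @param n_high Number of high-order parameters screened for
#'   co-regulations.
#' @param bias_settle Settling duration used during bias fitting (ms).
#' @param reference Named density vector of the cohort's reference model
#'   (pS/um^2); defaults to mid-grid values with somatodendritic h.
#' @return A list of class `olm_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, grid = grid_presets("v2"),
                            cohort = cohort_config(seed = seed),
                            target_rin = 474, passive_morph = 1,
                            lambda_fraction = 0.1, dt = 0.025,
                            dt_save = 0.1, pre = 1000, step_dur = 1000,
                            post = 1000, amps = c(-90, 90),
                            target_vm = -74, bias_window = c(-28, 12),
                            sensitivity = 3, persistence = 0.01,
                            spike_floor = 2, n_high = 5,
                            bias_settle = 1500, reference = NULL) {
  if (is.null(reference))
    reference <- vapply(grid$values, function(v) v[ceiling(length(v) / 2)],
                        1)
  structure(as.list(environment()), class = "olm_pipeline_config")
}

#' @param ... Overrides passed to [pipeline_config()].
#' @rdname pipeline_config
#' @export
mini_config <- function(seed = 1, ...) {
  grid <- grid_design(values = list(
    Na_s = c(60, 107, 220), Na_d = c(70, 117, 230),
    KDRf = c(6, 95, 506), KDRs = c(2.3, 42, 222),
    A = c(2.5, 32, 169), h = c(0.05, 0.1, 0.5), M = c(0.375, 0.75, 1.5),
    CaL = 25, CaT = 2.5, AHP = 5.5),
    ih_dist = "somatodendritic", morphologies = "surrogate")
  pipeline_config(seed = seed, grid = grid,
                  cohort = cohort_config(seed = seed),
                  lambda_fraction = 0.5, dt = 0.05, pre = 400,
                  post = 400, bias_settle = 600, ...)
}

stage_hashes <- function(files) {
  as.list(tools::md5sum(files))
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  mp <- manifest_path(out_dir)
  if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = FALSE)
  else list(stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, manifest_path(out_dir),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_done <- function(manifest, name) {
  st <- manifest$stages[[name]]
  if (is.null(st)) return(FALSE)
  files <- names(st$outputs)
  if (!all(file.exists(files))) return(FALSE)
  now <- stage_hashes(files)
  ok <- identical(unname(unlist(st$outputs)), unname(unlist(now)))
  if (!ok)
    stop("resumption error: outputs of completed stage '", name,
         "' do not match their recorded hashes (corrupted artifact?)")
  TRUE
}

#' Run the full ensemble-modeling pipeline
#'
#' Executes the cyclical pipeline stage by stage: synthetic cohort
#' generation, grid enumeration, grid simulation (bias fitting plus the
#' +/-90 pA step pair per model), feature extraction, ranking, subset
#' extraction (general and restricted criteria) and co-regulation
#' analysis. Each stage persists plain-text artifacts under `out_dir` and
#' records their hashes in `manifest.json`; rerunning with an unchanged
#' configuration skips completed stages, and a corrupted intermediate
#' raises an error naming the stage. Identical config and seed produce
#' identical artifacts regardless of `workers`.
#'
#' @param config An `olm_pipeline_config`.
#' @param out_dir Artifact directory.
#' @param workers Number of worker processes for the simulation stage.
#' @param quiet Suppress progress messages.
#' @return The manifest (invisibly), with the key result objects attached
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir, workers = 1, quiet = FALSE) {
  stopifnot(inherits(config, "olm_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(out_dir)
  manifest$config <- list(seed = config$seed,
                          grid_size = grid_size(config$grid))
  results <- list()
  say <- function(...) if (!quiet) message(...)

  passive <- olm_passive_defaults(config$passive_morph)
  disc <- discretization(lambda_fraction = config$lambda_fraction,
                         dt = config$dt, dt_save = config$dt_save)
  channels <- default_channel_set()
  morph <- surrogate_morphology(config$target_rin, passive, disc = disc)

  run_stage <- function(name, outputs, fn) {
    if (stage_done(manifest, name)) {
      say("[", name, "] up to date, skipping")
      return(invisible(NULL))
    }
    say("[", name, "] running")
    t0 <- Sys.time()
    fn()
    manifest$stages[[name]] <<- list(
      outputs = stage_hashes(outputs),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    write_manifest(manifest, out_dir)
  }

  # -- stage: synth ---------------------------------------------------------
  synth_dir <- file.path(out_dir, "synth")
  synth_meas <- file.path(out_dir, "synth_measures.csv")
  run_stage("synth", synth_meas, function() {
    cohort <- generate_cohort(config$cohort, config$reference, morph,
                              passive, channels, disc,
                              pre = config$pre,
                              step_dur = config$step_dur,
                              post = config$post, dt = config$dt)
    write_traces(cohort$traces, synth_dir)
    rep <- cohort_report(cohort)
    write_measures(rep$measures, synth_meas)
  })
  exp_measures <- read_measures(synth_meas)

  # -- stage: grid ----------------------------------------------------------
  grid_file <- file.path(out_dir, "grid.csv")
  run_stage("grid", grid_file, function() {
    write_grid(build_grid(config$grid), grid_file)
  })
  grid <- read_grid(grid_file)

  # -- stage: simulate + features ------------------------------------------
  meas_file <- file.path(out_dir, "model_measures.csv")
  rej_file <- file.path(out_dir, "rejections.csv")
  run_stage("simulate", c(meas_file, rej_file), function() {
    reg <- measure_registry()
    sim_one <- function(i) {
      spec <- model_spec(grid, grid$model_id[i])
      cab <- build_cable(spec, morph, passive, channels, disc)
      fit <- tryCatch(
        fit_bias_current(cab, target_vm = config$target_vm,
                         window = config$bias_window, dt = config$dt,
                         settle = config$bias_settle),
        error = function(e) structure(list(ok = FALSE,
                                           reason = conditionMessage(e),
                                           bias = NA_real_),
                                      class = "olm_bias_fit"))
      if (!fit$ok)
        return(list(rej = data.frame(model_id = spec$model_id,
                                     reason = fit$reason)))
      traces <- tryCatch(
        run_step_pair(cab, fit$bias, amps = config$amps,
                      pre = config$pre, step_dur = config$step_dur,
                      post = config$post, dt = config$dt),
        error = function(e) NULL)
      if (is.null(traces))
        return(list(rej = data.frame(model_id = spec$model_id,
                                     reason = "instability")))
      rows <- lapply(names(traces), function(p) {
        m <- extract_measures(traces[[p]], reg)
        full <- setNames(rep(NA_real_, nrow(reg)), reg$name)
        full[names(m)] <- as.numeric(m)
        cbind(data.frame(model_id = spec$model_id, protocol = p,
                         bias = fit$bias),
              as.data.frame(as.list(full)))
      })
      list(meas = rows)
    }
    res <- if (workers > 1)
      parallel::mclapply(seq_len(nrow(grid)), sim_one,
                         mc.cores = workers)
    else lapply(seq_len(nrow(grid)), sim_one)
    meas <- do.call(rbind, unlist(lapply(res, `[[`, "meas"),
                                  recursive = FALSE))
    rej <- do.call(rbind, c(list(data.frame(model_id = integer(0),
                                            reason = character(0))),
                            lapply(res, `[[`, "rej")))
    write_measures(meas, meas_file)
    write.csv(rej, rej_file, row.names = FALSE)
  })
  model_meas <- read_measures(meas_file)
  rejections <- read.csv(rej_file)

  # -- stage: rank ----------------------------------------------------------
  ranks_file <- file.path(out_dir, "ranks.csv")
  run_stage("rank", ranks_file, function() {
    stats <- dataset_stats(exp_measures)
    meta <- c("model_id", "protocol", "bias")
    ids <- unique(model_meas$model_id)
    d_x <- vapply(ids, function(id) {
      rows <- model_meas[model_meas$model_id == id, ]
      vecs <- lapply(split(rows, rows$protocol), function(r) {
        v <- unlist(r[1, setdiff(names(r), meta)])
        v
      })
      as.numeric(aggregate_distance(vecs, exp_measures, stats))
    }, 1)
    ranked <- rank_models(data.frame(model_id = ids, d_x = d_x))
    write.csv(ranked, ranks_file, row.names = FALSE)
  })
  ranked <- read.csv(ranks_file)

  # -- stage: subsets -------------------------------------------------------
  subsets_base <- file.path(out_dir, "subset_general")
  subsets_fire <- file.path(out_dir, "subset_fire")
  subsets_sag <- file.path(out_dir, "subset_sagtau")
  subset_files <- c(paste0(subsets_base, ".json"),
                    paste0(subsets_base, "_members.csv"),
                    paste0(subsets_fire, ".json"),
                    paste0(subsets_fire, "_members.csv"),
                    paste0(subsets_sag, ".json"),
                    paste0(subsets_sag, "_members.csv"))
  run_stage("subsets", subset_files, function() {
    morph_label <- config$grid$morphologies[1]
    gc <- if (nrow(ranked) >= 10)
      general_cutoff(ranked$d_x, sensitivity = config$sensitivity,
                     persistence = config$persistence)
    else structure(list(criterion = "general", cutoff = NA_integer_,
                        verdict = "no cutoff", diagnostics = list()),
                   class = "olm_cutoff")
    if (is.na(gc$cutoff)) gc$cutoff <- nrow(ranked)
    write_subset_report(subset_report(ranked, gc, morph_label),
                        subsets_base)
    dep_rows <- model_meas[model_meas$protocol == "dep", ]
    spikes <- dep_rows$PulseSpikes[match(ranked$model_id,
                                         dep_rows$model_id)]
    fc <- failure_to_fire_cutoff(spikes, spike_floor = config$spike_floor)
    write_subset_report(subset_report(ranked, fc, morph_label),
                        subsets_fire)
    # sag time-constant comparator (historically redundant with the firing
    # cutoff, but reported alongside it)
    hyp_rows <- model_meas[model_meas$protocol == "hyp", ]
    tau <- hyp_rows$PulseSagTau[match(ranked$model_id, hyp_rows$model_id)]
    exp_tau <- exp_measures$PulseSagTau[
      exp_measures$protocol == "hyp"]
    sc <- tryCatch(
      sag_tau_cutoff(tau, exp_tau[is.finite(exp_tau)],
                     persistence = config$persistence),
      error = function(e) structure(
        list(criterion = "sag_tau", cutoff = nrow(ranked),
             verdict = "criterion unavailable", diagnostics = list()),
        class = "olm_cutoff"))
    write_subset_report(subset_report(ranked, sc, morph_label),
                        subsets_sag)
  })
  general <- jsonlite::read_json(paste0(subsets_base, ".json"),
                                 simplifyVector = TRUE)
  general_members <- read.csv(paste0(subsets_base, "_members.csv"))

  # -- stage: analyze -------------------------------------------------------
  coreg_file <- file.path(out_dir, "coreg.csv")
  order_file <- file.path(out_dir, "stack_order.json")
  run_stage("analyze", c(coreg_file, order_file), function() {
    db <- merge(grid, ranked[c("model_id", "d_x", "rank")],
                by = "model_id")
    varied <- names(config$grid$values)[
      vapply(config$grid$values, function(v) length(unique(v)) > 1, TRUE)]
    db$retained <- db$model_id %in% general_members$model_id
    so <- cbdr_order(db, params = varied)
    jsonlite::write_json(list(order = so$order, clutter = so$clutter),
                         order_file, auto_unbox = TRUE, digits = NA)
    screen <- coreg_screen(db, so, n_high = config$n_high)
    write.csv(screen, coreg_file, row.names = FALSE)
  })

  results$ranked <- ranked
  results$rejections <- rejections
  results$coreg <- read.csv(coreg_file)
  results$stack_order <- jsonlite::read_json(order_file,
                                             simplifyVector = TRUE)
  results$general <- general
  manifest <- read_manifest(out_dir)
  attr(manifest, "results") <- results
  invisible(manifest)
}
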