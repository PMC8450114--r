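# Experiment recipes, configuration serialization and the experiment runner.

#' Experiment presets
#'
#' Ready-made configurations for the package's main experiments, at full
#' scale (a ~20 Mb chromosome of 100000 nucleosomes):
#'
#' * `"le_sweep"`: sixteen LE counts between 50 and 2000 crossed with the
#'   three centromere modes, 100 centromeric nucleosomes, 10 replicates; the
#'   condensation-versus-LE-count sweep.
#' * `"holo_line"`: 1000 LEs, 100 anchoring centromeric nucleosomes spread
#'   chromosome-wide; the line-like holocentromere run (with 3D stage).
#' * `"holo_vs_mono"`: 1000 LEs; holocentric (100 centromeres genome-wide)
#'   versus monocentric (20 centromeres in a 400 kb region), anchoring mode.
#' * `"groove"`: the kinetochore stage: anchoring run of 100000 1D steps, the
#'   last 50000 replayed in 3D against the kinetochore plate.
#'
#' @param name preset name.
#' @param scale proportional reduction factor in (0, 1]; scales the number of
#'   nucleosomes, centromeres, LEs, 1D steps and 3D blocks for desk-scale
#'   runs. Full scale (`scale = 1`) is the documented default.
#' @param seed base RNG seed; replicate r uses `seed + r - 1`.
#' @return An `experiment_config` list understood by [run_experiment()].
#' @export
preset <- function(name = c("le_sweep", "holo_line", "holo_vs_mono",
                            "groove"), scale = 1, seed = 1L) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  sc <- function(x) max(1L, as.integer(round(x * scale)))
  base <- list(
    name = name, scale = scale, seed = as.integer(seed),
    chromosome = list(n_nucleosomes = sc(100000), bp_per_nucleosome = 200),
    extrusion = list(lifetime = 1000, n_steps = sc(100000)),
    forcefield = unclass(forcefield_params()),
    integrator = list(kBT = 1, friction = 0.5, dt = 0.08,
                      steps_per_block = 100,
                      n_blocks_warmup = sc(10000),
                      n_blocks_extrusion = sc(40000),
                      snapshot_every = sc(1000)),
    replicates = 10L, run_3d = FALSE)
  switch(name,
    le_sweep = within_list(base, {
      chromosome$n_centromeric <- sc(100)
      chromosome$kind <- "holocentric"
      extrusion$n_les_values <- unique(sc_vec(
        c(50, 100, 150, 200, 300, 400, 500, 600, 700, 800, 900, 1000, 1200,
          1400, 1700, 2000), scale))
      extrusion$modes <- c("none", "blocking", "anchoring")
    }),
    holo_line = within_list(base, {
      chromosome$n_centromeric <- sc(100)
      chromosome$kind <- "holocentric"
      extrusion$n_les_values <- sc(1000)
      extrusion$modes <- "anchoring"
      run_3d <- TRUE
    }),
    holo_vs_mono = within_list(base, {
      chromosome$variants <- list(
        holocentric = list(kind = "holocentric", n_centromeric = sc(100)),
        monocentric = list(kind = "monocentric", n_centromeric = sc(20),
                           region_bp = sc(2000) * 200))
      extrusion$n_les_values <- sc(1000)
      extrusion$modes <- "anchoring"
    }),
    groove = within_list(base, {
      chromosome$n_centromeric <- sc(100)
      chromosome$kind <- "holocentric"
      extrusion$n_les_values <- sc(1000)
      extrusion$modes <- "anchoring"
      replicates <- 1L
      run_3d <- TRUE
      kinetochore <- TRUE
      integrator$n_blocks_warmup <- 0L
      integrator$n_blocks_extrusion <- sc(50000)
    }))
}

within_list <- function(x, expr) {
  e <- substitute(expr)
  env <- list2env(x, parent = parent.frame())
  eval(e, env)
  out <- as.list(env)
  out[order(match(names(out), names(x)))]
}

sc_vec <- function(x, scale) pmax(1L, as.integer(round(x * scale)))

config_spec <- function(chrom, seed, variant = NULL) {
  ch <- if (is.null(variant)) chrom else utils::modifyList(chrom, variant)
  if (identical(ch$kind, "monocentric")) {
    monocentric_spec(ch$n_nucleosomes, ch$n_centromeric, ch$region_bp,
                     ch$bp_per_nucleosome, seed = seed)
  } else {
    holocentric_spec(ch$n_nucleosomes, ch$n_centromeric, seed = seed,
                     bp_per_nucleosome = ch$bp_per_nucleosome)
  }
}

#' Read / write an experiment configuration
#'
#' Configurations are YAML documents; re-running a serialized configuration
#' with the same seeds reproduces all 1D outputs exactly.
#'
#' @param config an `experiment_config`.
#' @param path file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) yaml::read_yaml(path)

#' Run an experiment configuration
#'
#' Executes the 1D stage (always) for every combination of mode, LE count,
#' chromosome variant and replicate in the configuration, computes the
#' equilibrium compaction summary of each run, and optionally runs the 3D
#' stage. When `out_dir` is given, writes `summary.tsv` (one row per run),
#' optional per-run trace TSVs, and a `manifest.json` with all parameters and
#' seeds.
#'
#' @param config an `experiment_config` from [preset()] or
#'   [read_experiment_config()].
#' @param out_dir optional output directory.
#' @param save_traces also write each run's bond trace TSV.
#' @param verbose print per-run progress.
#' @return List with `summary` (data.frame), `traces` (last replicate of each
#'   parameter set), and `trajectories` (if the 3D stage ran).
#' @export
run_experiment <- function(config, out_dir = NULL, save_traces = FALSE,
                           verbose = interactive()) {
  variants <- config$chromosome$variants
  if (is.null(variants)) variants <- list(default = NULL)
  grid <- expand.grid(variant = names(variants),
                      mode = config$extrusion$modes,
                      n_les = config$extrusion$n_les_values,
                      replicate = seq_len(config$replicates),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  rows <- list(); traces <- list(); trajs <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed <- config$seed + g$replicate - 1L
    spec <- config_spec(config$chromosome, seed, variants[[g$variant]])
    params <- extrusion_params(g$n_les, config$extrusion$lifetime, g$mode,
                               config$extrusion$n_steps, seed = seed)
    tr <- run_extrusion(spec, params)
    summ <- equilibrium_summary(tr)
    row <- cbind(data.frame(variant = g$variant, mode = g$mode,
                            n_les = g$n_les, replicate = g$replicate,
                            seed = seed), summ)
    rows[[i]] <- row
    key <- sprintf("%s_%s_%d", g$variant, g$mode, g$n_les)
    traces[[key]] <- tr
    if (verbose) {
      message(sprintf("[%d/%d] %s mode=%s n_les=%d rep=%d: length=%.0f",
                      i, nrow(grid), g$variant, g$mode, g$n_les, g$replicate,
                      summ$chromosome_length))
    }
    if (save_traces && !is.null(out_dir)) {
      write_bond_trace(tr, file.path(out_dir, sprintf("trace_%s_rep%d.tsv",
                                                      key, g$replicate)))
    }
  }
  summary <- do.call(rbind, rows)

  if (isTRUE(config$run_3d)) {
    ip <- do.call(integrator_params, config$integrator)
    ff <- do.call(forcefield_params, config$forcefield)
    for (key in names(traces)) {
      tr <- traces[[key]]
      if (isTRUE(config$kinetochore)) {
        conf0 <- kinetochore_initial_conformation(tr$spec, final_state(tr))
        trajs[[key]] <- run_kinetochore_dynamics(conf0, tr$spec, tr, ff, ip)
      } else {
        conf0 <- random_walk_conformation(tr$spec, ff$bond_mean,
                                          seed = config$seed)
        trajs[[key]] <- run_dynamics(conf0, tr$spec, tr, ff, ip)
      }
      if (!is.null(out_dir)) {
        write_trajectory_xyz(trajs[[key]],
                             file.path(out_dir, paste0(key, ".xyz")))
      }
    }
  }

  if (!is.null(out_dir)) {
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summary = summary, traces = traces, trajectories = trajs)
}

#' Per-parameter-set equilibrium means and SDs
#'
#' Collapses a [run_experiment()] summary over replicates.
#'
#' @param summary data.frame from [run_experiment()].
#' @return data.frame with means and SDs of the equilibrium metrics per
#'   (variant, mode, n_les).
#' @export
summarize_sweep <- function(summary) {
  keys <- c("variant", "mode", "n_les")
  metrics <- c("chromosome_length", "avg_loop_length", "frac_outside",
               "n_side_by_side")
  agg_mean <- stats::aggregate(summary[metrics], summary[keys], mean)
  agg_sd <- stats::aggregate(summary[metrics], summary[keys], stats::sd)
  names(agg_sd)[-seq_along(keys)] <- paste0(metrics, "_sd")
  merge(agg_mean, agg_sd, by = keys)
}
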