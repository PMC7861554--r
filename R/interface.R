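#' Generate the canned fixture pack
#'
#' Writes small benchmark datasets (spikes as interchange CSV + metadata
#' JSON, ground truth as JSON) for the scenarios `fig1`, `fig6` (strength 1,
#' 40 trials), `fig8`, `fig10` and a two-neuron stationary null. Every file
#' records the seed it was generated from, so the pack regenerates
#' identically.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Master seed.
#' @return Invisibly, the vector of scenario names written.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- list(
    fig1 = function(s) make_scenario("fig1", seed = s),
    fig6 = function(s) make_scenario("fig6", seed = s, strength = 1),
    fig8 = function(s) make_scenario("fig8", seed = s),
    fig10 = function(s) make_scenario("fig10", seed = s),
    null2 = function(s) {
      net <- network_spec(2, baseline_rate = 15, bump_amplitude = 0)
      list(name = "null2", network = net, truth = truth_edges(net),
           spikes = simulate_network(net, 40, seed = s))
    })
  for (k in seq_along(scen)) {
    name <- names(scen)[k]
    s <- child_seed(seed, k)
    sc <- scen[[k]](s)
    write_spikes_csv(sc$spikes, file.path(out_dir, paste0(name, ".csv")))
    jsonlite::write_json(
      list(scenario = name, seed = s, master_seed = seed,
           truth_edges = sc$truth),
      file.path(out_dir, paste0(name, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(names(scen))
}

# Load a hyperparameter grid from a JSON config:
# {"window_width": [...], "n_history": [...], "n_exo": [...]}
read_grid_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cif_grid(window_width = as.numeric(cfg$window_width),
           n_history = as.integer(cfg$n_history),
           n_exo = as.integer(cfg$n_exo))
}

#' Command-line dispatcher
#'
#' Entry point behind the `inst/cli/ppgranger` script. Subcommands:
#' `simulate` (write a scenario's spike trains to CSV), `granger`
#' (connectivity analysis of a spike CSV, result to JSON plus a p-value
#' matrix CSV), `montecarlo` (a [run_comparison()] experiment, summary to
#' JSON), `fixtures` (write the fixture pack).
#'
#' @param args Character vector of command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status (0 on success), invisibly.
#' @export
ppg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppgranger <simulate|granger|montecarlo|fixtures> [options]",
    "  simulate   --scenario fig1 --trials 40 --seed 1 [--strength 1] --out spikes.csv",
    "  granger    --spikes spikes.csv --method getm|kim|getmv [--alpha 0.05]",
    "             [--grid grid.json] [--padjust none] --out result.json",
    "  montecarlo --experiment fig4_pp|fig5_if|fig9_trialvar [--methods kim,getm]",
    "             [--runs 25] --seed 11 --out summary.json",
    "  fixtures   --out dir [--seed 1]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--"))
      { message("unexpected argument: ", rest[i], "\n", usage); return(invisible(1L)) }
    key <- substring(rest[i], 3)
    if (i + 1L > length(rest))
      { message("missing value for --", key); return(invisible(1L)) }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required option --", key,
                                   call. = FALSE)
    opts[[key]]
  }
  status <- tryCatch({
    switch(
      cmd,
      simulate = {
        sc <- make_scenario(
          need("scenario"),
          seed = as.integer(need("seed")),
          n_trials = as.integer(opts[["trials"]] %||% 40),
          strength = as.numeric(opts[["strength"]] %||% 1))
        out <- need("out")
        write_spikes_csv(sc$spikes, out)
        jsonlite::write_json(
          list(scenario = sc$name, seed = as.integer(need("seed")),
               truth_edges = sc$truth),
          paste0(out, ".truth.json"), auto_unbox = TRUE, digits = NA)
        message("wrote ", out)
        0L
      },
      granger = {
        spikes_path <- need("spikes")
        if (!file.exists(spikes_path))
          stop("spike file not found: ", spikes_path, call. = FALSE)
        spikes <- read_spikes_csv(spikes_path)
        grid <- if (!is.null(opts[["grid"]])) read_grid_config(opts[["grid"]])
                else cif_grid()
        res <- connectivity(
          spikes, need("method"),
          alpha = as.numeric(opts[["alpha"]] %||% 0.05), grid = grid,
          p_adjust = opts[["padjust"]] %||% "none")
        out <- need("out")
        write_connectivity_json(res, out)
        utils::write.csv(res$p_value, paste0(out, ".pvalues.csv"))
        print(res)
        0L
      },
      montecarlo = {
        methods <- if (!is.null(opts[["methods"]]))
          strsplit(opts[["methods"]], ",")[[1]]
        mc <- run_comparison(
          need("experiment"), methods = methods,
          n_runs = as.integer(opts[["runs"]] %||% 25),
          seed = as.integer(need("seed")))
        jsonlite::write_json(
          list(experiment = mc$experiment, summary = mc$summary,
               runs = mc$runs, n_redraws = mc$n_redraws,
               config = mc$config),
          need("out"), auto_unbox = TRUE, digits = NA)
        print(mc)
        0L
      },
      fixtures = {
        generate_fixtures(need("out"),
                          seed = as.integer(opts[["seed"]] %||% 1))
        message("wrote fixture pack to ", need("out"))
        0L
      },
      { message("unknown subcommand: ", cmd, "\n", usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
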