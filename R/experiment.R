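#' Build an experiment configuration
#'
#' Bundles every knob of the comparison protocol: the network source (an
#' edge-list path *or* a generator spec, exactly one), the selection
#' parameters (`mu`, `l_max`), the SIR sweep (`beta_grid`, `gamma`, `runs`,
#' `infect_fraction`), the pinned trajectory infection rate, the methods to
#' compare and the output directory.
#'
#' @param edgelist Path to an edge-list file, or `NULL`.
#' @param generator List `list(model = "ba", n, m, seed)` (or `model = "er"`
#'   with `n`, `p`, `seed`), or `NULL`.
#' @param mu Giant-component threshold for the selection.
#' @param l_max Valid-path length bound.
#' @param beta_grid Infection-rate sweep (default 0.01 to 0.15 by 0.01).
#' @param gamma Recovery rate (default 0.01).
#' @param runs Ensemble size per grid point (default 100).
#' @param infect_fraction Initial infected fraction for immunization runs.
#' @param trajectory_beta Pinned infection rate for the time-course CSV.
#' @param methods Ranking methods to compare against the selection.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for CSVs and the manifest.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(edgelist = NULL, generator = NULL,
                              mu = 0.01, l_max = 6,
                              beta_grid = seq(0.01, 0.15, by = 0.01),
                              gamma = 0.01, runs = 100,
                              infect_fraction = 0.05,
                              trajectory_beta = 0.05,
                              methods = c("degree", "betweenness", "kshell",
                                          "eigenvector", "voterank"),
                              seed = 1L, out_dir = tempfile("spreadrank_")) {
  if (is.null(edgelist) == is.null(generator))
    abort("supply exactly one of `edgelist` or `generator`")
  if (length(beta_grid) == 0) abort("`beta_grid` must be non-empty")
  if (!(mu > 0 && mu < 1)) abort("`mu` must lie in (0, 1)")
  if (!(infect_fraction > 0 && infect_fraction < 1))
    abort("`infect_fraction` must lie in (0, 1)")
  structure(
    list(edgelist = edgelist, generator = generator, mu = mu, l_max = l_max,
         beta_grid = beta_grid, gamma = gamma, runs = runs,
         infect_fraction = infect_fraction,
         trajectory_beta = trajectory_beta, methods = methods,
         seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the `yaml` package is required to read YAML configs")
  # keep bare y/n tokens (e.g. the generator size key `n:`) as strings
  # instead of YAML 1.1 booleans; true/false still parse as logicals
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("y", "yes")) x else TRUE,
    "bool#no" = function(x) if (tolower(x) %in% c("n", "no")) x else FALSE
  ))
  do.call(experiment_config, raw)
}

experiment_network <- function(cfg) {
  if (!is.null(cfg$edgelist)) return(read_edgelist(cfg$edgelist))
  g <- cfg$generator
  model <- tolower(g$model %||% "ba")
  if (model == "ba") ba_graph(g$n, g$m, seed = g$seed %||% cfg$seed)
  else if (model == "er") er_graph(g$n, g$p, seed = g$seed %||% cfg$seed)
  else abort(sprintf("unknown generator model '%s'", model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparison experiment
#'
#' Reproduces the standard comparison protocol on one network: select the
#' influential set with [spreadrank_select()]; give every baseline method the
#' same budget (its top-`|S|` ranked nodes); then, per method, run (i) the
#' spreading sweep (set as initial infected) and (ii) the immunization sweep
#' (set as initial recovered, random initial infections among the rest) over
#' the `beta` grid, plus a time-course ensemble at the pinned
#' `trajectory_beta`. Writes one `curves_spreading_<method>.csv`,
#' `curves_immunization_<method>.csv` and `trajectory_<method>.csv` per
#' method and a `manifest.json` recording all parameters, seeds, `|S|` and
#' the residual giant-component fraction `q`. Reruns with the same config
#' produce identical files.
#'
#' @param cfg An [experiment_config()].
#' @return Invisibly, a list with the selection object, the per-method node
#'   sets, the combined `spreading` and `immunization` tibbles, the
#'   trajectories, and the manifest; all also written to `cfg$out_dir`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("experiment stage '%s' failed: %s", what,
                    conditionMessage(e))))
  }
  net <- stage("network", experiment_network(cfg))
  sel <- stage("selection",
               spreadrank_select(net, mu = cfg$mu, l_max = cfg$l_max))
  k <- length(sel$selected)
  sets <- list(spreadrank = sel$selected)
  for (mth in setdiff(cfg$methods, "spreadrank"))
    sets[[mth]] <- stage(paste0("ranking:", mth),
                         top_k_set(rank_nodes(net, mth), k))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(cfg$seed, 3L * length(sets))
  spreading <- list(); immunization <- list(); trajectories <- list()
  for (i in seq_along(sets)) {
    mth <- names(sets)[i]
    s3 <- seeds[(3 * i - 2):(3 * i)]
    sp <- stage(paste0("spreading:", mth),
      spreading_experiment(net, sets[[mth]], cfg$beta_grid,
                           gamma = cfg$gamma, runs = cfg$runs, seed = s3[1]))
    im <- stage(paste0("immunization:", mth),
      immunization_experiment(net, sets[[mth]], cfg$beta_grid,
                              gamma = cfg$gamma,
                              infect_fraction = cfg$infect_fraction,
                              runs = cfg$runs, seed = s3[2]))
    tr <- stage(paste0("trajectory:", mth),
      sir_ensemble(net, beta = cfg$trajectory_beta, gamma = cfg$gamma,
                   infected = sets[[mth]], runs = cfg$runs, seed = s3[3]))
    sp$method <- mth; im$method <- mth
    spreading[[mth]] <- sp; immunization[[mth]] <- im
    trajectories[[mth]] <- tr$trajectory
    write.csv(sp, file.path(cfg$out_dir,
              sprintf("curves_spreading_%s.csv", mth)), row.names = FALSE)
    write.csv(im, file.path(cfg$out_dir,
              sprintf("curves_immunization_%s.csv", mth)), row.names = FALSE)
    write.csv(tr$trajectory, file.path(cfg$out_dir,
              sprintf("trajectory_%s.csv", mth)), row.names = FALSE)
  }
  manifest <- list(
    parameters = cfg[c("mu", "l_max", "beta_grid", "gamma", "runs",
                       "infect_fraction", "trajectory_beta", "methods")],
    network = if (is.null(cfg$edgelist)) cfg$generator
              else list(edgelist = cfg$edgelist),
    seed = cfg$seed, stage_seeds = as.integer(seeds),
    n_nodes = sel$n_nodes, n_selected = k, q = sel$q,
    selected = sel$selected
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    network = net, selection = sel, sets = sets,
    spreading = dplyr::bind_rows(spreading),
    immunization = dplyr::bind_rows(immunization),
    trajectories = trajectories, manifest = manifest,
    out_dir = cfg$out_dir
  ))
}
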