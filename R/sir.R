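# Validate SIR inputs and build the initial state vector (0=S, 1=I, 2=R)
# in canonical vertex order.
sir_state0 <- function(net, beta, gamma, infected, recovered) {
  if (!is.numeric(beta) || beta < 0 || beta > 1) abort("`beta` must be in [0, 1]")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) abort("`gamma` must be in [0, 1]")
  infected <- as.character(infected)
  recovered <- as.character(recovered)
  if (length(infected) == 0) abort("`infected` must be non-empty")
  check_nodes(net, c(infected, recovered))
  if (length(intersect(infected, recovered)) > 0)
    abort("`infected` and `recovered` must be disjoint")
  lab <- node_labels(net)
  state <- integer(length(lab))
  state[lab %in% infected] <- 1L
  state[lab %in% recovered] <- 2L
  state
}

#' Single discrete-time SIR realization on a network
#'
#' Synchronous susceptible-infected-recovered dynamics: at every time step,
#' each susceptible node with `m` currently infected neighbours becomes
#' infected with probability `1 - (1 - beta)^m` (independent per-contact
#' Bernoulli trials), and simultaneously each node that was infected at the
#' start of the step recovers with probability `gamma`. A node infected in a
#' step cannot recover in that same step. The run stops when no infected
#' node remains or `max_steps` is hit.
#'
#' @inheritParams write_edgelist
#' @param beta Per-contact, per-step infection probability in `[0, 1]`.
#' @param gamma Per-step recovery probability in `[0, 1]`.
#' @param infected Initial infected node labels (non-empty).
#' @param recovered Initial recovered (immunized) node labels; disjoint from
#'   `infected`.
#' @param max_steps Step cap; default `10 * N`. Hitting it is flagged in the
#'   result (`extinct = FALSE`).
#' @param seed Optional integer seed (local to the call).
#' @return An object of class `sir_run`: list with `trajectory` (tibble
#'   `step`, `s`, `i`, `r`, including step 0), `pr` (final recovered
#'   fraction), `steps` and `extinct`.
#' @examples
#' g <- ba_graph(50, 2, seed = 1)
#' run <- sir_run(g, beta = 0.2, gamma = 0.1, infected = "1", seed = 42)
#' glance(run)
#' @export
sir_run <- function(net, beta, gamma, infected, recovered = character(),
                    max_steps = NULL, seed = NULL) {
  net <- as_spread_network(net)
  state <- sir_state0(net, beta, gamma, infected, recovered)
  n <- igraph::vcount(net)
  if (is.null(max_steps)) max_steps <- 10L * n
  res <- with_local_seed(seed,
    cpp_sir_run(adj_list(net), state, beta, gamma, as.integer(max_steps)))
  if (!res$extinct)
    warn(sprintf("SIR run hit max_steps = %d before extinction", max_steps))
  structure(
    list(
      trajectory = tibble(step = seq_along(res$s) - 1L,
                          s = res$s, i = res$i, r = res$r),
      pr = res$r[length(res$r)] / n,
      steps = res$steps, extinct = res$extinct, n_nodes = n,
      beta = beta, gamma = gamma
    ),
    class = "sir_run"
  )
}

#' @export
print.sir_run <- function(x, ...) {
  cat(sprintf("<sir_run> N = %d, beta = %g, gamma = %g: Pr = %.4f after %d step(s)%s\n",
              x$n_nodes, x$beta, x$gamma, x$pr, x$steps,
              if (x$extinct) "" else " (not extinct)"))
  invisible(x)
}

#' @describeIn sir_run Trajectory as a tibble.
#' @param x A `sir_run`.
#' @param ... Unused.
#' @export
tidy.sir_run <- function(x, ...) x$trajectory

#' @describeIn sir_run One-row summary (`pr`, `steps`, `extinct`).
#' @export
glance.sir_run <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, beta = x$beta, gamma = x$gamma,
         pr = x$pr, steps = x$steps, extinct = x$extinct)
}

#' Ensemble of SIR realizations
#'
#' Runs `runs` independent realizations with child seeds derived from one
#' master seed, and averages them. Trajectories are padded to the longest run
#' by carrying each run's final state forward, so the per-step means are over
#' all runs at every step.
#'
#' @inheritParams sir_run
#' @param runs Number of independent realizations (default 100, the usual
#'   ensemble size for this kind of experiment).
#' @param seed Master seed; fixed seed gives a bit-identical ensemble.
#' @return An object of class `sir_ensemble`: `trajectory` (tibble `step`,
#'   `s`, `i`, `r` of per-step means), `pr_mean`, `pr_sd`, `pr` (per-run
#'   vector), `runs`.
#' @export
sir_ensemble <- function(net, beta, gamma, infected, recovered = character(),
                         runs = 100, max_steps = NULL, seed = NULL) {
  if (runs < 1) abort("`runs` must be >= 1")
  net <- as_spread_network(net)
  state0 <- sir_state0(net, beta, gamma, infected, recovered)
  n <- igraph::vcount(net)
  if (is.null(max_steps)) max_steps <- 10L * n
  adj <- adj_list(net)
  seeds <- child_seeds(seed, runs)
  sims <- lapply(seeds, function(s)
    with_local_seed(s, cpp_sir_run(adj, state0, beta, gamma,
                                   as.integer(max_steps))))
  len <- max(vapply(sims, function(x) length(x$s), integer(1)))
  pad <- function(v) c(v, rep(v[length(v)], len - length(v)))
  traj <- tibble(
    step = 0:(len - 1),
    s = rowMeans(sapply(sims, function(x) pad(x$s))),
    i = rowMeans(sapply(sims, function(x) pad(x$i))),
    r = rowMeans(sapply(sims, function(x) pad(x$r)))
  )
  prs <- vapply(sims, function(x) x$r[length(x$r)] / n, numeric(1))
  structure(
    list(trajectory = traj, pr_mean = mean(prs),
         pr_sd = if (runs > 1) sd(prs) else 0, pr = prs, runs = runs,
         n_nodes = n, beta = beta, gamma = gamma),
    class = "sir_ensemble"
  )
}

#' @export
print.sir_ensemble <- function(x, ...) {
  cat(sprintf("<sir_ensemble> %d run(s), N = %d, beta = %g, gamma = %g: Pr = %.4f (sd %.4f)\n",
              x$runs, x$n_nodes, x$beta, x$gamma, x$pr_mean, x$pr_sd))
  invisible(x)
}

#' @describeIn sir_ensemble Mean trajectory as a tibble.
#' @param x A `sir_ensemble`.
#' @param ... Unused.
#' @export
tidy.sir_ensemble <- function(x, ...) x$trajectory

#' @describeIn sir_ensemble One-row summary (`pr_mean`, `pr_sd`, `runs`).
#' @export
glance.sir_ensemble <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, beta = x$beta, gamma = x$gamma,
         pr_mean = x$pr_mean, pr_sd = x$pr_sd, runs = x$runs)
}

#' @describeIn sir_ensemble Plot the mean S/I/R trajectory.
#' @param object A `sir_ensemble`.
#' @export
autoplot.sir_ensemble <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trajectory, c("s", "i", "r"),
                            names_to = "compartment", values_to = "count")
  df$compartment <- factor(toupper(df$compartment), levels = c("S", "I", "R"))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$count,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "mean node count",
                  title = sprintf("SIR ensemble (beta = %g, gamma = %g, %d runs)",
                                  object$beta, object$gamma, object$runs))
}

#' Spreading experiment: final infection scale versus infection rate
#'
#' For each `beta` in the grid, runs an SIR ensemble with the given node set
#' as the initial infected nodes (no initial immunity) and records the mean
#' final recovered fraction `Pr` — the infection scale reached by those
#' seeds. Larger `Pr` means more effective spreaders.
#'
#' @inheritParams sir_ensemble
#' @param seed_set Non-empty character vector of seed (initially infected)
#'   nodes.
#' @param beta_grid Numeric vector of infection probabilities.
#' @return A tibble: `beta`, `mean_pr`, `sd_pr`, `runs`.
#' @export
spreading_experiment <- function(net, seed_set, beta_grid, gamma = 0.01,
                                 runs = 100, max_steps = NULL, seed = NULL) {
  net <- as_spread_network(net)
  seed_set <- as.character(seed_set)
  if (length(seed_set) == 0) abort("`seed_set` must be non-empty")
  if (length(beta_grid) == 0) abort("`beta_grid` must be non-empty")
  seeds <- child_seeds(seed, length(beta_grid))
  purrr::map2_dfr(beta_grid, seeds, function(b, s) {
    ens <- sir_ensemble(net, beta = b, gamma = gamma, infected = seed_set,
                        runs = runs, max_steps = max_steps, seed = s)
    tibble(beta = b, mean_pr = ens$pr_mean, sd_pr = ens$pr_sd, runs = runs)
  })
}

#' Immunization experiment: final infection scale under targeted immunity
#'
#' For each `beta`, the immune set starts in the recovered state and, in each
#' realization, a fresh uniform random sample of
#' `ceiling(infect_fraction * (N - |immune|))` non-immune nodes is infected.
#' The reported `Pr` is the fraction of nodes recovered *through infection*,
#' `(R_final - |immune|) / N`, so that the initially immunized nodes (which
#' start in R and are never infected) do not inflate the infection scale.
#' Lower mean `Pr` means better suppression by the immunized set.
#'
#' @inheritParams sir_ensemble
#' @param immune_set Nodes immunized up-front (may be empty; not all nodes).
#' @param infect_fraction Fraction of the non-immune population initially
#'   infected, in `(0, 1)`; default 0.05.
#' @return A tibble: `beta`, `mean_pr`, `sd_pr`, `runs`.
#' @export
immunization_experiment <- function(net, immune_set, beta_grid, gamma = 0.01,
                                    infect_fraction = 0.05, runs = 100,
                                    max_steps = NULL, seed = NULL) {
  net <- as_spread_network(net)
  immune_set <- as.character(immune_set)
  check_nodes(net, immune_set, "immune_set")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) abort("`gamma` must be in [0, 1]")
  if (!(infect_fraction > 0 && infect_fraction < 1))
    abort("`infect_fraction` must lie in (0, 1)")
  lab <- node_labels(net)
  pool <- setdiff(lab, immune_set)
  if (length(pool) == 0) abort("`immune_set` cannot cover every node")
  n_inf <- ceiling(infect_fraction * length(pool))
  if (length(beta_grid) == 0) abort("`beta_grid` must be non-empty")
  lab <- node_labels(net)
  n <- length(lab)
  if (is.null(max_steps)) max_steps <- 10L * n
  adj <- adj_list(net)
  base_state <- integer(n)
  base_state[lab %in% immune_set] <- 2L
  pool_idx <- match(pool, lab)
  bseeds <- child_seeds(seed, length(beta_grid))
  purrr::map2_dfr(beta_grid, bseeds, function(b, bs) {
    if (b < 0 || b > 1) abort("`beta_grid` values must be in [0, 1]")
    rseeds <- child_seeds(bs, runs)
    prs <- vapply(rseeds, function(s) {
      with_local_seed(s, {
        state <- base_state
        state[sample(pool_idx, n_inf)] <- 1L
        res <- cpp_sir_run(adj, state, b, gamma, as.integer(max_steps))
        (res$r[length(res$r)] - length(immune_set)) / n
      })
    }, numeric(1))
    tibble(beta = b, mean_pr = mean(prs),
           sd_pr = if (runs > 1) sd(prs) else 0, runs = runs)
  })
}

#' Plot spreading / immunization curves
#'
#' @param curves A tibble as returned by [spreading_experiment()] or
#'   [immunization_experiment()], optionally with a `method` column to
#'   compare several seed/immune sets.
#' @return A ggplot.
#' @export
plot_pr_curves <- function(curves) {
  aes <- if ("method" %in% names(curves))
    ggplot2::aes(.data$beta, .data$mean_pr, colour = .data$method)
  else ggplot2::aes(.data$beta, .data$mean_pr)
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta), y = expression(P[r]))
}
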