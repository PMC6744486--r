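#' Simulation-based recovery of one ginkgo demographic parameter
#'
#' The validation workflow for the shipped four-lineage model: simulate a
#' joint site frequency spectrum under the model's published best-fit
#' parameters (10 diploids per lineage by default), then re-estimate one
#' free parameter by maximizing the summed pairwise folded 2D-SFS
#' composite likelihood with all other parameters fixed at their generating
#' values. Common random numbers stabilize the Monte-Carlo objective.
#'
#' @param free One of `"f_north_south"` (NORTH ancestry fraction from
#'   SOUTH), `"t_split_swest"`, `"t_split_east_south"`, `"t_pulse_north"`
#'   (years), or `"n_anc"` (ancestral diploid size).
#' @param seed Integer seed; observation and search seeds are derived from
#'   it deterministically.
#' @param n_obs_reps Coalescent replicates for the observed spectrum
#'   (default 50000).
#' @param n_sims Coalescent replicates per likelihood evaluation
#'   (default 20000).
#' @param diploids Diploid samples per lineage (default 10).
#' @param n_restarts Seeded restarts of the 1-D search (default 2).
#' @return A list: `estimate`, `truth`, `bounds`, `fit`
#'   (the `demographic_fit`).
#' @export
ginkgo_parameter_recovery <- function(free, seed,
                                      n_obs_reps = 50000,
                                      n_sims = 20000,
                                      diploids = 10,
                                      n_restarts = 2) {
  specs <- list(
    f_north_south      = list(bounds = c(0.05, 0.999), truth = 0.7155),
    t_split_swest      = list(bounds = c(1e5, 2e6), truth = 515780),
    t_split_east_south = list(bounds = c(139261, 515779), truth = 318120),
    t_pulse_north      = list(bounds = c(1e4, 318000), truth = 139260),
    n_anc              = list(bounds = c(5e3, 5e5), truth = 50514))
  if (!free %in% names(specs))
    stop("unknown free parameter: ", free, call. = FALSE)
  par_spec <- specs[[free]]
  sc <- do.call(sample_config,
                as.list(setNames(rep(diploids, 4),
                                 c("EAST", "SOUTH", "NORTH", "SWEST"))))
  seed_obs <- (seed * 2003 + match(free, names(specs))) %% 2^30
  seed_fit <- (seed * 4007 + match(free, names(specs)) * 13) %% 2^30
  obs <- simulate_sfs(ginkgo_model(), sc, n_replicates = n_obs_reps,
                      folded = FALSE, seed = seed_obs)
  fit <- fit_model(obs, model_template("ginkgo_admixture"),
                   bounds = setNames(list(par_spec$bounds), free),
                   samples = sc, n_restarts = n_restarts, n_sims = n_sims,
                   n_cycles = 1, seed = seed_fit, pairwise_2d = TRUE)
  list(estimate = unname(fit$estimates[[free]]), truth = par_spec$truth,
       bounds = par_spec$bounds, fit = fit)
}
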