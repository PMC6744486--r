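#' Expected SFS under a demographic model (Monte Carlo)
#'
#' Wraps [simulate_sfs()] for likelihood work: the spectrum is normalized
#' over polymorphic cells and zero cells are floored at
#' `1 / (10 * n_sims * n_cells)` and renormalized, so the composite
#' likelihood stays finite wherever the observation has mass.
#'
#' @param model A [demographic_model()].
#' @param samples A [sample_config()].
#' @param n_sims Number of coalescent replicates.
#' @param seed Integer seed (fix it across evaluations for common random
#'   numbers).
#' @param folded Fold the spectrum?
#' @return A normalized [sfs_spectrum()].
#' @export
expected_sfs <- function(model, samples, n_sims, seed, folded = FALSE) {
  sfs <- simulate_sfs(model, samples, n_replicates = n_sims,
                      folded = folded, seed = seed, normalize = TRUE)
  mask <- monomorphic_mask(sfs)
  if (sfs$folded) {
    tot <- total_count_array(sfs$n_hap)
    mask <- mask | tot > sum(sfs$n_hap) / 2
  }
  v <- sfs$values
  floor_val <- 1 / (10 * n_sims * length(v))
  zero <- !mask & v <= 0
  v[zero] <- floor_val
  v[mask] <- 0
  sfs$values <- v / sum(v)
  sfs
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' `lnL = sum_cells m_cell * log(p_cell)` over polymorphic cells with
#' `m_cell > 0`, where `m` are observed cell weights (counts or proportions;
#' the maximizer is invariant to their scale) and `p` the expected
#' normalized spectrum. Monomorphic cells are masked in both.
#'
#' @param obs Observed [sfs_spectrum()] (counts or proportions).
#' @param expected Expected normalized [sfs_spectrum()] on the same lattice.
#' @return The composite log-likelihood (numeric scalar).
#' @examples
#' obs <- sfs_spectrum(c(0, 3, 7, 0), "A", 3)
#' ex <- sfs_spectrum(c(0, .3, .7, 0), "A", 3, normalized = TRUE)
#' composite_loglik(obs, ex)  # 3 log .3 + 7 log .7
#' @export
composite_loglik <- function(obs, expected) {
  stopifnot(inherits(obs, "sfs_spectrum"),
            inherits(expected, "sfs_spectrum"))
  if (!identical(dim(as.array(obs$values)), dim(as.array(expected$values))))
    stop("observed and expected SFS shapes differ", call. = FALSE)
  if (!identical(obs$demes, expected$demes))
    stop("observed and expected deme order differ", call. = FALSE)
  m <- obs$values
  p <- expected$values
  mask <- monomorphic_mask(obs)
  m[mask] <- 0
  use <- m > 0
  if (!any(use)) return(0)
  if (any(p[use] <= 0)) return(-Inf)
  sum(m[use] * log(p[use]))
}

#' Summed pairwise-2D composite log-likelihood
#'
#' The SFS likelihood convention of the study's demographic inference: the
#' joint spectrum is reduced to its two-dimensional marginals (one per deme
#' pair), each folded onto minor-allele counts, and the multinomial
#' composite log-likelihoods of all pairs are summed. Far fewer cells than
#' the full joint lattice, so Monte-Carlo noise per cell is much smaller.
#'
#' @param obs Observed unfolded joint [sfs_spectrum()] (counts or
#'   proportions) over >= 2 demes.
#' @param expected Expected unfolded joint [sfs_spectrum()] on the same
#'   lattice (raw or normalized; each 2D marginal is renormalized).
#' @param fold Fold each 2D marginal (default `TRUE`).
#' @param floor_n Flooring scale for empty expected cells; zero cells get
#'   `1 / (10 * floor_n * n_cells)` before renormalization.
#' @return The summed composite log-likelihood.
#' @export
composite_loglik_2d <- function(obs, expected, fold = TRUE,
                                floor_n = 20000) {
  stopifnot(inherits(obs, "sfs_spectrum"),
            inherits(expected, "sfs_spectrum"))
  if (length(obs$demes) < 2)
    stop("pairwise mode needs >= 2 demes", call. = FALSE)
  if (obs$folded || expected$folded)
    stop("pairwise mode expects unfolded joint spectra", call. = FALSE)
  if (!identical(obs$demes, expected$demes))
    stop("observed and expected deme order differ", call. = FALSE)
  pairs <- utils::combn(length(obs$demes), 2)
  tot <- 0
  for (k in seq_len(ncol(pairs))) {
    dd <- pairs[, k]
    om <- prep_pair_spectrum(sfs_marginal(obs, dd), fold = fold)
    ncell <- length(om$values)
    em <- prep_pair_spectrum(sfs_marginal(expected, dd), fold = fold,
                             floor_val = 1 / (10 * floor_n * ncell))
    tot <- tot + composite_loglik(om, em)
  }
  tot
}

#' Fit free demographic parameters by SFS composite likelihood
#'
#' Maximizes the multinomial composite log-likelihood over named free
#' parameters of a model template by cyclic conditional maximization: each
#' cycle runs a bracketed 1-D search (golden-section via [stats::optimize])
#' over one parameter at a time, in log-space for scale parameters. The
#' Monte-Carlo objective is stabilized with common random numbers: the
#' simulation seed is fixed within a cycle and refreshed between cycles.
#' Multiple seeded restarts from random starting points are kept; the best
#' restart is returned.
#'
#' @param obs_sfs Observed [sfs_spectrum()] (counts or proportions).
#' @param template A function `function(pars)` returning a
#'   [demographic_model()] from a named parameter vector.
#' @param bounds Named list of `c(lower, upper)` per free parameter
#'   (finite, positive).
#' @param samples A [sample_config()] matching `obs_sfs`.
#' @param n_restarts Number of seeded restarts (default 3).
#' @param n_sims Coalescent replicates per likelihood evaluation
#'   (default 20000).
#' @param n_cycles Conditional-maximization cycles per restart (default 2;
#'   a single cycle suffices for one free parameter).
#' @param seed Integer seed.
#' @param log_space Search in log-parameter space (default `TRUE`).
#' @param rel_tol Relative bracket tolerance of each 1-D search.
#' @param pairwise_2d Use the summed pairwise folded 2D-SFS composite
#'   likelihood ([composite_loglik_2d()]) instead of the full joint lattice;
#'   requires an unfolded joint `obs_sfs` over >= 2 demes.
#' @return A `demographic_fit`: `estimates` (named), `loglik`, `bounds`,
#'   `restart_logliks`, `n_sims`, `seed`, `template`.
#' @export
fit_model <- function(obs_sfs, template, bounds, samples,
                      n_restarts = 3, n_sims = 20000, n_cycles = 2,
                      seed = 1, log_space = TRUE, rel_tol = 1e-3,
                      pairwise_2d = FALSE) {
  stopifnot(is.function(template), length(bounds) >= 0)
  par_names <- names(bounds)
  if (length(bounds)) {
    for (b in bounds)
      if (any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
        stop("bounds must be finite, positive and increasing", call. = FALSE)
  }
  folded <- obs_sfs$folded
  if (pairwise_2d && folded)
    stop("pairwise_2d mode needs an unfolded joint obs_sfs", call. = FALSE)
  # invalid parameter combinations (e.g. a proposed split time that leaves
  # lineages with no ancestral path) get a large finite penalty so bracketed
  # searches pass through the region without warnings
  eval_ll <- function(pars, eval_seed) {
    tryCatch({
      model <- template(pars)
      if (pairwise_2d) {
        ex <- simulate_sfs(model, samples, n_replicates = n_sims,
                           folded = FALSE, seed = eval_seed,
                           normalize = FALSE)
        composite_loglik_2d(obs_sfs, ex, floor_n = n_sims)
      } else {
        ex <- expected_sfs(model, samples, n_sims = n_sims, seed = eval_seed,
                           folded = folded)
        composite_loglik(obs_sfs, ex)
      }
    }, error = function(e) -1e18)
  }
  if (!length(bounds)) {
    ll <- eval_ll(numeric(0), seed)
    return(structure(list(estimates = numeric(0), loglik = ll,
                          bounds = bounds, restart_logliks = ll,
                          n_sims = n_sims, seed = seed, template = template),
                     class = "demographic_fit"))
  }
  set.seed(seed %% .Machine$integer.max)
  restart_seeds <- sample.int(2^30, n_restarts)
  runs <- lapply(seq_len(n_restarts), function(r) {
    rs <- restart_seeds[r]
    set.seed(rs)
    pars <- vapply(bounds, function(b) {
      if (log_space) exp(runif(1, log(b[1]), log(b[2])))
      else runif(1, b[1], b[2])
    }, 0)
    names(pars) <- par_names
    ll <- -Inf
    for (cyc in seq_len(n_cycles)) {
      crn_seed <- (rs + cyc * 7919) %% 2^31   # fixed within the cycle
      for (pn in par_names) {
        f <- function(x) {
          p <- pars
          p[pn] <- if (log_space) exp(x) else x
          eval_ll(p, crn_seed)
        }
        b <- bounds[[pn]]
        interval <- if (log_space) log(b) else b
        opt <- tryCatch(
          optimize(f, interval = interval, maximum = TRUE, tol = rel_tol *
                     diff(interval)),
          error = function(e) NULL)
        if (is.null(opt)) next
        pars[pn] <- if (log_space) exp(opt$maximum) else opt$maximum
        ll <- opt$objective
      }
    }
    # score the final parameters on a fresh, larger common batch so restarts
    # are compared on the same footing
    ll_final <- eval_ll(pars, (seed + 104729) %% 2^31)
    list(pars = pars, loglik = ll_final)
  })
  logliks <- vapply(runs, `[[`, 0, "loglik")
  best <- runs[[which.max(logliks)]]
  structure(list(estimates = best$pars, loglik = max(logliks),
                 bounds = bounds, restart_logliks = logliks,
                 n_sims = n_sims, seed = seed, template = template),
            class = "demographic_fit")
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat("<demographic_fit> loglik =", format(x$loglik), "|",
      length(x$estimates), "free parameter(s)\n")
  for (pn in names(x$estimates))
    cat(sprintf("  %s = %.6g  [%g, %g]\n", pn, x$estimates[[pn]],
                x$bounds[[pn]][1], x$bounds[[pn]][2]))
  invisible(x)
}

#' @export
tidy.demographic_fit <- function(x, ...) {
  if (!length(x$estimates))
    return(tibble(parameter = character(0), estimate = numeric(0),
                  lower_bound = numeric(0), upper_bound = numeric(0)))
  tibble(parameter = names(x$estimates),
         estimate = unname(x$estimates),
         lower_bound = vapply(x$bounds, `[`, 0, 1),
         upper_bound = vapply(x$bounds, `[`, 0, 2))
}

#' @export
glance.demographic_fit <- function(x, ...) {
  tibble(loglik = x$loglik, k = length(x$estimates),
         n_restarts = length(x$restart_logliks), n_sims = x$n_sims,
         seed = x$seed)
}

#' Compare fitted models by AIC and Akaike weights
#'
#' `AIC = 2k - 2 lnL`; `Delta_i = AIC_i - min AIC`;
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`. The model with the
#' maximum weight is the preferred model.
#'
#' @param fits Named list of `demographic_fit` objects (or a list of
#'   `list(loglik=, k=)`).
#' @return A tibble: `model`, `k`, `loglik`, `aic`, `delta_aic`, `weight`,
#'   sorted by `delta_aic`.
#' @examples
#' compare_models(list(adm = list(loglik = -100, k = 3),
#'                     noadm = list(loglik = -110, k = 2)))
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits to compare", call. = FALSE)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model_", seq_along(fits))
  rows <- purrr::map2_dfr(fits, nm, function(f, name) {
    k <- if (inherits(f, "demographic_fit")) length(f$estimates) else f$k
    ll <- f$loglik
    tibble(model = name, k = k, loglik = ll, aic = 2 * k - 2 * ll)
  })
  rows$delta_aic <- rows$aic - min(rows$aic)
  w <- exp(-rows$delta_aic / 2)
  rows$weight <- w / sum(w)
  dplyr::arrange(rows, .data$delta_aic)
}

#' Parametric bootstrap confidence intervals for a demographic fit
#'
#' Simulates `n_boot` observed spectra from the fitted model (a multinomial
#' draw of `n_sites` polymorphic sites from the fitted expected SFS),
#' refits the free parameters on each, and reports percentile 2.5/97.5
#' intervals.
#'
#' @param fit A `demographic_fit`.
#' @param samples The [sample_config()] used for the fit.
#' @param n_boot Number of bootstrap replicates (>= 2; the study protocol
#'   uses 100).
#' @param n_sites Number of polymorphic sites per simulated spectrum.
#' @param seed Integer seed.
#' @param n_sims,n_restarts,n_cycles Refitting effort per replicate
#'   (defaults scaled down from the original fit).
#' @param folded Simulate folded spectra (ignored in `pairwise_2d` mode,
#'   which folds at the pair level).
#' @param pairwise_2d Refit with the pairwise folded 2D-SFS likelihood.
#' @return A `bootstrap_result` tibble: `parameter`, `estimate`,
#'   `ci_lower`, `ci_upper`, plus attributes `replicates` (matrix) and
#'   `seed`.
#' @export
parametric_bootstrap <- function(fit, samples, n_boot = 100, n_sites,
                                 seed = 1, n_sims = fit$n_sims,
                                 n_restarts = 1, n_cycles = 1,
                                 folded = TRUE, pairwise_2d = FALSE) {
  stopifnot(inherits(fit, "demographic_fit"))
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  model_hat <- fit$template(fit$estimates)
  if (pairwise_2d) folded <- FALSE
  ex <- expected_sfs(model_hat, samples, n_sims = max(n_sims, 20000),
                     seed = seed, folded = folded)
  p <- as.vector(ex$values)
  reps <- matrix(NA_real_, n_boot, length(fit$estimates),
                 dimnames = list(NULL, names(fit$estimates)))
  set.seed(seed %% .Machine$integer.max)
  boot_seeds <- sample.int(2^30, n_boot)
  for (b in seq_len(n_boot)) {
    counts <- as.vector(rmultinom(1, size = n_sites, prob = p))
    obs_b <- ex
    obs_b$values <- array(counts, dim = dim(as.array(ex$values)))
    obs_b$normalized <- FALSE
    refit <- fit_model(obs_b, fit$template, fit$bounds, samples,
                       n_restarts = n_restarts, n_sims = n_sims,
                       n_cycles = n_cycles, seed = boot_seeds[b],
                       pairwise_2d = pairwise_2d)
    reps[b, ] <- refit$estimates
  }
  out <- tibble(
    parameter = names(fit$estimates),
    estimate = unname(fit$estimates),
    ci_lower = apply(reps, 2, quantile, probs = 0.025, names = FALSE),
    ci_upper = apply(reps, 2, quantile, probs = 0.975, names = FALSE))
  attr(out, "replicates") <- reps
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_result", class(out))
  out
}

#' Shipped model templates for the four-lineage demography
#'
#' Returns a model-template function for use with [fit_model()]:
#' * `"ginkgo_admixture"` — the full four-deme model with two dated splits
#'   and the NORTH admixture pulse; free parameters may be any of
#'   `f_north_south`, `t_split_swest`, `t_split_east_south`,
#'   `t_pulse_north`, `n_anc`, `n_desc` (shared descendant size).
#' * `"ginkgo_no_admixture"` — a bifurcating alternative where NORTH splits
#'   from SOUTH (no pulse); free parameters as above minus `f_north_south`,
#'   plus `t_split_north`.
#' * `"single_deme"` — one constant-size deme; free parameter `n`.
#'
#' @param name Template name.
#' @param ... Fixed-parameter overrides applied after the free parameters.
#' @return A function `function(pars)` returning a [demographic_model()].
#' @export
model_template <- function(name = c("ginkgo_admixture",
                                    "ginkgo_no_admixture",
                                    "single_deme"), ...) {
  name <- match.arg(name)
  fixed <- list(...)
  switch(name,
    ginkgo_admixture = function(pars) {
      args <- utils::modifyList(as.list(fixed), as.list(pars))
      ok <- intersect(names(args),
                      names(formals(ginkgo_model)))
      do.call(ginkgo_model, c(args[ok],
        if ("n_desc" %in% names(args))
          list(n_east = args$n_desc, n_south = args$n_desc,
               n_north = args$n_desc, n_swest = args$n_desc)))
    },
    ginkgo_no_admixture = function(pars) {
      args <- utils::modifyList(as.list(fixed), as.list(pars))
      n_desc <- args$n_desc %||% 28456
      demographic_model(
        deme_sizes = c(EAST = args$n_east %||% n_desc,
                       SOUTH = args$n_south %||% n_desc,
                       NORTH = args$n_north %||% n_desc,
                       SWEST = args$n_swest %||% n_desc,
                       ES = args$n_es %||% (args$n_anc %||% 50514),
                       ANC = args$n_anc %||% 50514),
        splits = list(
          list(time_years = args$t_split_swest %||% 515780,
               child = "SWEST", parent = "ANC"),
          list(time_years = args$t_split_swest %||% 515780,
               child = "ES", parent = "ANC"),
          list(time_years = args$t_split_east_south %||% 318120,
               child = "EAST", parent = "ES"),
          list(time_years = args$t_split_east_south %||% 318120,
               child = "SOUTH", parent = "ES"),
          list(time_years = args$t_split_north %||% 139260,
               child = "NORTH", parent = "SOUTH")))
    },
    single_deme = function(pars) {
      args <- utils::modifyList(as.list(fixed), as.list(pars))
      demographic_model(deme_sizes = c(A = args$n %||% 10000))
    })
}
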