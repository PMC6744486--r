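test_that("the multinomial composite log-likelihood matches direct arithmetic", {
  obs <- sfs_spectrum(c(0, 3, 7, 0), "A", 3L)
  ex <- sfs_spectrum(c(0, 0.3, 0.7, 0), "A", 3L, normalized = TRUE)
  expect_equal(composite_loglik(obs, ex), 3 * log(0.3) + 7 * log(0.7))
  expect_equal(composite_loglik(obs, ex), -6.10864, tolerance = 1e-5)
  # shape mismatch
  ex2 <- sfs_spectrum(c(0, 0.5, 0.3, 0.2, 0), "A", 4L, normalized = TRUE)
  expect_error(composite_loglik(obs, ex2), "shapes")
  # monomorphic cells carry no weight
  obs_m <- sfs_spectrum(c(10, 3, 7, 2), "A", 3L)
  expect_equal(composite_loglik(obs_m, ex), composite_loglik(obs, ex))
})

test_that("the composite likelihood is maximized at the observed proportions", {
  obs <- sfs_spectrum(c(0, 5, 3, 2, 0), "A", 4L)
  p0 <- c(0, 0.5, 0.3, 0.2, 0)
  ll0 <- composite_loglik(obs, sfs_spectrum(p0, "A", 4L, normalized = TRUE))
  set.seed(2)
  for (i in 1:20) {
    d <- runif(3, -0.05, 0.05); d <- d - mean(d)
    p <- p0; p[2:4] <- p[2:4] + d
    if (any(p[2:4] <= 0)) next
    ll <- composite_loglik(obs, sfs_spectrum(p / sum(p), "A", 4L,
                                             normalized = TRUE))
    expect_lte(ll, ll0 + 1e-12)
  }
})

test_that("expected spectra are floored, normalized, and shrink like 1/sqrt(n)", {
  m <- demographic_model(deme_sizes = c(A = 4000))
  sc <- sample_config(A = 2)
  ex <- expected_sfs(m, sc, n_sims = 10000, seed = 5)
  expect_equal(sum(ex$values), 1)
  i <- 1:3
  expect_equal(as.vector(ex$values)[2:4], (1 / i) / sum(1 / i),
               tolerance = 0.03)
  # a floored zero cell keeps the likelihood finite
  obs <- sfs_spectrum(c(0, 1, 1, 1, 1), "A", 4L)
  ex_small <- expected_sfs(m, sample_config(A = 2), n_sims = 50, seed = 6)
  expect_true(is.finite(composite_loglik(
    sfs_spectrum(c(0, 1, 1, 1, 0), "A", 4L), ex_small)))
  # Monte-Carlo error scaling ~ 1/sqrt(n_sims)
  ref <- (1 / i) / sum(1 / i)
  err <- function(ns) {
    e <- vapply(1:12, function(r) {
      v <- expected_sfs(m, sc, n_sims = ns, seed = 100 + r)$values
      sqrt(mean((as.vector(v)[2:4] - ref)^2))
    }, 0)
    mean(e)
  }
  ratio <- err(4000) / err(1000)
  expect_lt(abs(ratio - 0.5), 0.25)
})

test_that("pairwise-2D composite likelihood reduces and folds per deme pair", {
  m <- demographic_model(
    deme_sizes = c(A = 2000, B = 2000, ANC = 2000),
    splits = list(list(time_years = 4e4, child = "A", parent = "ANC"),
                  list(time_years = 4e4, child = "B", parent = "ANC")),
    generation_time_years = 1)
  sc <- sample_config(A = 2, B = 2)
  obs <- simulate_sfs(m, sc, n_replicates = 5000, seed = 11, folded = FALSE)
  ex <- simulate_sfs(m, sc, n_replicates = 5000, seed = 12, folded = FALSE,
                     normalize = FALSE)
  ll <- composite_loglik_2d(obs, ex)
  expect_true(is.finite(ll))
  # one pair only: equals the single-pair computation done by hand
  om <- ginkgopop:::prep_pair_spectrum(sfs_marginal(obs, c(1, 2)))
  em <- ginkgopop:::prep_pair_spectrum(sfs_marginal(ex, c(1, 2)),
                                       floor_val = 1 / (10 * 20000 * 25))
  expect_equal(ll, composite_loglik(om, em))
  expect_error(composite_loglik_2d(fold_sfs(obs), ex), "unfolded")
})

test_that("marginalizing a joint SFS sums out the other demes", {
  v <- array(1:9, dim = c(3, 3))
  s <- sfs_spectrum(v, c("A", "B"), c(2L, 2L))
  mA <- sfs_marginal(s, "A")
  expect_equal(as.vector(mA$values), rowSums(v))
  mB <- sfs_marginal(s, "B")
  expect_equal(as.vector(mB$values), colSums(v))
  expect_error(sfs_marginal(s, "Z"), "unknown")
})

test_that("AIC and Akaike weights follow the closed form", {
  cmp <- compare_models(list(m1 = list(loglik = -100, k = 3),
                             m2 = list(loglik = -110, k = 2)))
  expect_equal(cmp$aic, c(206, 224))
  expect_equal(cmp$weight[1], 1 / (1 + exp(-9)), tolerance = 1e-9)
  expect_equal(sum(cmp$weight), 1)
  expect_true(all(cmp$delta_aic >= 0) && min(cmp$delta_aic) == 0)
  # identical models share the weight
  cmp2 <- compare_models(list(a = list(loglik = -50, k = 2),
                              b = list(loglik = -50, k = 2)))
  expect_equal(cmp2$weight, c(0.5, 0.5))
  # a dominated model does not change the winner
  cmp3 <- compare_models(list(m1 = list(loglik = -100, k = 3),
                              m2 = list(loglik = -110, k = 2),
                              m3 = list(loglik = -500, k = 2)))
  expect_equal(cmp3$model[1], "m1")
  # invariance to a constant shift in logliks
  cmp4 <- compare_models(list(m1 = list(loglik = -100 + 42, k = 3),
                              m2 = list(loglik = -110 + 42, k = 2)))
  expect_equal(cmp4$weight, cmp$weight, tolerance = 1e-12)
  expect_error(compare_models(list()), "no fits")
})

test_that("fit_model handles degenerate and invalid inputs", {
  m <- demographic_model(deme_sizes = c(A = 2000))
  sc <- sample_config(A = 2)
  obs <- simulate_sfs(m, sc, n_replicates = 2000, seed = 1)
  # all parameters fixed: evaluated loglik, no search
  fit <- fit_model(obs, function(p) m, bounds = list(), samples = sc,
                   n_sims = 2000, seed = 3)
  expect_length(fit$estimates, 0)
  expect_true(is.finite(fit$loglik))
  expect_error(
    fit_model(obs, function(p) m, bounds = list(n = c(-1, 5)), samples = sc),
    "bounds")
})

test_that("a free ancestral size is recovered from two-deme joint spectra", {
  truth <- 8000
  tpl <- function(pars) demographic_model(
    deme_sizes = c(A = 2000, B = 2000, ANC = pars[["n_anc"]]),
    splits = list(list(time_years = 2e4, child = "A", parent = "ANC"),
                  list(time_years = 2e4, child = "B", parent = "ANC")),
    generation_time_years = 1)
  sc <- sample_config(A = 4, B = 4)
  obs <- simulate_sfs(tpl(c(n_anc = truth)), sc, n_replicates = 20000,
                      seed = 21, folded = FALSE)
  fit <- fit_model(obs, tpl, list(n_anc = c(1000, 64000)), sc,
                   n_restarts = 2, n_sims = 10000, n_cycles = 1, seed = 22,
                   pairwise_2d = TRUE)
  expect_lt(abs(fit$estimates[["n_anc"]] - truth) / truth, 0.15)
  expect_equal(fit$loglik, max(fit$restart_logliks))
  td <- tidy(fit)
  expect_equal(td$parameter, "n_anc")
})

test_that("the admixture model beats a misspecified no-admixture alternative", {
  sc <- sample_config(EAST = 4, SOUTH = 4, NORTH = 4, SWEST = 4)
  obs <- simulate_sfs(ginkgo_model(), sc, n_replicates = 20000, seed = 31,
                      folded = FALSE)
  ex_true <- simulate_sfs(ginkgo_model(), sc, n_replicates = 20000,
                          seed = 32, folded = FALSE, normalize = FALSE)
  no_adm <- model_template("ginkgo_no_admixture")(numeric(0))
  ex_alt <- simulate_sfs(no_adm, sc, n_replicates = 20000, seed = 32,
                         folded = FALSE, normalize = FALSE)
  expect_gt(composite_loglik_2d(obs, ex_true),
            composite_loglik_2d(obs, ex_alt))
})

test_that("parametric bootstrap yields ordered intervals that cover the truth", {
  truth <- 8000
  tpl <- function(pars) demographic_model(
    deme_sizes = c(A = 2000, B = 2000, ANC = pars[["n_anc"]]),
    splits = list(list(time_years = 2e4, child = "A", parent = "ANC"),
                  list(time_years = 2e4, child = "B", parent = "ANC")),
    generation_time_years = 1)
  sc <- sample_config(A = 4, B = 4)
  obs <- simulate_sfs(tpl(c(n_anc = truth)), sc, n_replicates = 20000,
                      seed = 41, folded = FALSE)
  fit <- fit_model(obs, tpl, list(n_anc = c(1000, 64000)), sc,
                   n_restarts = 1, n_sims = 8000, n_cycles = 1, seed = 42,
                   pairwise_2d = TRUE)
  bt <- parametric_bootstrap(fit, sc, n_boot = 8, n_sites = 20000,
                             seed = 43, n_sims = 8000, pairwise_2d = TRUE)
  expect_equal(nrow(bt), 1)
  expect_lte(bt$ci_lower, bt$ci_upper)
  expect_true(bt$ci_lower <= truth && truth <= bt$ci_upper)
  reps <- attr(bt, "replicates")
  expect_equal(dim(reps), c(8, 1))
  expect_error(parametric_bootstrap(fit, sc, n_boot = 1, n_sites = 100),
               "n_boot")
})

test_that("bootstrap spread shrinks as the number of sites grows", {
  tpl <- function(pars) demographic_model(
    deme_sizes = c(A = 2000, B = 2000, ANC = pars[["n_anc"]]),
    splits = list(list(time_years = 2e4, child = "A", parent = "ANC"),
                  list(time_years = 2e4, child = "B", parent = "ANC")),
    generation_time_years = 1)
  sc <- sample_config(A = 4, B = 4)
  obs <- simulate_sfs(tpl(c(n_anc = 8000)), sc, n_replicates = 20000,
                      seed = 51, folded = FALSE)
  fit <- fit_model(obs, tpl, list(n_anc = c(1000, 64000)), sc,
                   n_restarts = 1, n_sims = 8000, n_cycles = 1, seed = 52,
                   pairwise_2d = TRUE)
  bt_small <- parametric_bootstrap(fit, sc, n_boot = 6, n_sites = 300,
                                   seed = 53, n_sims = 8000,
                                   pairwise_2d = TRUE)
  bt_large <- parametric_bootstrap(fit, sc, n_boot = 6, n_sites = 3000,
                                   seed = 53, n_sims = 8000,
                                   pairwise_2d = TRUE)
  v_small <- var(attr(bt_small, "replicates")[, 1])
  v_large <- var(attr(bt_large, "replicates")[, 1])
  expect_lt(v_large / v_small, 1)
})
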