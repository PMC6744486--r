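test_that("pairwise coalescence time averages 2N generations", {
  # E[T2] = 2N for two lineages in a constant deme
  N <- 2000
  m <- demographic_model(deme_sizes = c(A = N))
  sc <- sample_config(A = 1)   # one diploid = two haploid lineages
  tm <- vapply(1:3000, function(i)
    attr(simulate_genealogy(m, sc, seed = i), "tmrca"), 0)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("genealogies are deterministic under a fixed seed", {
  m <- ginkgo_model()
  sc <- sample_config(EAST = 2, SOUTH = 2, NORTH = 2, SWEST = 2)
  t1 <- simulate_genealogy(m, sc, seed = 99)
  t2 <- simulate_genealogy(m, sc, seed = 99)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
  t3 <- simulate_genealogy(m, sc, seed = 100)
  expect_false(identical(t1$edge.length, t3$edge.length))
  # simulated genealogies are valid ultrametric-from-present phylo trees
  expect_s3_class(t1, "phylo")
  expect_equal(ape::Ntip(t1), 16)   # 2 diploids x 4 demes = 16 haploids
  depth <- ape::node.depth.edgelength(t1)
  expect_equal(max(depth[1:16]) - min(depth[1:16]), 0, tolerance = 1e-8)
})

test_that("lineages with no ancestral path raise a model error", {
  m <- demographic_model(deme_sizes = c(A = 1000, B = 1000))
  sc <- sample_config(A = 1, B = 1)
  expect_error(simulate_genealogy(m, sc, seed = 1), "trapped")
})

test_that("the unfolded single-deme SFS follows the 1/i law", {
  m <- demographic_model(deme_sizes = c(A = 5000))
  s <- simulate_sfs(m, sample_config(A = 2), n_replicates = 20000, seed = 42)
  expected <- (1 / 1:3) / sum(1 / 1:3)   # (0.5455, 0.2727, 0.1818)
  expect_equal(as.vector(s$values)[2:4], expected, tolerance = 0.02)
  expect_equal(sum(s$values), 1)
  expect_equal(as.vector(s$values)[c(1, 5)], c(0, 0))
})

test_that("a split at (essentially) time zero behaves panmictically", {
  m1 <- demographic_model(
    deme_sizes = c(A = 5000, B = 5000, ANC = 5000),
    splits = list(list(time_years = 1e-9, child = "A", parent = "ANC"),
                  list(time_years = 1e-9, child = "B", parent = "ANC")))
  s_joint <- simulate_sfs(m1, sample_config(A = 1, B = 1),
                          n_replicates = 20000, seed = 7)
  # total allele-count distribution matches the panmictic spectrum
  tot <- ginkgopop:::total_count_array(s_joint$n_hap)
  merged <- vapply(1:3, function(k) sum(s_joint$values[tot == k]), 0)
  expect_equal(merged, (1 / 1:3) / sum(1 / 1:3), tolerance = 0.03)
})

test_that("an admixture pulse with fraction 1 degenerates to a merge", {
  # A pulses fully into B at t; identical in law to A splitting into B
  mk <- function(pulse) {
    ev_time <- 4000
    if (pulse)
      demographic_model(
        deme_sizes = c(A = 3000, B = 3000),
        admixture_pulses = list(list(time_years = ev_time, recipient = "A",
                                     sources = c(B = 1))),
        generation_time_years = 1)
    else
      demographic_model(
        deme_sizes = c(A = 3000, B = 3000),
        splits = list(list(time_years = ev_time, child = "A", parent = "B")),
        generation_time_years = 1)
  }
  s_pulse <- simulate_sfs(mk(TRUE), sample_config(A = 1, B = 1),
                          n_replicates = 15000, seed = 3)
  s_split <- simulate_sfs(mk(FALSE), sample_config(A = 1, B = 1),
                          n_replicates = 15000, seed = 4)
  expect_equal(as.vector(s_pulse$values), as.vector(s_split$values),
               tolerance = 0.05)
})

test_that("admixture pulses route lineages at the stated fraction", {
  f <- 0.3
  m <- demographic_model(
    deme_sizes = c(R = 1e7, S1 = 1000, S2 = 1000),  # huge R: no coalescence
    admixture_pulses = list(list(time_years = 100, recipient = "R",
                                 sources = c(S1 = f, S2 = 1 - f))),
    splits = list(list(time_years = 1e6, child = "S2", parent = "S1")),
    generation_time_years = 1)
  sc <- sample_config(R = 5, S1 = 1, S2 = 1)
  cm <- ginkgopop:::compile_model(m, sc)
  moved <- ginkgopop:::cpp_trace_pulse(
    cm$sizes, cm$events, cm$samples, cm$deme_index[["R"]],
    cm$deme_index[["S1"]], 400L, 12345)
  # with negligible pre-pulse coalescence each of 10 lineages is Bernoulli(f)
  k <- sum(moved); n <- 400 * 10
  expect_lt(abs(k / n - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("segregating-site counts match Watterson's expectation at 3 sigma", {
  N <- 1000; L <- 1e4; n_loci <- 600
  for (dip in c(1, 2, 5)) {        # n = 2, 4, 10 haploids
    n <- 2 * dip
    m <- demographic_model(deme_sizes = c(A = N), generation_time_years = 1,
                           mu_per_site_per_year = 1e-7,
                           mu_is_per_generation = TRUE)
    g <- simulate_genotypes(m, sample_config(A = dip), n_loci = n_loci,
                            locus_length_bp = L, seed = 1000 + n)
    a_n <- sum(1 / seq_len(n - 1))
    theta <- 4 * N * 1e-7
    exp_S <- theta * a_n * L * n_loci
    # per-locus S variance estimated empirically
    S_per_locus <- table(factor(g$chrom, levels = paste0("locus_", 1:n_loci)))
    se <- sd(S_per_locus) * sqrt(n_loci)
    expect_lt(abs(ncol(g$G) - exp_S), 3 * se)
  }
})

test_that("per-site diversity matches the 4 N mu neutral expectation", {
  N <- 5000; mu_gen <- 1e-6; L <- 1e4; n_loci <- 100
  m <- demographic_model(deme_sizes = c(A = N), generation_time_years = 1,
                         mu_per_site_per_year = mu_gen,
                         mu_is_per_generation = TRUE)
  g <- simulate_genotypes(m, sample_config(A = 5), n_loci = n_loci,
                          locus_length_bp = L, seed = 77)
  # per-locus pi to get an empirical standard error
  pis <- vapply(unique(g$chrom), function(ch) {
    idx <- which(g$chrom == ch)
    G <- g$G[, idx, drop = FALSE]
    n_s <- 2 * colSums(!is.na(G))
    p <- colSums(G) / n_s
    sum((n_s / (n_s - 1)) * 2 * p * (1 - p)) / L
  }, 0)
  se <- sd(pis) / sqrt(n_loci)
  expect_lt(abs(mean(pis) - 4 * N * mu_gen), 3 * se)
})

test_that("between-deme divergence grows linearly with split time", {
  N <- 500; mu <- 1e-6; L <- 5e3
  times <- c(2e4, 5e4, 1e5)     # generations (generation time 1)
  dxy <- vapply(seq_along(times), function(i) {
    m <- demographic_model(
      deme_sizes = c(A = N, B = N, ANC = N),
      splits = list(list(time_years = times[i], child = "A", parent = "ANC"),
                    list(time_years = times[i], child = "B", parent = "ANC")),
      generation_time_years = 1, mu_per_site_per_year = mu,
      mu_is_per_generation = TRUE)
    g <- simulate_genotypes(m, sample_config(A = 1, B = 1), n_loci = 150,
                            locus_length_bp = L, seed = 500 + i)
    A <- g$G[1, ]; B <- g$G[2, ]
    sum(abs(A - B)) / 2 / (150 * L)   # mean haploid-pair difference per site
  }, 0)
  slope <- coef(lm(dxy ~ times))[2]
  expect_gt(slope, 0)
  expect_lt(abs(slope - 2 * mu) / (2 * mu), 0.10)
})

test_that("mutation-free and degenerate inputs behave as documented", {
  m0 <- demographic_model(deme_sizes = c(A = 1000), mu_per_site_per_year = 0)
  g0 <- simulate_genotypes(m0, sample_config(A = 3), n_loci = 5,
                           locus_length_bp = 1e4, seed = 1)
  expect_equal(ncol(g0$G), 0)
  expect_error(simulate_genotypes(ginkgo_model(),
                                  sample_config(EAST = 2), n_loci = 0,
                                  locus_length_bp = 100, seed = 1), "n_loci")
})

test_that("genotype simulation is reproducible and VCF output byte-identical", {
  m <- demographic_model(deme_sizes = c(A = 2000), generation_time_years = 1,
                         mu_per_site_per_year = 1e-6,
                         mu_is_per_generation = TRUE)
  g1 <- simulate_genotypes(m, sample_config(A = 3), n_loci = 4,
                           locus_length_bp = 1e4, seed = 314)
  g2 <- simulate_genotypes(m, sample_config(A = 3), n_loci = 4,
                           locus_length_bp = 1e4, seed = 314)
  expect_identical(g1$G, g2$G)
  expect_identical(g1$pos, g2$pos)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g1, p1); write_vcf(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("cross-check: marginal SFS agrees with the closed form on 3 parameter sets", {
  for (cfg in list(list(N = 1000, n = 4), list(N = 20000, n = 6),
                   list(N = 500, n = 8))) {
    m <- demographic_model(deme_sizes = c(A = cfg$N))
    s <- simulate_sfs(m, sample_config(A = cfg$n / 2),
                      n_replicates = 15000, seed = cfg$N + cfg$n)
    i <- seq_len(cfg$n - 1)
    expect_equal(as.vector(s$values)[i + 1], (1 / i) / sum(1 / i),
                 tolerance = 0.04)
  }
})
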