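test_that("windows follow the 0-based half-open coordinate convention", {
  G <- matrix(rep(c(0L, 1L, 2L, 1L), 3), 4, 3)
  g <- gm_from_diploids(G, pops = c("A", "A", "B", "B"),
                        pos = c(99999L, 100000L, 150000L))
  tbl <- window_stats(g, "A", "B", window_bp = 1e5, min_snps = 1)
  expect_equal(tbl$start, c(0, 100000))
  expect_equal(tbl$end, c(100000, 200000))
  # site at position 100,000 falls in the second window
  expect_equal(tbl$n_snps, c(1L, 2L))
  expect_error(window_stats(gm_from_diploids(matrix(integer(0), 4, 0),
                                             pops = c("A", "A", "B", "B")),
                            "A", "B"), "empty")
})

test_that("Z columns are standardized over non-missing windows", {
  set.seed(61)
  n_win <- 40
  pos <- as.integer(unlist(lapply(0:(n_win - 1), function(w)
    w * 1e5 + sort(sample(1e5 - 1, 12)))))
  G <- matrix(rbinom(20 * length(pos), 2, 0.3), 20, length(pos))
  g <- gm_from_diploids(G, pops = rep(c("A", "B"), each = 10), pos = pos,
                        locus_length_bp = n_win * 1e5)
  tbl <- window_stats(g, "A", "B", min_snps = 10)
  ok <- !is.na(tbl$z_he)
  expect_equal(mean(tbl$z_he[ok]), 0, tolerance = 1e-6)
  expect_equal(sd(tbl$z_he[ok]), 1, tolerance = 1e-6)
  expect_equal(mean(tbl$z_fst[ok]), 0, tolerance = 1e-6)
  expect_equal(sd(tbl$z_fst[ok]), 1, tolerance = 1e-6)
  expect_true(all(!tbl$selected))
})

test_that("identical windows yield zero Z-scores and no calls", {
  # same allele frequencies everywhere -> no variation between windows
  G <- matrix(rep(c(0L, 2L), 50), 2, 50)
  pos <- as.integer(seq(1000, 490000, length.out = 50))
  g <- gm_from_diploids(G, pops = c("A", "B"), pos = pos,
                        locus_length_bp = 5e5)
  tbl <- window_stats(g, "A", "B", min_snps = 1)
  expect_true(all(abs(tbl$z_he) < 1e-9))
  expect_true(all(!call_selected_windows(tbl)$selected))
})

test_that("a fixed-difference window attains the top Z_FST", {
  set.seed(62)
  n_win <- 12; per <- 15
  pos <- as.integer(unlist(lapply(0:(n_win - 1), function(w)
    w * 1e5 + sort(sample(1e5 - 1, per)))))
  G <- matrix(rbinom(12 * length(pos), 2, 0.5), 12, length(pos))
  sweep_cols <- (3 * per + 1):(4 * per)      # window 4
  G[1:6, sweep_cols] <- 0L
  G[7:12, sweep_cols] <- 2L
  g <- gm_from_diploids(G, pops = rep(c("A", "B"), each = 6), pos = pos,
                        locus_length_bp = n_win * 1e5)
  tbl <- window_stats(g, "A", "B", min_snps = 5)
  expect_equal(which.max(tbl$z_fst), 4L)
  called <- call_selected_windows(tbl)
  expect_true(called$selected[4])
})

test_that("the window caller applies the joint-tail rule", {
  tbl <- tibble::tibble(chrom = "c", start = 0:3 * 1e5,
                        end = 1:4 * 1e5, n_snps = 10L,
                        he = 0.1, fst = 0.1,
                        z_he = c(-3, 0, -1, 2), z_fst = c(3, 3, 0.5, -1),
                        selected = FALSE)
  out <- call_selected_windows(tbl)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, FALSE))
  out0 <- call_selected_windows(tbl, z_fst_min = 0.2, z_he_max = -0.2)
  expect_equal(out0$selected, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("at 1%-tail defaults few null windows are called", {
  set.seed(63)
  n_win <- 1000; per <- 10
  pos <- as.integer(unlist(lapply(0:(n_win - 1), function(w)
    w * 1e5 + sort(sample(1e5 - 1, per)))))
  G <- matrix(rbinom(16 * length(pos), 2, 0.4), 16, length(pos))
  g <- gm_from_diploids(G, pops = rep(c("A", "B"), each = 8), pos = pos,
                        locus_length_bp = n_win * 1e5)
  tbl <- call_selected_windows(window_stats(g, "A", "B", min_snps = 5))
  expect_lte(mean(tbl$selected), 0.03)
})

test_that("the background spectrum tabulates folded minor-allele counts", {
  # all singletons
  G <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  g <- gm_from_diploids(G)
  bg <- background_spectrum(g)
  expect_equal(unname(bg[1]), 1)
  expect_equal(sum(bg), 1)
  # neutral simulator output follows the folded 1/i + 1/(n-i) law; many
  # short loci keep the genealogical (between-tree) variance manageable
  m <- demographic_model(deme_sizes = c(A = 3000), generation_time_years = 1,
                         mu_per_site_per_year = 2e-6,
                         mu_is_per_generation = TRUE)
  gs <- simulate_genotypes(m, sample_config(A = 4), n_loci = 2000,
                           locus_length_bp = 1e3, seed = 64)
  bgs <- background_spectrum(gs)
  n <- 8; i <- 1:4
  th <- 1 / i + 1 / (n - i); th[4] <- 1 / 4   # hinge class counted once
  expect_lt(max(abs(unname(bgs) - th / sum(th))), 0.02)
  # a single homozygous individual has no usable polymorphic site
  expect_error(background_spectrum(gm_from_diploids(
    matrix(c(2L, 0L), 1, 2))), "polymorphic")
})

test_that("CLR is identically zero when sites reproduce the background", {
  # at every distance the local spectrum equals the background exactly:
  # three position clusters, each holding the full background composition,
  # so no distance-dependent model can beat the background (Gibbs)
  n_hap <- 8
  block <- rep(1:4, times = c(24, 12, 8, 3))   # ~ 1/i + 1/(n-i), hinge half
  counts <- rep(block, 3)
  pos <- rep(c(10000, 20000, 30000), each = length(block))
  bg <- structure(setNames(tabulate(block, 4) / length(block), 1:4),
                  n_hap = n_hap, class = "sfs_background")
  scan <- clr_scan(counts, pos, bg, grid_points = c(5050, 15050, 25016))
  expect_equal(scan$clr, rep(0, 3))
  expect_true(all(is.na(scan$alpha_hat)))
})

test_that("the sweep model collapses to the background in the escape limit", {
  n_hap <- 8
  counts <- rep(1:4, times = c(24, 12, 8, 3))
  bg <- structure(setNames(tabulate(counts, 4) / length(counts), 1:4),
                  n_hap = n_hap, class = "sfs_background")
  pos <- seq(1e6, by = 1e4, length.out = length(counts))
  # grid point far away + huge alpha only: p_e ~ 1 everywhere
  scan <- clr_scan(counts, pos, bg, grid_points = 1,
                   alpha_grid = c(10, 100))
  expect_equal(scan$clr, 0, tolerance = 1e-8)
})

test_that("CLR scans are non-negative and empty input gives empty output", {
  bg <- structure(setNames(c(0.6, 0.25, 0.1, 0.05), 1:4),
                  n_hap = 8, class = "sfs_background")
  empty <- clr_scan(integer(0), numeric(0), bg)
  expect_equal(nrow(empty), 0)
  set.seed(65)
  counts <- sample(1:4, 120, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05))
  scan <- clr_scan(counts, sort(sample(1e6, 120)), bg,
                   grid_points = seq(1e5, 9e5, length.out = 9))
  expect_true(all(scan$clr >= 0))
  expect_true(all(is.na(scan$alpha_hat) | scan$alpha_hat > 0))
})

test_that("injected sweeps are localized by the CLR scan", {
  # 21 independent 20 kb loci laid out as one 420 kb pseudo-chromosome
  # (free recombination between loci); the middle locus carries the sweep
  m <- demographic_model(deme_sizes = c(A = 4000), generation_time_years = 1,
                         mu_per_site_per_year = 1e-6,
                         mu_is_per_generation = TRUE)
  hits <- 0; center_beats_far <- 0; n_runs <- 10
  for (r in 1:n_runs) {
    g <- simulate_genotypes(
      m, sample_config(A = 8), n_loci = 21, locus_length_bp = 2e4,
      seed = 7000 + r,
      sweep_injection = list(chrom = "locus_11", start = 0, end = 2e4,
                             escape_frac = 0.05))
    locus <- as.integer(sub("locus_", "", g$chrom))
    gpos <- (locus - 1) * 2e4 + g$pos
    n_hap <- 16
    ac <- colSums(g$G)
    minor <- pmin(ac, n_hap - ac)
    bg <- background_spectrum(g)
    grid <- seq(1e4, 4.1e5, by = 2e4)      # one point per locus centre
    scan <- clr_scan(minor, gpos, bg, grid_points = grid)
    inside <- scan$position > 2e5 & scan$position <= 2.2e5
    if (max(scan$clr[inside]) > max(scan$clr[!inside])) hits <- hits + 1
    # the sweep centre beats every point >= 5 sweep-widths away
    far <- max(scan$clr[abs(scan$position - 2.1e5) >= 1e5])
    if (scan$clr[inside][1] >= far) center_beats_far <- center_beats_far + 1
    expect_true(all(scan$clr >= 0))
  }
  expect_gte(hits, 9)
  expect_gte(center_beats_far, 9)
})

test_that("window tables and sweep scans serialize to annotated TSVs", {
  tbl <- tibble::tibble(chrom = "locus_1", start = 0, end = 1e5,
                        n_snps = 10L, he = 0.2, fst = 0.1, z_he = 0,
                        z_fst = 0, selected = FALSE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_window_table(tbl, p1, comment = "subcommand=scan seed=1")
  lines <- readLines(p1)
  expect_match(lines[1], "^# subcommand=scan seed=1")
  expect_match(lines[2], "^chrom\tstart\tend")
  scan <- tibble::tibble(position = 1, clr = 0, alpha_hat = NA_real_)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_scan(scan, p2, comment = "x")
  expect_equal(length(readLines(p2)), 3)
})
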