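#' Windowed heterozygosity and F_ST with Z-scores
#'
#' Computes, in non-overlapping windows along each chromosome, the focal
#' group's mean expected heterozygosity and its Hudson F_ST against the
#' other group, then Z-transforms both columns across all non-missing
#' windows (chromosome-set-wide). Windows are 0-based half-open
#' `[k*w, (k+1)*w)`; a site is assigned by `floor(pos / w)`. Windows with
#' fewer than `min_snps` usable SNPs are reported with `NA` statistics.
#'
#' @param g A `genotype_matrix`.
#' @param focal_pop Focal population label (H_E is computed here).
#' @param other_pop Contrast population label (for F_ST).
#' @param window_bp Window size in bp (default 100000).
#' @param min_snps Minimum SNPs per window (default 10).
#' @return A `window_table` tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `he`, `fst`, `z_he`, `z_fst`, `selected` (all `FALSE` until
#'   [call_selected_windows()] is applied).
#' @export
window_stats <- function(g, focal_pop, other_pop, window_bp = 1e5,
                         min_snps = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (window_bp <= 0) stop("window_bp must be > 0", call. = FALSE)
  if (ncol(g$G) == 0) stop("empty genotype input", call. = FALSE)
  win <- g$pos %/% window_bp
  key <- paste0(g$chrom, ":", win)
  rows <- purrr::map_dfr(unique(key), function(k) {
    s <- which(key == k)
    chrom <- g$chrom[s[1]]
    w0 <- win[s[1]]
    n <- length(s)
    if (n < min_snps) {
      he <- NA_real_; fst <- NA_real_
    } else {
      he <- expected_heterozygosity(g, focal_pop, sites = s)
      fst <- tryCatch(pairwise_fst(g, focal_pop, other_pop, sites = s),
                      error = function(e) NA_real_)
    }
    tibble(chrom = chrom, start = w0 * window_bp,
           end = (w0 + 1) * window_bp, n_snps = n, he = he, fst = fst)
  })
  rows <- dplyr::arrange(rows, .data$chrom, .data$start)
  rows$z_he <- z_transform(rows$he)
  rows$z_fst <- z_transform(rows$fst)
  rows$selected <- FALSE
  class(rows) <- c("window_table", class(rows))
  rows
}

z_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2 || sd(x[ok]) == 0) return(ifelse(ok, 0, NA_real_))
  (x - mean(x[ok])) / sd(x[ok])
}

#' Flag selected windows by joint Z-score tails
#'
#' A window is called selected when differentiation is extreme and focal
#' diversity depleted: `Z_FST >= z_fst_min` and `Z_HE <= z_he_max`.
#' Defaults are the 1% normal tails (2.326 / -2.326).
#'
#' @param tbl A `window_table` from [window_stats()].
#' @param z_fst_min Lower bound on Z_FST (default `qnorm(0.99)` rounded).
#' @param z_he_max Upper bound on Z_HE (default `-2.326`).
#' @return The table with the `selected` flag set.
#' @export
call_selected_windows <- function(tbl, z_fst_min = 2.326,
                                  z_he_max = -2.326) {
  stopifnot(all(c("z_he", "z_fst") %in% names(tbl)))
  tbl$selected <- !is.na(tbl$z_fst) & !is.na(tbl$z_he) &
    tbl$z_fst >= z_fst_min & tbl$z_he <= z_he_max
  tbl
}

#' Genome-wide folded background spectrum
#'
#' The folded marginal site frequency spectrum of one population (as
#' proportions over minor-allele counts `1..floor(n/2)`), used as the
#' neutral background model of the CLR scan.
#'
#' @param g A `genotype_matrix`.
#' @param pop Population label (or `NULL` for all samples).
#' @return A named numeric vector of proportions with attribute
#'   `n_hap`; class `sfs_background`.
#' @export
background_spectrum <- function(g, pop = NULL) {
  G <- subset_pop(g, pop)
  n_hap <- 2L * nrow(G)
  if (n_hap < 2) stop("need at least 2 haploids", call. = FALSE)
  complete <- colSums(is.na(G)) == 0
  ac <- colSums(G[, complete, drop = FALSE])
  ac <- ac[ac > 0 & ac < n_hap]
  minor <- pmin(ac, n_hap - ac)
  kmax <- floor(n_hap / 2)
  counts <- tabulate(minor, nbins = kmax)
  if (sum(counts) == 0) stop("no polymorphic complete site", call. = FALSE)
  structure(setNames(counts / sum(counts), seq_len(kmax)),
            n_hap = n_hap, class = "sfs_background")
}

# symmetric unfolded spectrum over 0..n implied by a folded background:
# mass of each folded class split equally between j and n - j
unfold_symmetric <- function(bg) {
  n <- attr(bg, "n_hap")
  p <- numeric(n + 1)
  for (j in seq_along(bg)) {
    if (j == n - j) p[j + 1] <- p[j + 1] + bg[j]
    else {
      p[j + 1] <- p[j + 1] + bg[j] / 2
      p[n - j + 1] <- p[n - j + 1] + bg[j] / 2
    }
  }
  p / sum(p)
}

# hypergeometric projection of an unfolded spectrum on n lineages down to k:
# P_k(j') = sum_j p(j) * C(j, j') C(n-j, k-j') / C(n, k)
project_spectrum <- function(p_unf, n, k) {
  if (k == 0) return(1)
  out <- numeric(k + 1)
  for (j in 0:n) {
    if (p_unf[j + 1] == 0) next
    jp <- max(0, k - (n - j)):min(k, j)
    out[jp + 1] <- out[jp + 1] +
      p_unf[j + 1] * exp(lchoose(j, jp) + lchoose(n - j, k - jp) -
                           lchoose(n, k))
  }
  out
}

#' Composite-likelihood-ratio scan for selective sweeps
#'
#' SweepFinder/SweeD-style test. At each grid position and candidate sweep
#' intensity `alpha`, each of the `n` lineages at a site at distance `d`
#' escapes the sweep independently with probability
#' `p_e = 1 - exp(-alpha * d)`; the sweep-modified spectrum mixes, over the
#' binomial number of escapees `k`, the background spectrum projected to
#' `k` lineages with the non-escaping lineages collapsed onto the swept
#' allele class. Spectra are conditioned on polymorphism and folded before
#' scoring. `CLR(x) = 2 [ max_alpha lnL_sweep - lnL_background ]`, floored
#' at zero (the large-`alpha` limit recovers the background model exactly).
#'
#' @param minor_counts Integer folded minor-allele counts per site
#'   (`1..floor(n/2)`).
#' @param positions Site positions in bp (same length).
#' @param background A [background_spectrum()].
#' @param grid_points Grid positions (bp) to test; default 50 points
#'   spanning the site range.
#' @param alpha_grid Candidate intensities per bp; default 21 log-spaced
#'   values in `[1e-5, 1e2]`.
#' @return A `sweep_scan` tibble: `position`, `clr`, `alpha_hat`.
#' @export
clr_scan <- function(minor_counts, positions, background,
                     grid_points = NULL, alpha_grid = NULL) {
  stopifnot(inherits(background, "sfs_background"))
  if (length(minor_counts) != length(positions))
    stop("minor_counts and positions lengths differ", call. = FALSE)
  if (!length(minor_counts)) {
    out <- tibble(position = numeric(0), clr = numeric(0),
                  alpha_hat = numeric(0))
    class(out) <- c("sweep_scan", class(out))
    return(out)
  }
  n <- attr(background, "n_hap")
  kmax <- floor(n / 2)
  if (any(minor_counts < 1 | minor_counts > kmax))
    stop("minor counts must lie in 1..floor(n/2)", call. = FALSE)
  if (is.null(grid_points))
    grid_points <- seq(min(positions), max(positions), length.out = 50)
  if (is.null(alpha_grid))
    alpha_grid <- exp(seq(log(1e-5), log(1e2), length.out = 21))
  p_unf <- unfold_symmetric(background)
  proj <- lapply(0:n, function(k) project_spectrum(p_unf, n, k))
  log_bg <- log(pmax(background, 1e-300))
  ll_bg_site <- log_bg[minor_counts]
  # folded sweep spectrum for a given escape probability, classes 1..kmax
  sweep_folded <- function(pe) {
    probs <- numeric(n + 1)  # unfolded derived counts 0..n
    wk <- stats::dbinom(0:n, n, pe)
    for (k in 0:n) {
      if (wk[k + 1] < 1e-12) next
      pk <- proj[[k + 1]]                 # escaped allele counts 0..k
      j <- 0:k + (n - k)                  # + swept class on non-escapees
      probs[j + 1] <- probs[j + 1] + wk[k + 1] * pk
    }
    f <- numeric(kmax)
    for (c in 1:kmax) {
      f[c] <- probs[c + 1] + if (c != n - c) probs[n - c + 1] else 0
    }
    s <- sum(f)
    if (s <= 0) rep(1e-300, kmax) else f / s
  }
  # escape probabilities are bucketed to 1/1000, so at most 1001 distinct
  # sweep spectra are ever computed; per-class log-likelihoods fill a
  # lazily-computed lookup matrix (bucket x folded class)
  LSW <- matrix(NA_real_, 1001L, kmax)
  ensure_buckets <- function(buckets) {
    todo <- buckets[is.na(LSW[buckets, 1L])]
    for (b in unique(todo))
      LSW[b, ] <<- log(pmax(sweep_folded((b - 1L) / 1000), 1e-300))
  }
  rows <- purrr::map_dfr(grid_points, function(x) {
    d <- abs(positions - x)
    best_ll <- -Inf; best_alpha <- NA_real_
    ll_bg <- sum(ll_bg_site)
    for (a in alpha_grid) {
      bucket <- as.integer(round(1000 * (1 - exp(-a * d)))) + 1L
      ensure_buckets(bucket)
      ll <- sum(LSW[cbind(bucket, minor_counts)])
      if (ll > best_ll) { best_ll <- ll; best_alpha <- a }
    }
    clr <- max(0, 2 * (best_ll - ll_bg))
    tibble(position = x, clr = clr,
           alpha_hat = if (clr > 0) best_alpha else NA_real_)
  })
  class(rows) <- c("sweep_scan", class(rows))
  rows
}

#' @export
autoplot.sweep_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$clr)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "position (bp)", y = "CLR")
}

#' Manhattan-style plot of windowed Z-scores
#' @param object A `window_table`.
#' @param ... Unused.
#' @return A ggplot object showing Z_FST (positive axis) and Z_HE.
#' @export
autoplot.window_table <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("z_he", "z_fst"),
                            names_to = "statistic", values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$z,
                                   colour = .data$statistic)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::geom_hline(yintercept = c(-2.326, 2.326),
                        linetype = "dotted") +
    ggplot2::labs(x = "window midpoint (bp)", y = "Z-score")
}

#' Write a window table as BED-compatible TSV
#' @param tbl A `window_table`.
#' @param path Output path.
#' @param comment Optional provenance line.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(tbl, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(tbl), collapse = "\t"), con)
  write.table(as.data.frame(tbl), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sweep scan as TSV (position, CLR, alpha_hat)
#' @param scan A `sweep_scan`.
#' @param path Output path.
#' @param comment Optional provenance line.
#' @return `path`, invisibly.
#' @export
write_sweep_scan <- function(scan, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("position\tclr\talpha_hat", con)
  write.table(as.data.frame(scan), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
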