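#' Nucleotide diversity (pi)
#'
#' The average number of pairwise nucleotide differences per site,
#' computed from per-site allele frequencies with the unbiased small-sample
#' correction: `pi = (1/L) * sum_s n_s/(n_s - 1) * 2 p_s (1 - p_s)`, where
#' `n_s` is the number of non-missing haploid calls and `p_s` the
#' alternate-allele frequency at site `s`. This equals the mean pairwise
#' difference count divided by `L`.
#'
#' @param g A `genotype_matrix`.
#' @param pop Optional population label(s); defaults to all samples.
#' @param total_length_bp Total callable sequence length L (bp).
#' @return Per-site nucleotide diversity (numeric scalar).
#' @export
nucleotide_diversity <- function(g, pop = NULL, total_length_bp) {
  if (total_length_bp <= 0) stop("total_length_bp must be > 0", call. = FALSE)
  G <- subset_pop(g, pop)
  if (ncol(G) == 0) return(0)
  n_s <- 2 * colSums(!is.na(G))
  p_s <- colSums(G, na.rm = TRUE) / n_s
  use <- n_s >= 2
  sum((n_s[use] / (n_s[use] - 1)) * 2 * p_s[use] * (1 - p_s[use])) /
    total_length_bp
}

subset_pop <- function(g, pop) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(pop)) g$G else g$G[pop_rows(g, pop), , drop = FALSE]
}

#' Watterson's theta per base pair
#'
#' `theta_W = S / (a_{n-1} * L)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`,
#' `S` the number of segregating sites, `n` the haploid sample size.
#'
#' @param S Number of segregating sites.
#' @param n Haploid sample size (>= 2).
#' @param L Sequence length in bp (> 0).
#' @return Watterson's estimator per site.
#' @examples
#' watterson_theta(5, 2, 1000)  # 0.005
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("haploid sample size must be >= 2", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  a <- sum(1 / seq_len(n - 1))
  S / (a * L)
}

#' Mean expected heterozygosity over sites
#'
#' Mean over sites of `2 p (1 - p)` with `p` the alternate-allele frequency
#' in the chosen samples.
#'
#' @param g A `genotype_matrix`.
#' @param pop Optional population label(s).
#' @param sites Optional integer site indices (default: all).
#' @return Mean H_E, or `NA_real_` when no usable site remains.
#' @export
expected_heterozygosity <- function(g, pop = NULL, sites = NULL) {
  G <- subset_pop(g, pop)
  if (!is.null(sites)) G <- G[, sites, drop = FALSE]
  n_s <- 2 * colSums(!is.na(G))
  use <- n_s >= 2
  if (!any(use)) return(NA_real_)
  p <- colSums(G[, use, drop = FALSE], na.rm = TRUE) / n_s[use]
  mean(2 * p * (1 - p))
}

#' Pairwise F_ST between two populations
#'
#' Hudson's estimator in ratio-of-averages form:
#' `F_ST = sum_s N_s / sum_s D_s` with
#' `N_s = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D_s = p1(1-p2) + p2(1-p1)`; frequencies are per-population
#' alternate-allele frequencies and `n1`, `n2` haploid counts. Negative
#' values are reported as computed. A Weir-Cockerham variant is available
#' behind `estimator = "wc"`.
#'
#' @param g A `genotype_matrix`.
#' @param pop_a,pop_b Population labels.
#' @param sites Optional site indices.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return F_ST (numeric scalar).
#' @export
pairwise_fst <- function(g, pop_a, pop_b, sites = NULL,
                         estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  G1 <- subset_pop(g, pop_a)
  G2 <- subset_pop(g, pop_b)
  if (!is.null(sites)) {
    G1 <- G1[, sites, drop = FALSE]
    G2 <- G2[, sites, drop = FALSE]
  }
  n1 <- 2 * colSums(!is.na(G1)); n2 <- 2 * colSums(!is.na(G2))
  use <- n1 >= 2 & n2 >= 2
  if (!any(use))
    stop("both populations need >= 2 haploid calls at some site",
         call. = FALSE)
  p1 <- colSums(G1[, use, drop = FALSE], na.rm = TRUE) / n1[use]
  p2 <- colSums(G2[, use, drop = FALSE], na.rm = TRUE) / n2[use]
  n1 <- n1[use]; n2 <- n2[use]
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir & Cockerham (1984) theta for two populations, haploid counts
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
    num <- s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1)
    den <- ((nc - 1) / (nbar - 1)) * pbar * (1 - pbar) +
      (1 + (nbar - nc) / (nbar - 1)) * s2 / 2
  }
  keep <- is.finite(num) & is.finite(den)
  sum(num[keep]) / sum(den[keep])
}

#' Joint site frequency spectrum from genotypes
#'
#' Counts polymorphic (and monomorphic) sites by their per-population
#' alternate-allele count. Sites with any missing call in the involved
#' populations are excluded. Folding uses the global minor allele.
#'
#' @param g A `genotype_matrix`.
#' @param pops Population labels (one array dimension each).
#' @param folded Fold onto minor-allele counts?
#' @return A [sfs_spectrum()] of site counts (not normalized).
#' @export
joint_sfs <- function(g, pops, folded = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  mats <- lapply(pops, function(p) subset_pop(g, p))
  n_hap <- vapply(mats, function(m) 2L * nrow(m), 0L)
  complete <- Reduce(`&`, lapply(mats, function(m) colSums(is.na(m)) == 0))
  counts <- lapply(mats, function(m)
    colSums(m[, complete, drop = FALSE], na.rm = TRUE))
  dims <- n_hap + 1L
  v <- array(0, dim = dims)
  if (any(complete)) {
    idx <- do.call(cbind, counts) + 1L
    for (r in seq_len(nrow(idx))) {
      cell <- matrix(idx[r, ], nrow = 1)
      v[cell] <- v[cell] + 1
    }
  }
  sfs <- sfs_spectrum(v, demes = pops, n_hap = n_hap)
  if (folded) sfs <- fold_sfs(sfs)
  sfs
}

#' Per-population diversity summary
#'
#' Table-style summary per population: number of samples, SNP count, mean
#' per-site pi and Watterson's theta, with standard deviations across
#' non-overlapping windows.
#'
#' @param g A `genotype_matrix`.
#' @param total_length_bp Total callable length per chromosome (defaults to
#'   the matrix's `locus_length_bp`).
#' @param window_bp Window size for the SD computation (default 100 kb).
#' @return A tibble with one row per population: `lineage`, `n_samples`,
#'   `n_snps`, `pi`, `pi_sd`, `thetaw`, `thetaw_sd`.
#' @export
diversity_summary <- function(g, total_length_bp = NULL,
                              window_bp = 1e5) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(total_length_bp)) total_length_bp <- g$locus_length_bp
  pops <- unique(unname(g$popmap))
  n_chrom <- length(unique(g$chrom))
  L_total <- total_length_bp * n_chrom
  purrr::map_dfr(pops, function(p) {
    G <- subset_pop(g, p)
    n_hap <- 2L * nrow(G)
    ac <- colSums(G, na.rm = TRUE)
    nn <- 2 * colSums(!is.na(G))
    seg <- ac > 0 & ac < nn
    win_id <- paste0(g$chrom, "_", g$pos %/% window_bp)
    win_stats <- purrr::map_dfr(unique(win_id), function(w) {
      s <- which(win_id == w)
      Lw <- min(window_bp, total_length_bp)
      nw <- nn[s]; pw <- ac[s] / nw
      use <- nw >= 2
      pi_w <- sum((nw[use] / (nw[use] - 1)) * 2 * pw[use] * (1 - pw[use])) / Lw
      th_w <- if (n_hap >= 2) sum(seg[s]) / (sum(1 / seq_len(n_hap - 1)) * Lw)
              else NA_real_
      tibble(pi = pi_w, thetaw = th_w)
    })
    tibble(
      lineage = p,
      n_samples = nrow(G),
      n_snps = sum(seg),
      pi = nucleotide_diversity(g, p, L_total),
      pi_sd = sd(win_stats$pi),
      thetaw = watterson_theta(sum(seg), n_hap, L_total),
      thetaw_sd = sd(win_stats$thetaw)
    )
  })
}
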