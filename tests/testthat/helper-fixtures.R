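# in-code fixtures shared across test files

# genotype matrix from an explicit haploid 0/1 matrix (rows = haploids,
# consecutive rows pair into diploids), one chromosome
gm_from_haploids <- function(H, pops = NULL, locus_length_bp = 1e4,
                             pos = NULL) {
  n_hap <- nrow(H)
  stopifnot(n_hap %% 2 == 0)
  G <- H[seq(1, n_hap, 2), , drop = FALSE] + H[seq(2, n_hap, 2), , drop = FALSE]
  n <- nrow(G)
  ids <- paste0("s", seq_len(n))
  rownames(G) <- ids
  if (is.null(pops)) pops <- rep("all", n)
  if (is.null(pos)) pos <- seq_len(ncol(G)) * 10L
  genotype_matrix(G, chrom = rep("chr1", ncol(G)), pos = pos,
                  popmap = stats::setNames(pops, ids),
                  locus_length_bp = locus_length_bp)
}

# genotype matrix straight from diploid calls
gm_from_diploids <- function(G, pops = NULL, locus_length_bp = 1e4,
                             pos = NULL, chrom = NULL) {
  n <- nrow(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  rownames(G) <- ids
  if (is.null(pops)) pops <- rep("all", n)
  if (is.null(pos)) pos <- seq_len(ncol(G)) * 10L
  if (is.null(chrom)) chrom <- rep("chr1", ncol(G))
  genotype_matrix(G, chrom = chrom, pos = pos,
                  popmap = stats::setNames(pops, ids),
                  locus_length_bp = locus_length_bp)
}

# two deeply diverged demes: fixed-difference blocks plus private noise,
# deterministic under seed
gm_two_demes <- function(n_per = 5, n_fixed = 40, n_noise = 40, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  fixed <- rbind(matrix(0L, n_per, n_fixed), matrix(2L, n_per, n_fixed))
  noise <- matrix(rbinom(n * n_noise, 2, 0.2), n, n_noise)
  G <- cbind(fixed, noise)
  gm_from_diploids(G, pops = rep(c("P1", "P2"), each = n_per))
}
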