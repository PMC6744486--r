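#' Simulate a genealogy under the structured coalescent
#'
#' Draws one genealogy of the sampled lineages under the model: within a deme
#' of diploid size N each lineage pair coalesces at rate 1/(2N) per
#' generation; at a split time the child deme's lineages move to the parent;
#' at a pulse time each recipient lineage independently chooses a source with
#' the stated fractions. Branch lengths are in generations.
#'
#' @param model A [demographic_model()].
#' @param samples A [sample_config()].
#' @param seed Integer seed; the same seed reproduces the same genealogy.
#' @return An [ape::phylo] tree with tip labels `<deme>_<i>` (haploid
#'   lineages, deme-major order) and attributes `tmrca` (generations) and
#'   `tip_deme`.
#' @examples
#' m <- demographic_model(deme_sizes = c(A = 1000))
#' tr <- simulate_genealogy(m, sample_config(A = 3), seed = 1)
#' @export
simulate_genealogy <- function(model, samples, seed) {
  cm <- compile_model(model, samples)
  if (sum(cm$samples) < 2)
    stop("at least 2 lineages required", call. = FALSE)
  res <- cpp_sim_genealogy(cm$sizes, cm$events, cm$samples, as.double(seed))
  n <- sum(cm$samples)
  tip_deme <- rep(cm$tip_demes, times = cm$samples)
  tip_label <- paste0(tip_deme, "_",
                      unlist(lapply(cm$samples, seq_len)))
  # C++ node ids: leaves 0..n-1, internal n..2n-2 in coalescence order;
  # ape wants tips 1..n, root n+1, then internals.
  n_int <- n - 1L
  map <- integer(2L * n - 1L)
  map[1:n] <- 1:n
  # internal C++ ids n..2n-2; root is the last created (id 2n-2) -> n+1
  internal_ids <- (n + 1L):(2L * n - 1L)   # 1-based C++ ids + 1
  # reverse order so the last-created (root) becomes n+1
  map[internal_ids] <- n + rev(seq_len(n_int))
  edge <- cbind(map[res$parent + 1L], map[res$child + 1L])
  phy <- structure(list(edge = edge, edge.length = res$length,
                        tip.label = tip_label, Nnode = n_int),
                   class = "phylo")
  attr(phy, "tmrca") <- res$tmrca
  attr(phy, "tip_deme") <- tip_deme
  phy
}

#' Monte-Carlo expected site frequency spectrum
#'
#' Estimates the expected (joint) SFS from simulated genealogies: every
#' branch contributes its length (in generations) to the cell indexed by its
#' number of descendant leaves in each deme. Entries are normalized to sum to
#' 1 over polymorphic cells; folding merges complementary cells.
#'
#' @param model A [demographic_model()].
#' @param samples A [sample_config()].
#' @param n_replicates Number of independent genealogies to average over.
#' @param folded Fold the spectrum onto minor-allele counts?
#' @param seed Integer seed.
#' @param normalize Normalize over polymorphic cells (default `TRUE`)?
#' @return A [sfs_spectrum()] with one dimension per sampled deme.
#' @examples
#' m <- demographic_model(deme_sizes = c(A = 1000))
#' s <- simulate_sfs(m, sample_config(A = 2), n_replicates = 200, seed = 1)
#' @export
simulate_sfs <- function(model, samples, n_replicates, folded = FALSE,
                         seed, normalize = TRUE) {
  stopifnot(n_replicates >= 1)
  cm <- compile_model(model, samples)
  res <- cpp_sim_sfs(cm$sizes, cm$events, cm$samples,
                     as.integer(n_replicates), as.double(seed))
  v <- array(res$sfs, dim = cm$samples + 1L)
  sfs <- sfs_spectrum(v, demes = cm$tip_demes, n_hap = cm$samples)
  if (folded) sfs <- fold_sfs(sfs)
  if (normalize) sfs <- normalize_sfs(sfs)
  attr(sfs, "n_replicates") <- n_replicates
  attr(sfs, "seed") <- seed
  sfs
}

#' Simulate a genotype matrix under the model
#'
#' Draws `n_loci` independent, non-recombining loci: a genealogy per locus,
#' mutations as a Poisson process at the per-generation rate times total
#' branch length, infinite-sites placement at distinct uniform positions, and
#' diploid genotypes formed by pairing consecutive haploid lineages within
#' each deme. Optionally injects a selective-sweep signature into a named
#' interval: each non-escaping site's derived count is redrawn from
#' `{n - 1, n}` (count `n` is monomorphic and dropped, depleting diversity),
#' while an `escape_frac` fraction of sites keeps its background frequency.
#'
#' @param model A [demographic_model()].
#' @param samples A [sample_config()].
#' @param n_loci Number of independent loci (chromosomes in the output).
#' @param locus_length_bp Length of each locus in bp.
#' @param seed Integer seed.
#' @param sweep_injection Optional `list(chrom=, start=, end=,
#'   escape_frac=)` (0-based half-open interval on the named locus).
#' @return A `genotype_matrix`: diploid genotypes (0/1/2, NA for missing) of
#'   dimension individuals x sites, with per-site chromosome and 1-based
#'   position, sample ids and a population map.
#' @examples
#' m <- demographic_model(deme_sizes = c(A = 1000))
#' g <- simulate_genotypes(m, sample_config(A = 4), n_loci = 3,
#'                         locus_length_bp = 1e4, seed = 1)
#' @export
simulate_genotypes <- function(model, samples, n_loci, locus_length_bp,
                               seed, sweep_injection = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  cm <- compile_model(model, samples)
  n_hap <- sum(cm$samples)
  if (n_hap < 2) stop("no samples", call. = FALSE)
  mu_gen <- mu_per_generation(model)
  loci <- cpp_sim_loci(cm$sizes, cm$events, cm$samples,
                       as.integer(n_loci), as.double(locus_length_bp),
                       as.double(mu_gen), as.double(seed))
  set.seed(seed %% .Machine$integer.max)
  deme_of_hap <- rep(cm$tip_demes, times = cm$samples)
  n_dip <- n_hap %/% 2L
  # pair consecutive haploids; with per-deme even counts pairs stay in-deme
  sample_ids <- character(n_dip)
  popmap <- character(n_dip)
  for (i in seq_len(n_dip)) {
    popmap[i] <- deme_of_hap[2L * i - 1L]
  }
  counts <- table(factor(popmap, levels = unique(popmap)))
  sample_ids <- unlist(lapply(names(counts), function(d)
    paste0(d, "_", seq_len(counts[[d]]))))
  geno_cols <- list()
  chrom <- character(0)
  pos <- integer(0)
  for (l in seq_len(n_loci)) {
    H <- loci[[l]]
    n_sites <- ncol(H)
    if (n_sites == 0) next
    positions <- sort(sample.int(locus_length_bp, min(n_sites, locus_length_bp)))
    if (length(positions) < n_sites) {
      keep <- seq_along(positions)
      H <- H[, keep, drop = FALSE]
      n_sites <- length(positions)
    }
    G <- H[seq(1, n_hap, by = 2), , drop = FALSE] +
      H[seq(2, n_hap, by = 2), , drop = FALSE]
    this_chrom <- paste0("locus_", l)
    if (!is.null(sweep_injection) && sweep_injection$chrom == this_chrom) {
      inj <- inject_sweep(G, positions, n_hap, sweep_injection)
      G <- inj$G; positions <- inj$positions
    }
    # drop monomorphic columns (fixed by injection or by chance)
    ac <- colSums(G)
    poly <- ac > 0 & ac < n_hap
    G <- G[, poly, drop = FALSE]
    positions <- positions[poly]
    if (!length(positions)) next
    geno_cols[[length(geno_cols) + 1L]] <- G
    chrom <- c(chrom, rep(this_chrom, length(positions)))
    pos <- c(pos, positions)
  }
  G <- if (length(geno_cols)) do.call(cbind, geno_cols)
       else matrix(integer(0), nrow = n_dip, ncol = 0)
  rownames(G) <- sample_ids
  genotype_matrix(G, chrom = chrom, pos = pos,
                  popmap = setNames(popmap, sample_ids),
                  locus_length_bp = locus_length_bp,
                  seed = seed)
}

# redraw derived counts inside the swept interval from a completed-sweep
# spectrum: each of the n lineages escapes the sweep with probability
# rising from escape_frac at the interval centre toward 1 at the edges
# (the recombination-during-sweep gradient); escapees carry an allele count
# projected from the neutral spectrum, non-escapees all carry the swept
# (derived) allele. At the centre this reduces to counts in {n-1, n}
# (count n is monomorphic and later dropped, thinning diversity); toward
# the edges the spectrum grades into the background.
inject_sweep <- function(G, positions, n_hap, inj) {
  escape <- if (!is.null(inj$escape_frac)) inj$escape_frac else 0.1
  centre <- (inj$start + inj$end) / 2
  halfwidth <- (inj$end - inj$start) / 2
  inside <- positions > inj$start & positions <= inj$end
  if (!any(inside)) return(list(G = G, positions = positions))
  n <- n_hap
  # symmetric-unfolded neutral spectrum and its projections to k lineages
  i <- seq_len(n - 1)
  p_neutral <- numeric(n + 1)
  p_neutral[i + 1] <- (1 / i + 1 / (n - i)) / 2
  p_neutral <- p_neutral / sum(p_neutral)
  proj <- lapply(0:n, function(k) project_spectrum(p_neutral, n, k))
  for (s in which(inside)) {
    d <- abs(positions[s] - centre)
    pe <- 1 - (1 - escape) * exp(-2 * d / halfwidth)
    k <- rbinom(1, n, pe)
    jp <- sample.int(k + 1L, 1, prob = proj[[k + 1]]) - 1L
    count <- jp + (n - k)
    hap <- integer(n)
    if (count > 0) hap[sample.int(n, count)] <- 1L
    G[, s] <- hap[seq(1, n, by = 2)] + hap[seq(2, n, by = 2)]
  }
  list(G = G, positions = positions)
}

#' Genotype matrix container
#'
#' @param G Integer matrix, individuals x sites, values 0/1/2 or NA.
#' @param chrom Character chromosome label per site.
#' @param pos Integer 1-based position per site (strictly increasing within
#'   a chromosome).
#' @param popmap Named character vector mapping sample id to population.
#' @param locus_length_bp Sequence length per chromosome (scalar or named).
#' @param seed Optional seed recorded for provenance.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, chrom, pos, popmap,
                            locus_length_bp = NA_real_, seed = NULL) {
  G <- as.matrix(G)
  if (ncol(G) != length(pos) || length(chrom) != length(pos))
    stop("chrom/pos must have one entry per site", call. = FALSE)
  ok <- G %in% c(0L, 1L, 2L) | is.na(G)
  if (!all(ok))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  if (ncol(G) > 0) {
    any_called <- colSums(!is.na(G)) > 0
    if (!all(any_called))
      stop("every retained site needs at least one non-missing call",
           call. = FALSE)
  }
  if (is.null(rownames(G))) rownames(G) <- paste0("sample_", seq_len(nrow(G)))
  if (!all(rownames(G) %in% names(popmap)))
    stop("popmap must cover all samples", call. = FALSE)
  structure(list(G = G, chrom = as.character(chrom), pos = as.integer(pos),
                 samples = rownames(G),
                 popmap = popmap[rownames(G)],
                 locus_length_bp = locus_length_bp,
                 seed = seed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x$G), "samples x", ncol(x$G), "sites on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$popmap)),
                                      table(x$popmap)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    chrom = rep(x$chrom, each = nrow(x$G)),
    pos = rep(x$pos, each = nrow(x$G)),
    sample = rep(x$samples, times = ncol(x$G)),
    population = rep(unname(x$popmap), times = ncol(x$G)),
    genotype = as.vector(x$G)
  )
}

# subset helper: samples of one or more populations
pop_rows <- function(g, pops) {
  stopifnot(inherits(g, "genotype_matrix"))
  which(g$popmap %in% pops)
}
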