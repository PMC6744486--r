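#' Pairwise identity-by-state (IBS) distance matrix
#'
#' For each sample pair the distance is `sum_s |g_i - g_j| / (2 m)` over the
#' `m` sites where both genotypes are non-missing — the `1 - ibs` distance of
#' standard genotype tooling, equal to `1 - (IBS2 + 0.5 IBS1) / m`. Pairs
#' sharing no called site get `NA`.
#'
#' @param g A `genotype_matrix`.
#' @return An `ibs_dist` object: symmetric distance matrix in `[0, 1]` with
#'   zero diagonal, plus the per-pair count of sites used (`attr "n_sites"`).
#' @export
ibs_distance_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$G
  n <- nrow(G)
  if (!anyNA(G)) {
    D <- as.matrix(dist(G, method = "manhattan")) / (2 * ncol(G))
    M <- matrix(ncol(G), n, n)
  } else {
    D <- matrix(0, n, n)
    M <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      gi <- G[i, ]
      for (j in (i + 1):n) {
        ok <- !is.na(gi) & !is.na(G[j, ])
        m <- sum(ok)
        d <- if (m == 0) NA_real_ else sum(abs(gi[ok] - G[j, ok])) / (2 * m)
        D[i, j] <- D[j, i] <- d
        M[i, j] <- M[j, i] <- m
      }
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(g$samples, g$samples)
  structure(D, class = c("ibs_dist", "matrix"), n_sites = M)
}

#' Classify sample pairs by IBS distance
#'
#' Applies the dispersal-history bracket rule: near-identical pairs
#' (`IBS < 0.03`) reflect recent dispersal or introduction;
#' `0.03 <= IBS < 0.07` marks earlier introductions; `0.07 <= IBS <= 0.09`
#' is intermediate; `IBS > 0.09` marks deep between-lineage divergence.
#'
#' @param D An `ibs_dist` (or plain symmetric matrix with dimnames).
#' @param cutoffs Three strictly increasing cutoffs
#'   (default `c(0.03, 0.07, 0.09)`).
#' @return A tibble of unordered pairs: `sample_a`, `sample_b`, `ibs`,
#'   `category` (factor: `near_identical`, `early_introduction`,
#'   `intermediate`, `deep_divergence`).
#' @examples
#' classify_pairs(matrix(c(0, .02, .02, 0), 2, 2,
#'                dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
classify_pairs <- function(D, cutoffs = c(0.03, 0.07, 0.09)) {
  if (length(cutoffs) != 3 || any(diff(cutoffs) <= 0))
    stop("cutoffs must be three strictly increasing values", call. = FALSE)
  D <- as.matrix(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(D)))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ibs <- D[upper.tri(D)]
  category <- classify_ibs_values(ibs, cutoffs)
  tibble(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
         ibs = ibs, category = category)
}

classify_ibs_values <- function(ibs, cutoffs = c(0.03, 0.07, 0.09)) {
  lv <- c("near_identical", "early_introduction", "intermediate",
          "deep_divergence")
  out <- rep(NA_character_, length(ibs))
  out[ibs < cutoffs[1]] <- lv[1]
  out[ibs >= cutoffs[1] & ibs < cutoffs[2]] <- lv[2]
  out[ibs >= cutoffs[2] & ibs <= cutoffs[3]] <- lv[3]
  out[ibs > cutoffs[3]] <- lv[4]
  factor(out, levels = lv)
}

#' @export
tidy.ibs_dist <- function(x, ...) classify_pairs(x, ...)

#' Plot the distribution of pairwise IBS distances
#'
#' Histogram of the upper-triangle IBS distances with the classification
#' cutoffs drawn as dashed verticals — the display used to read off
#' near-identical, introduced and deeply diverged pairs.
#'
#' @param object An `ibs_dist`.
#' @param cutoffs Classification cutoffs to draw.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibs_dist <- function(object, cutoffs = c(0.03, 0.07, 0.09),
                              bins = 60, ...) {
  df <- tibble(ibs = as.matrix(object)[upper.tri(object)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ibs)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoffs, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "pairwise IBS distance (1 - ibs)", y = "pairs")
}

#' Write a square distance matrix with id header row and column
#' @param D Matrix (e.g. an `ibs_dist`).
#' @param path Output TSV path.
#' @param comment Optional provenance line (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(D, path, comment = NULL) {
  D <- as.matrix(D)
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("id", rownames(D)), collapse = "\t"), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i],
                       format(D[i, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
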