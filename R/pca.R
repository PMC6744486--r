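#' PCA of the variance-standardized genotype relationship matrix
#'
#' Each polymorphic site is standardized as `(g - 2p) / sqrt(2p(1-p))`
#' (missing entries imputed to the site mean, i.e. 0 after centering), the
#' sample-by-sample relationship matrix `XX'/M` is formed over the `M` used
#' sites, and its leading eigenvectors are extracted. Percent variance
#' explained is `eigenvalue / trace * 100`.
#'
#' @param g A `genotype_matrix`.
#' @param n_components Number of leading components to return (default 10).
#' @return A `pca_result`: `vectors` (samples x components), `values`
#'   (eigenvalues), `pct_var` (percent variance per component),
#'   `n_sites_used`, `populations`.
#' @export
pca <- function(g, n_components = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$G
  if (nrow(G) < 2) stop("PCA needs >= 2 samples", call. = FALSE)
  n_called <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_called)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic", call. = FALSE)
  X <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(X, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  M <- ncol(X)
  R <- tcrossprod(X) / M
  eig <- eigen(R, symmetric = TRUE)
  k <- min(n_components, nrow(G))
  vectors <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(vectors) <- g$samples
  colnames(vectors) <- paste0("PC", seq_len(k))
  structure(
    list(vectors = vectors,
         values = eig$values[seq_len(k)],
         pct_var = 100 * eig$values[seq_len(k)] / sum(diag(R)),
         n_sites_used = M,
         populations = unname(g$popmap)),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$vectors), "samples,", length(x$values),
      "components over", x$n_sites_used, "sites\n")
  cat("  pct variance:", paste(sprintf("%.2f", head(x$pct_var, 5)),
                               collapse = ", "), "...\n")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$vectors))
  out <- dplyr::bind_cols(
    tibble(sample = rownames(x$vectors), population = x$populations), out)
  out
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_samples = nrow(x$vectors),
         n_sites = x$n_sites_used,
         pc1_pct = x$pct_var[1],
         pc2_pct = if (length(x$pct_var) > 1) x$pct_var[2] else NA_real_)
}

#' Scatter plot of the leading principal components
#' @param object A `pca_result`.
#' @param pcs Which two components to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot object, points coloured by population.
#' @export
autoplot.pca_result <- function(object, pcs = c(1, 2), ...) {
  df <- tidy(object)
  xn <- paste0("PC", pcs[1]); yn <- paste0("PC", pcs[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xn]], y = .data[[yn]],
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.2f%%)", xn, object$pct_var[pcs[1]]),
      y = sprintf("%s (%.2f%%)", yn, object$pct_var[pcs[2]]))
}

#' Write eigenvectors and eigenvalues in PLINK-style TSVs
#' @param x A `pca_result`.
#' @param prefix Output path prefix; writes `<prefix>.eigenvec` and
#'   `<prefix>.eigenval`.
#' @return The two paths, invisibly.
#' @export
write_pca <- function(x, prefix) {
  stopifnot(inherits(x, "pca_result"))
  vec_path <- paste0(prefix, ".eigenvec")
  val_path <- paste0(prefix, ".eigenval")
  df <- data.frame(sample = rownames(x$vectors), x$vectors,
                   check.names = FALSE)
  write.table(df, vec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(x$values, digits = 10), val_path)
  invisible(c(vec_path, val_path))
}
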