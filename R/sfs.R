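#' Site frequency spectra
#'
#' A `sfs_spectrum` holds the (possibly joint) allele-count spectrum over one
#' or more demes: an array with one dimension per deme, dimension `d` indexed
#' by derived/alternate allele count `0..n_d` (so extent `n_d + 1`). Entries
#' are counts, branch-length weights, or probabilities; the two monomorphic
#' corner cells (all-zero and all-n) are masked whenever the spectrum is
#' normalized, following the SNP-data convention of SFS-based demographic
#' inference.
#'
#' @param values Numeric array (or vector for one deme) of cell weights.
#' @param demes Character vector of deme labels, one per dimension.
#' @param n_hap Integer haploid sample sizes per deme (`dim(values) - 1`).
#' @param folded Logical: is the spectrum folded onto minor-allele counts?
#' @param normalized Logical: do polymorphic cells sum to 1?
#' @return An object of class `sfs_spectrum`.
#' @export
sfs_spectrum <- function(values, demes, n_hap, folded = FALSE,
                         normalized = FALSE) {
  values <- as.array(values)
  if (length(dim(values)) != length(demes))
    stop("one array dimension per deme required", call. = FALSE)
  if (!all(dim(values) == n_hap + 1L))
    stop("dim(values) must equal n_hap + 1", call. = FALSE)
  if (any(values < 0)) stop("SFS entries must be non-negative", call. = FALSE)
  structure(list(values = values, demes = demes,
                 n_hap = as.integer(n_hap), folded = folded,
                 normalized = normalized),
            class = "sfs_spectrum")
}

# logical mask of monomorphic corner cells (total count 0 or total count n)
monomorphic_mask <- function(sfs) {
  tot <- total_count_array(sfs$n_hap)
  tot == 0 | tot == sum(sfs$n_hap)
}

# array of total derived counts per cell
total_count_array <- function(n_hap) {
  dims <- n_hap + 1L
  tot <- array(0, dim = dims)
  idx <- arrayInd(seq_along(tot), dims)
  array(rowSums(idx - 1L), dim = dims)
}

#' Normalize an SFS over its polymorphic cells
#' @param sfs A `sfs_spectrum`.
#' @return The spectrum with monomorphic corners zeroed and polymorphic
#'   entries summing to 1.
#' @export
normalize_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  v <- sfs$values
  v[monomorphic_mask(sfs)] <- 0
  s <- sum(v)
  if (s <= 0) stop("no polymorphic mass to normalize", call. = FALSE)
  sfs$values <- v / s
  sfs$normalized <- TRUE
  sfs
}

#' Fold an SFS onto minor-allele counts
#'
#' Each cell is merged with its complementary cell (per-deme counts
#' `n_d - c_d`); mass lands on the cell whose total count is below half the
#' total sample size, and cells exactly on the hinge keep half of the merged
#' mass so the overall sum is preserved.
#'
#' @param sfs A `sfs_spectrum`.
#' @return The folded spectrum.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  if (sfs$folded) return(sfs)
  v <- sfs$values
  dims <- dim(v)
  rev_v <- v
  # complement: reverse every dimension
  idx <- lapply(dims, function(d) d:1)
  rev_v <- do.call(`[`, c(list(v), idx))
  tot <- total_count_array(sfs$n_hap)
  half <- sum(sfs$n_hap) / 2
  folded <- v + rev_v
  folded[tot > half] <- 0
  folded[tot == half] <- folded[tot == half] / 2
  sfs$values <- folded
  sfs$folded <- TRUE
  sfs
}

#' Marginalize a joint SFS onto a subset of demes
#'
#' Sums cell mass over the dropped dimensions, giving the marginal
#' (lower-dimensional) spectrum of the retained demes. Marginalizing an
#' unfolded joint spectrum commutes with site counting; fold afterwards if a
#' minor-allele spectrum over the retained demes is wanted.
#'
#' @param sfs A `sfs_spectrum` (unfolded recommended).
#' @param demes Deme labels (or integer indices) to retain, in order.
#' @return The marginal `sfs_spectrum`.
#' @export
sfs_marginal <- function(sfs, demes) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  idx <- if (is.character(demes)) match(demes, sfs$demes) else as.integer(demes)
  if (anyNA(idx) || !length(idx)) stop("unknown deme in marginal",
                                       call. = FALSE)
  v <- apply(x_array(sfs), idx, sum)
  sfs_spectrum(v, demes = sfs$demes[idx], n_hap = sfs$n_hap[idx],
               folded = sfs$folded)
}

# fold + mask monomorphic + normalize a marginal; used by the pairwise-2D
# composite likelihood
prep_pair_spectrum <- function(sfs, fold = TRUE, floor_val = NULL) {
  if (fold && !sfs$folded) sfs <- fold_sfs(sfs)
  v <- sfs$values
  mask <- monomorphic_mask(sfs)
  if (sfs$folded) {
    tot <- total_count_array(sfs$n_hap)
    mask <- mask | tot > sum(sfs$n_hap) / 2
  }
  v[mask] <- 0
  if (!is.null(floor_val)) v[!mask & v <= 0] <- floor_val
  s <- sum(v)
  if (s <= 0) stop("no polymorphic mass in pair spectrum", call. = FALSE)
  sfs$values <- v / s
  sfs$normalized <- TRUE
  sfs
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat("<sfs_spectrum> demes:", paste(x$demes, collapse = ", "),
      "| n_hap:", paste(x$n_hap, collapse = ", "),
      "|", if (x$folded) "folded" else "unfolded",
      "|", if (x$normalized) "normalized" else "raw", "\n")
  cat("  total mass:", format(sum(x$values)), "over",
      length(x$values), "cells\n")
  invisible(x)
}

#' @export
tidy.sfs_spectrum <- function(x, ...) {
  dims <- dim(x$values)
  idx <- arrayInd(seq_along(x$values), dims) - 1L
  colnames(idx) <- x$demes
  out <- as_tibble(as.data.frame(idx))
  out$value <- as.vector(x$values)
  out[out$value != 0, , drop = FALSE]
}

#' Write an SFS in the flat-text exchange format
#'
#' One comment line recording provenance, a header line with the per-deme
#' haploid sample sizes, then the cell values in row-major (last deme fastest)
#' order, whitespace-separated — the layout used by dadi- and
#' fastsimcoal-style tooling.
#'
#' @param sfs A `sfs_spectrum`.
#' @param path Output file path.
#' @param comment Optional provenance string placed on the first line.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path, comment = NULL) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ginkgopop sfs | demes=",
                    paste(sfs$demes, collapse = ","),
                    " | folded=", sfs$folded,
                    if (!is.null(comment)) paste0(" | ", comment)), con)
  writeLines(paste(sfs$n_hap, collapse = " "), con)
  v <- aperm(x_array(sfs), rev(seq_along(dim(sfs$values))))
  writeLines(paste(format(as.vector(v), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   collapse = " "), con)
  invisible(path)
}

x_array <- function(sfs) {
  v <- sfs$values
  if (is.null(dim(v))) dim(v) <- length(v)
  v
}

#' Read an SFS from the flat-text exchange format
#' @param path File written by [write_sfs()].
#' @param demes Optional deme labels; parsed from the comment line if absent.
#' @param folded Optional folded flag; parsed from the comment line if absent.
#' @return A `sfs_spectrum`.
#' @export
read_sfs <- function(path, demes = NULL, folded = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  meta <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(lines) < 2) stop("malformed SFS file", call. = FALSE)
  n_hap <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  vals <- as.numeric(strsplit(trimws(paste(lines[-1], collapse = " ")),
                              "\\s+")[[1]])
  if (length(vals) != prod(n_hap + 1L))
    stop("SFS cell count does not match sample sizes", call. = FALSE)
  if (is.null(demes) && length(meta)) {
    m <- regmatches(meta[1], regexec("demes=([^ |]+)", meta[1]))[[1]]
    if (length(m) == 2) demes <- strsplit(m[2], ",")[[1]]
  }
  if (is.null(demes)) demes <- paste0("deme", seq_along(n_hap))
  if (is.null(folded) && length(meta))
    folded <- grepl("folded=TRUE", meta[1])
  if (is.null(folded)) folded <- FALSE
  v <- array(vals, dim = rev(n_hap + 1L))
  v <- aperm(v, rev(seq_along(n_hap)))
  sfs_spectrum(v, demes = demes, n_hap = n_hap, folded = folded,
               normalized = abs(sum(v) - 1) < 1e-6)
}
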