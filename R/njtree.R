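#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining on a symmetric, non-negative distance matrix
#' (typically IBS distances). Rows are put into lexicographic label order
#' before joining so ties resolve deterministically; negative branch lengths
#' are permitted (a known NJ artefact) and flagged via an attribute.
#'
#' @param D An `ibs_dist` or plain symmetric matrix with dimnames.
#' @return An [ape::phylo] unrooted tree; attribute
#'   `has_negative_branches` records whether any estimated branch length is
#'   negative.
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- nj_tree(D)
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("NJ needs >= 3 samples", call. = FALSE)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("sample_", seq_len(nrow(D))),
                        paste0("sample_", seq_len(nrow(D))))
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (anyNA(D)) stop("distance matrix contains NA", call. = FALSE)
  if (any(D < 0)) stop("distance matrix has negative entries", call. = FALSE)
  ord <- order(rownames(D))
  D <- D[ord, ord]
  phy <- ape::nj(as.dist(D))
  attr(phy, "has_negative_branches") <- any(phy$edge.length < 0)
  phy
}

#' Write a tree in newick format
#' @param phy An [ape::phylo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}
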