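#' Write a genotype matrix as minimal VCF 4.2
#'
#' Emits a `##fileformat=VCFv4.2` header, `##contig` lines, the producing
#' seed when recorded, and one biallelic SNP record per site with
#' placeholder `A`/`T` alleles and unphased `GT` calls (`./.` for missing).
#' Output is byte-stable for identical input.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=ginkgopop", con)
  if (!is.null(g$seed)) writeLines(paste0("##ginkgopop_seed=", g$seed), con)
  for (ch in unique(g$chrom))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(g$locus_length_bp)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (s in seq_along(g$pos)) {
    calls <- g$G[, s]
    gt <- ifelse(is.na(calls), "./.", gt_codes[calls + 1L])
    writeLines(paste(c(g$chrom[s], g$pos[s], ".", "A", "T", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF 4.2 into a genotype matrix
#'
#' Parses biallelic SNP records with GT calls. Multi-allelic records are
#' rejected (`multiallelic = "error"`) or skipped with a count
#' (`multiallelic = "skip"`). Malformed headers or records raise an error
#' naming the offending line.
#'
#' @param path VCF path.
#' @param popmap Optional named character vector (sample -> population);
#'   defaults to a single population `"all"`.
#' @param multiallelic `"error"` or `"skip"`.
#' @return A `genotype_matrix`; attribute `n_multiallelic_skipped` counts
#'   skipped records.
#' @export
read_vcf <- function(path, popmap = NULL,
                     multiallelic = c("error", "skip")) {
  multiallelic <- match.arg(multiallelic)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##fileformat=VCFv4", lines[1]))
    stop("line 1: missing ##fileformat=VCFv4.x header", call. = FALSE)
  hdr_i <- grep("^#CHROM\t", lines)
  if (!length(hdr_i))
    stop("no #CHROM header line found", call. = FALSE)
  hdr_i <- hdr_i[1]
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10)
    stop("line ", hdr_i, ": header has no sample columns", call. = FALSE)
  samples <- hdr[-(1:9)]
  rec_i <- which(seq_along(lines) > hdr_i & nzchar(lines))
  chrom <- character(0); pos <- integer(0)
  geno <- list()
  n_skipped <- 0L
  gt_map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L,
              "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  for (i in rec_i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("line ", i, ": expected ", length(hdr), " fields, got ",
           length(f), call. = FALSE)
    if (grepl(",", f[5], fixed = TRUE)) {
      if (multiallelic == "error")
        stop("line ", i, ": multi-allelic record", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p)) stop("line ", i, ": non-integer POS", call. = FALSE)
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("line ", i, ": no GT in FORMAT", call. = FALSE)
    calls <- vapply(f[-(1:9)], function(x)
      strsplit(x, ":", fixed = TRUE)[[1]][gti], "", USE.NAMES = FALSE)
    gvals <- gt_map[calls]
    if (any(is.na(gvals) & !calls %in% names(gt_map)))
      stop("line ", i, ": unparsable GT value", call. = FALSE)
    chrom <- c(chrom, f[1]); pos <- c(pos, p)
    geno[[length(geno) + 1L]] <- unname(gvals)
  }
  G <- if (length(geno)) do.call(cbind, geno)
       else matrix(integer(0), nrow = length(samples), ncol = 0)
  rownames(G) <- samples
  if (is.null(popmap)) popmap <- setNames(rep("all", length(samples)),
                                          samples)
  # contig length from header if present
  len <- NA_real_
  m <- regmatches(lines, regexec("^##contig=<ID=[^,]+,length=(\\d+)>",
                                 lines))
  lens <- vapply(m, function(x) if (length(x) == 2) as.numeric(x[2])
                 else NA_real_, 0)
  if (any(!is.na(lens))) len <- max(lens, na.rm = TRUE)
  out <- genotype_matrix(G, chrom = chrom, pos = pos, popmap = popmap,
                         locus_length_bp = len)
  attr(out, "n_multiallelic_skipped") <- n_skipped
  out
}

#' Read a sample-to-population map (TSV)
#'
#' Two tab-separated columns, `sample_id` and `population`; tolerant of
#' CRLF line endings and trailing whitespace. Duplicate sample ids are an
#' error.
#'
#' @param path TSV path.
#' @param vcf_samples Optional character vector of samples that must all be
#'   covered (strict mode).
#' @param strict If `TRUE` (default) uncovered `vcf_samples` raise an
#'   error; otherwise they are grouped as `"unassigned"`.
#' @return Named character vector: population keyed by sample id.
#' @export
read_popmap <- function(path, vcf_samples = NULL, strict = TRUE) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t|\\s{2,}")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop("popmap line ", bad[1], ": expected sample<TAB>population",
         call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1)
  pops <- vapply(parts, `[[`, "", 2)
  if (anyDuplicated(ids))
    stop("duplicate sample id in popmap: ",
         ids[duplicated(ids)][1], call. = FALSE)
  map <- setNames(pops, ids)
  if (!is.null(vcf_samples)) {
    missing <- setdiff(vcf_samples, ids)
    if (length(missing)) {
      if (strict)
        stop("samples missing from popmap: ",
             paste(missing, collapse = ", "), call. = FALSE)
      map <- c(map, setNames(rep("unassigned", length(missing)), missing))
    }
    map <- map[vcf_samples]
  }
  map
}

#' Write a population map TSV
#' @param popmap Named character vector (sample -> population).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  writeLines(paste(names(popmap), popmap, sep = "\t"), path)
  invisible(path)
}

#' Write a per-population diversity summary TSV
#' @param summary A tibble from [diversity_summary()].
#' @param path Output path.
#' @param comment Optional provenance line.
#' @return `path`, invisibly.
#' @export
write_diversity_summary <- function(summary, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(summary), collapse = "\t"), con)
  write.table(as.data.frame(summary), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
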