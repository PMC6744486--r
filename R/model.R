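#' Demographic models: population trees with dated splits and admixture pulses
#'
#' A `demographic_model` describes a set of demes (present-day lineages plus
#' any ancestral demes), a constant diploid effective size per deme, dated
#' splits (backwards in time, a child deme merges into its parent), and dated
#' admixture pulses (instantaneous founding of a recipient deme from one or
#' more source demes with stated fractions). Times are in years; they are
#' converted to generations with `generation_time_years` when simulating.
#'
#' @param deme_sizes Named numeric vector of diploid effective sizes, one per
#'   deme (tip and ancestral demes alike). All must be positive.
#' @param splits A list of split events, each `list(time_years=, child=,
#'   parent=)`: at `time_years` (backwards) the child deme's lineages join the
#'   parent deme.
#' @param admixture_pulses A list of pulse events, each `list(time_years=,
#'   recipient=, sources=)` where `sources` is a named numeric vector of
#'   fractions summing to 1: at `time_years` each recipient lineage
#'   independently traces to one source with those probabilities.
#' @param mu_per_site_per_year Mutation rate per site per year
#'   (default `0.67e-9`).
#' @param generation_time_years Generation time in years (default 20).
#' @param mu_is_per_generation If `TRUE`, interpret `mu_per_site_per_year`
#'   as a per-generation rate and skip the generation-time scaling.
#' @return An object of class `demographic_model`.
#' @examples
#' m <- demographic_model(
#'   deme_sizes = c(A = 1e4, B = 1e4, ANC = 2e4),
#'   splits = list(
#'     list(time_years = 1e5, child = "A", parent = "ANC"),
#'     list(time_years = 1e5, child = "B", parent = "ANC")
#'   )
#' )
#' @export
demographic_model <- function(deme_sizes,
                              splits = list(),
                              admixture_pulses = list(),
                              mu_per_site_per_year = 0.67e-9,
                              generation_time_years = 20,
                              mu_is_per_generation = FALSE) {
  if (is.null(names(deme_sizes)) || any(!nzchar(names(deme_sizes))))
    stop("`deme_sizes` must be a fully named vector", call. = FALSE)
  if (anyDuplicated(names(deme_sizes)))
    stop("duplicate deme labels", call. = FALSE)
  if (any(!is.finite(deme_sizes)) || any(deme_sizes <= 0))
    stop("all effective sizes must be positive and finite", call. = FALSE)
  if (generation_time_years <= 0)
    stop("generation time must be positive", call. = FALSE)
  model <- structure(
    list(
      demes = names(deme_sizes),
      deme_sizes = deme_sizes,
      splits = splits,
      admixture_pulses = admixture_pulses,
      mu_per_site_per_year = mu_per_site_per_year,
      generation_time_years = generation_time_years,
      mu_is_per_generation = mu_is_per_generation
    ),
    class = "demographic_model"
  )
  validate_model(model)
  model
}

validate_model <- function(model) {
  demes <- model$demes
  chk_deme <- function(d, what) {
    if (!d %in% demes)
      stop("unknown deme '", d, "' in ", what, call. = FALSE)
  }
  for (s in model$splits) {
    if (!all(c("time_years", "child", "parent") %in% names(s)))
      stop("split events need time_years, child, parent", call. = FALSE)
    if (s$time_years <= 0) stop("split times must be positive", call. = FALSE)
    chk_deme(s$child, "splits"); chk_deme(s$parent, "splits")
  }
  for (p in model$admixture_pulses) {
    if (!all(c("time_years", "recipient", "sources") %in% names(p)))
      stop("pulse events need time_years, recipient, sources", call. = FALSE)
    if (p$time_years <= 0) stop("pulse times must be positive", call. = FALSE)
    chk_deme(p$recipient, "pulses")
    for (src in names(p$sources)) chk_deme(src, "pulses")
    f <- p$sources
    if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
      stop("pulse source fractions must lie in [0,1] and sum to 1",
           call. = FALSE)
  }
  # a deme removed by a pulse must not later be the child of a split at an
  # earlier or equal time on the same lineage path
  for (p in model$admixture_pulses) {
    for (s in model$splits) {
      if (s$child == p$recipient && s$time_years <= p$time_years)
        stop("deme '", p$recipient,
             "' splits no later than the pulse founding it", call. = FALSE)
    }
  }
  invisible(model)
}

#' Convert years to generations under a model's generation time
#' @param model A `demographic_model`.
#' @param years Numeric vector of times in years.
#' @return Times in generations (`years / generation_time_years`, exact).
#' @export
t_generations <- function(model, years) years / model$generation_time_years

#' Per-generation mutation rate implied by a model
#' @param model A `demographic_model`.
#' @return Mutation rate per site per generation.
#' @export
mu_per_generation <- function(model) {
  if (isTRUE(model$mu_is_per_generation)) model$mu_per_site_per_year
  else model$mu_per_site_per_year * model$generation_time_years
}

#' The four-lineage ginkgo demographic model
#'
#' Builds the best-fit demography of the global ginkgo phylogeography:
#' four extant lineages (EAST, SOUTH, NORTH, SWEST), with the SWEST lineage
#' diverging from the EAST+SOUTH ancestor 515,780 years ago, the EAST/SOUTH
#' split 318,120 years ago, and the NORTH lineage founded 139,260 years ago
#' by an admixture pulse of 71.55% SOUTH and 28.45% SWEST ancestry. The most
#' recent common ancestral population has diploid effective size 50,514;
#' descendant lineages default to 28,456, the midpoint of the inferred
#' 24,819-32,093 range, and can be overridden individually.
#'
#' @param n_anc Ancestral (root) diploid effective size.
#' @param n_east,n_south,n_north,n_swest Descendant diploid effective sizes.
#' @param n_es Effective size of the intermediate EAST+SOUTH ancestor
#'   (not separately reported; defaults to the ancestral size).
#' @param t_split_swest Years before present of the SWEST vs EAST+SOUTH split.
#' @param t_split_east_south Years before present of the EAST vs SOUTH split.
#' @param t_pulse_north Years before present of the NORTH founding pulse.
#' @param f_north_south Fraction of NORTH ancestry drawn from SOUTH (the
#'   remainder comes from SWEST).
#' @param mu_per_site_per_year,generation_time_years,mu_is_per_generation
#'   Passed to [demographic_model()].
#' @return A `demographic_model` with demes EAST, SOUTH, NORTH, SWEST, ES
#'   (intermediate ancestor) and ANC (root).
#' @examples
#' m <- ginkgo_model()
#' m$admixture_pulses[[1]]$sources
#' @export
ginkgo_model <- function(n_anc = 50514,
                         n_east = 28456, n_south = 28456,
                         n_north = 28456, n_swest = 28456,
                         n_es = n_anc,
                         t_split_swest = 515780,
                         t_split_east_south = 318120,
                         t_pulse_north = 139260,
                         f_north_south = 0.7155,
                         mu_per_site_per_year = 0.67e-9,
                         generation_time_years = 20,
                         mu_is_per_generation = FALSE) {
  stopifnot(f_north_south >= 0, f_north_south <= 1)
  demographic_model(
    deme_sizes = c(EAST = n_east, SOUTH = n_south, NORTH = n_north,
                   SWEST = n_swest, ES = n_es, ANC = n_anc),
    splits = list(
      list(time_years = t_split_swest, child = "SWEST", parent = "ANC"),
      list(time_years = t_split_swest, child = "ES", parent = "ANC"),
      list(time_years = t_split_east_south, child = "EAST", parent = "ES"),
      list(time_years = t_split_east_south, child = "SOUTH", parent = "ES")
    ),
    admixture_pulses = list(
      list(time_years = t_pulse_north, recipient = "NORTH",
           sources = c(SOUTH = f_north_south, SWEST = 1 - f_north_south))
    ),
    mu_per_site_per_year = mu_per_site_per_year,
    generation_time_years = generation_time_years,
    mu_is_per_generation = mu_is_per_generation
  )
}

#' Sampling configuration
#'
#' @param ... Named integers: diploid individuals sampled per deme.
#' @return A `sample_config`: named diploid counts with derived haploid sizes.
#' @examples
#' sample_config(EAST = 10, SOUTH = 10)
#' @export
sample_config <- function(...) {
  counts <- c(...)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("sample counts must be named by deme", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("sample counts must be non-negative integers", call. = FALSE)
  if (sum(counts) * 2 < 2)
    stop("at least 2 haploid lineages must be sampled in total",
         call. = FALSE)
  structure(list(diploids = counts, haploids = 2L * as.integer(counts),
                 demes = names(counts)),
            class = "sample_config")
}

# Compile a model + sample config into the flat representation the C++
# engine consumes: sampled demes first (sample-config order), events sorted
# by time in generations; simultaneous events keep list order, splits before
# pulses at equal times (oldest-label-first is irrelevant once each move is
# an independent relabelling).
compile_model <- function(model, samples) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(samples, "sample_config"))
  missing <- setdiff(samples$demes, model$demes)
  if (length(missing))
    stop("sampled demes absent from model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tip <- samples$demes
  rest <- setdiff(model$demes, tip)
  order <- c(tip, rest)
  idx <- setNames(seq_along(order) - 1L, order)
  gt <- model$generation_time_years
  ev <- list()
  for (s in model$splits) {
    ev[[length(ev) + 1L]] <- list(time = s$time_years / gt, type = 0L,
                                  a = idx[[s$child]], b = idx[[s$parent]])
  }
  for (p in model$admixture_pulses) {
    ev[[length(ev) + 1L]] <- list(
      time = p$time_years / gt, type = 1L, a = idx[[p$recipient]],
      src = unname(idx[names(p$sources)]),
      frac = unname(p$sources))
  }
  if (length(ev)) {
    ord <- order(vapply(ev, `[[`, 0, "time"),
                 vapply(ev, `[[`, 0L, "type"))
    ev <- ev[ord]
  }
  list(sizes = unname(model$deme_sizes[order]),
       events = ev,
       samples = unname(samples$haploids),
       tip_demes = tip,
       deme_index = idx)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> with", length(x$demes), "demes:",
      paste(x$demes, collapse = ", "), "\n")
  for (d in x$demes) cat("  N_e[", d, "] = ", x$deme_sizes[[d]], "\n", sep = "")
  for (s in x$splits)
    cat("  split: ", s$child, " -> ", s$parent, " at ", s$time_years,
        " y\n", sep = "")
  for (p in x$admixture_pulses)
    cat("  pulse: ", p$recipient, " <- {",
        paste(sprintf("%s: %.4f", names(p$sources), p$sources),
              collapse = ", "), "} at ", p$time_years, " y\n", sep = "")
  cat("  mu = ", x$mu_per_site_per_year,
      if (x$mu_is_per_generation) " /site/generation" else " /site/year",
      ", generation time = ", x$generation_time_years, " y\n", sep = "")
  invisible(x)
}
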