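#' Model-based ancestry estimation (ADMIXTURE-style)
#'
#' Maximizes the binomial admixture log-likelihood
#' `sum_{i,s} [ g_is log(q_i . p_.s) + (2 - g_is) log(1 - q_i . p_.s) ]`
#' over ancestry fractions Q (samples x K, rows on the simplex) and
#' component allele frequencies P (K x sites) by block relaxation with
#' EM-style multiplicative updates from a seeded random start. The
#' log-likelihood is non-decreasing across iterations; iteration stops when
#' the gain falls below `tol` or `max_iter` is reached. A multi-restart
#' wrapper keeps the best of `n_restarts` replicates.
#'
#' @param g A `genotype_matrix` (missing genotypes are ignored in the
#'   likelihood).
#' @param K Number of ancestral components (1 <= K <= samples).
#' @param seed Integer seed for the random starts.
#' @param max_iter Maximum block-relaxation iterations per restart.
#' @param tol Stop when the log-likelihood gain drops below this.
#' @param n_restarts Independent seeded restarts; the best fit is kept.
#' @return An `ancestry_fit`: `Q`, `P`, `loglik`, `loglik_trace`,
#'   `n_iterations`, `converged`, `K`, `seed`, `restart_logliks`.
#' @export
admixture_fit <- function(g, K, seed = 1, max_iter = 300, tol = 1e-4,
                          n_restarts = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$G
  n <- nrow(G); S <- ncol(G)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K cannot exceed the number of samples", call. = FALSE)
  if (S < 1) stop("no sites", call. = FALSE)
  fits <- lapply(seq_len(n_restarts), function(r)
    admixture_fit_once(G, K, seed = seed + (r - 1) * 1000L,
                       max_iter = max_iter, tol = tol))
  logliks <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(logliks)]]
  best$restart_logliks <- logliks
  best$seed <- seed
  rownames(best$Q) <- g$samples
  attr(best, "populations") <- unname(g$popmap)
  structure(best, class = "ancestry_fit")
}

admixture_fit_once <- function(G, K, seed, max_iter, tol) {
  n <- nrow(G); S <- ncol(G)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0
  G2 <- 2 - G; G2[!obs] <- 0
  denom_i <- 2 * rowSums(obs)
  set.seed(seed %% .Machine$integer.max)
  eps <- 1e-6
  if (K == 1) {
    p <- colSums(G0) / pmax(2 * colSums(obs), 1)
    P <- matrix(pmin(pmax(p, eps), 1 - eps), nrow = 1)
    Q <- matrix(1, n, 1)
    ll <- admix_loglik(G0, G2, Q, P)
    return(list(Q = Q, P = P, loglik = ll, loglik_trace = ll,
                n_iterations = 0L, converged = TRUE, K = 1L))
  }
  Q <- matrix(runif(n * K, 0.1, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(runif(K * S, 0.05, 0.95), K, S)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- Q %*% P                       # expected allele frequency, n x S
    E <- pmin(pmax(E, eps), 1 - eps)
    A <- G0 / E                        # g / (qp)
    B <- G2 / (1 - E)                  # (2-g) / (1-qp)
    # Q update: q_ik <- q_ik * [ (A P' )_ik + (B (1-P)')_ik ] / (2 S_i)
    Qn <- Q * (A %*% t(P) + B %*% t(1 - P)) / denom_i
    Qn <- Qn / rowSums(Qn)
    # P update with the refreshed responsibilities under old P, new Q kept
    # separate: use classic simultaneous EM update from (Q, P)
    num <- t(Q) %*% A * P              # K x S
    den <- num + (t(Q) %*% B) * (1 - P)
    Pn <- num / pmax(den, .Machine$double.xmin)
    Q <- Qn
    P <- pmin(pmax(Pn, eps), 1 - eps)
    ll <- admix_loglik(G0, G2, Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- ll - ll_old >= -1e-8
      break
    }
    ll_old <- ll
  }
  list(Q = Q, P = P, loglik = trace[length(trace)], loglik_trace = trace,
       n_iterations = length(trace), converged = converged, K = as.integer(K))
}

admix_loglik <- function(G0, G2, Q, P) {
  eps <- 1e-12
  E <- pmin(pmax(Q %*% P, eps), 1 - eps)
  sum(G0 * log(E) + G2 * log(1 - E))
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("<ancestry_fit> K =", x$K, "|", nrow(x$Q), "samples | loglik =",
      format(x$loglik), "|", x$n_iterations, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @export
tidy.ancestry_fit <- function(x, ...) {
  Q <- x$Q
  out <- tibble(
    sample = rep(rownames(Q), times = ncol(Q)),
    population = rep(attr(x, "populations") %||% NA_character_,
                     times = ncol(Q)),
    component = rep(paste0("K", seq_len(ncol(Q))), each = nrow(Q)),
    fraction = as.vector(Q))
  out
}

#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, n_iterations = x$n_iterations,
         converged = x$converged,
         n_restarts = length(x$restart_logliks %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stacked ancestry bar plot
#' @param object An `ancestry_fit`.
#' @param ... Unused.
#' @return A ggplot object with one stacked bar per sample.
#' @export
autoplot.ancestry_fit <- function(object, ...) {
  df <- tidy(object)
  df$sample <- factor(df$sample, levels = rownames(object$Q)[
    order(attr(object, "populations"), -object$Q[, 1])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                   fill = .data$component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "ancestry fraction")
}

#' Cross-validation over K for ancestry estimation
#'
#' For each fold, a random `1/n_folds` share of the non-missing genotype
#' entries is masked, the model is refitted on the rest, and the masked
#' entries are scored by squared error between the observed genotype and its
#' expectation `2 (Q P)`. Returns the mean CV error per K.
#'
#' @param g A `genotype_matrix`.
#' @param K_range Integer vector of K values to evaluate.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param ... Passed to [admixture_fit()] (e.g. `max_iter`, `tol`).
#' @return A tibble: `K`, `cv_error` (mean over folds), `cv_se`.
#' @export
admixture_cv <- function(g, K_range, n_folds = 10, seed = 1, ...) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$G
  obs_idx <- which(!is.na(G))
  set.seed(seed %% .Machine$integer.max)
  fold_of <- sample(rep_len(seq_len(n_folds), length(obs_idx)))
  purrr::map_dfr(K_range, function(K) {
    errs <- vapply(seq_len(n_folds), function(f) {
      mask <- obs_idx[fold_of == f]
      Gtrain <- G
      Gtrain[mask] <- NA
      if (all(is.na(Gtrain)))
        stop("fold leaves an empty training set", call. = FALSE)
      gt <- g
      gt$G <- Gtrain
      fit <- admixture_fit(gt, K, seed = seed + K * 100 + f, ...)
      E <- 2 * (fit$Q %*% fit$P)
      mean((G[mask] - E[mask])^2)
    }, 0)
    tibble(K = K, cv_error = mean(errs), cv_se = sd(errs) / sqrt(n_folds))
  })
}

#' Write an ancestry Q matrix in whitespace-separated .Q style
#' @param x An `ancestry_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(x, path) {
  stopifnot(inherits(x, "ancestry_fit"))
  write.table(format(x$Q, digits = 6), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
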