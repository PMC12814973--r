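#' Edge-by-network indicator matrix for a cluster of SENs
#'
#' Rows enumerate the union edge set over the cluster; entry (e, m) is 1
#' when network m contains edge e. All-zero rows cannot occur (every row
#' edge comes from some network).
#'
#' @param sens list of [sen()] objects (>= 2).
#' @return binary matrix with edge keys as rownames and network names as
#'   colnames.
#' @export
build_edge_matrix <- function(sens) {
  if (length(sens) < 2) stop("need at least 2 networks")
  edges <- lapply(sens, sen_edges)
  universe <- sort(unique(unlist(edges)))
  nm <- vapply(seq_along(sens), function(i) {
    d <- sens[[i]]$descriptor
    if (!is.null(d)) paste0(d$tool, "_", d$mapping) else sprintf("sen%02d", i)
  }, "")
  m <- vapply(edges, function(e) as.integer(universe %in% e),
              integer(length(universe)))
  m <- matrix(m, nrow = length(universe),
              dimnames = list(universe, make.unique(nm)))
  m
}

#' Aggregate binary networks by union, intersection or majority vote
#'
#' Union keeps an edge present in any network; intersection requires all;
#' majority requires strictly more than half (exact ties excluded by
#' default, configurable via `majority_ties`). The nesting
#' intersection, majority, union always holds.
#'
#' @param m an edge indicator matrix from [build_edge_matrix()].
#' @param method `"union"`, `"intersection"` or `"majority"`.
#' @param majority_ties `"exclude"` (default, strict > M/2) or `"include"`
#'   (>= M/2).
#' @return a [sen()] on the union edge universe.
#' @export
aggregate_simple <- function(m, method = c("union", "intersection", "majority"),
                             majority_ties = c("exclude", "include")) {
  method <- match.arg(method)
  majority_ties <- match.arg(majority_ties)
  M <- ncol(m)
  votes <- rowSums(m)
  keep <- switch(method,
    union = votes >= 1,
    intersection = votes == M,
    majority = if (majority_ties == "exclude") votes > M / 2 else votes >= M / 2)
  keys <- rownames(m)[keep]
  prs <- split_pair_key(keys)
  all_nodes <- unique(unlist(split_pair_key(rownames(m))))
  sen(prs$a, prs$b, nodes = all_nodes)
}

#' Fit a latent class model to an edge indicator matrix by EM
#'
#' Finite mixture of independent Bernoulli products over the network
#' indicators: `P(row y) = sum_c pi_c prod_m theta_cm^y_m (1-theta_cm)^(1-y_m)`.
#' Fitted by expectation-maximization from `n_restarts` random starts; the
#' best final log-likelihood wins. Latent classes partition the candidate
#' edges into groups with shared reporting profiles across networks — in a
#' homogeneous cluster, typically a consistently-reported class and an
#' idiosyncratic class.
#'
#' @param m an edge indicator matrix from [build_edge_matrix()].
#' @param n_classes number of latent classes C (>= 1; default 2).
#' @param n_restarts random restarts (default 10).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed.
#' @return object of class `lca_model`: list with `pi` (class prevalences),
#'   `theta` (C x M reporting probabilities), `posterior` (rows x C),
#'   `loglik`, `loglik_trace` (best start), `bic`, `n_classes`, `converged`.
#' @export
lca_fit <- function(m, n_classes = 2, n_restarts = 10, tol = 1e-8,
                    max_iter = 5000, seed = 1L) {
  if (n_classes < 1) stop("n_classes must be >= 1")
  m <- as.matrix(m)
  if (nrow(unique(as.data.frame(m))) < n_classes)
    stop("fewer distinct row patterns than classes")
  N <- nrow(m); M <- ncol(m)
  if (n_classes == 1) {
    theta <- matrix(colMeans(m), 1, M, dimnames = list(NULL, colnames(m)))
    th <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    ll <- sum(m %*% t(log(th)) + (1 - m) %*% t(log(1 - th)))
    p <- (n_classes - 1) + n_classes * M
    return(structure(list(pi = 1, theta = theta,
                          posterior = matrix(1, N, 1), loglik = ll,
                          loglik_trace = ll, bic = -2 * ll + p * log(N),
                          n_classes = 1L, converged = TRUE),
                     class = "lca_model"))
  }
  set.seed(seed)
  em_once <- function() {
    pi_c <- as.numeric(stats::rbeta(n_classes, 2, 2))
    pi_c <- pi_c / sum(pi_c)
    theta <- matrix(stats::runif(n_classes * M, 0.2, 0.8), n_classes, M)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      th <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
      logp <- m %*% t(log(th)) + (1 - m) %*% t(log(1 - th))
      logp <- sweep(logp, 2, log(pi_c), `+`)
      mx <- apply(logp, 1, max)
      lse <- mx + log(rowSums(exp(logp - mx)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      post <- exp(logp - lse)
      if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      nk <- colSums(post)
      pi_c <- nk / N
      theta <- crossprod(post, m) / nk
      theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    }
    if (!converged)
      warning("EM did not converge in ", max_iter, " iterations")
    list(pi = pi_c, theta = theta, posterior = post, loglik = ll,
         trace = trace, converged = converged)
  }
  fits <- lapply(seq_len(n_restarts), function(i) em_once())
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  colnames(best$theta) <- colnames(m)
  p <- (n_classes - 1) + n_classes * M
  structure(list(pi = best$pi, theta = best$theta, posterior = best$posterior,
                 loglik = best$loglik, loglik_trace = best$trace,
                 bic = -2 * best$loglik + p * log(N),
                 n_classes = as.integer(n_classes),
                 converged = best$converged),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("lca_model: %d class(es), loglik %.3f, BIC %.3f\n",
              x$n_classes, x$loglik, x$bic))
  cat("pi:", round(x$pi, 3), "\n")
  invisible(x)
}

#' Link prediction: summary network from a fitted latent class model
#'
#' The "signal" class is the one with the largest mean reporting probability
#' across networks (ties broken toward the larger prevalence, with a
#' message); an edge enters the summary network when its posterior
#' probability of the signal class exceeds `cutoff`.
#'
#' @param model an [lca_fit()] result.
#' @param m the edge indicator matrix the model was fitted to.
#' @param cutoff posterior cutoff (default 0.5).
#' @return a [sen()].
#' @export
lca_summary_network <- function(model, m, cutoff = 0.5) {
  mean_theta <- rowMeans(model$theta)
  top <- which(mean_theta == max(mean_theta))
  if (length(top) > 1) {
    message("tied mean theta; breaking toward larger class prevalence")
    top <- top[which.max(model$pi[top])]
  }
  keep <- model$posterior[, top] > cutoff
  keys <- rownames(m)[keep]
  prs <- split_pair_key(keys)
  all_nodes <- unique(unlist(split_pair_key(rownames(m))))
  sen(prs$a, prs$b, nodes = all_nodes)
}

#' Choose the number of latent classes by BIC
#'
#' Fits C = 1..c_max and returns the BIC-minimizing C. Class counts whose
#' fit is infeasible (more classes than distinct row patterns) are skipped.
#'
#' @param m an edge indicator matrix.
#' @param c_max largest class count to try (>= 1).
#' @param ... passed to [lca_fit()].
#' @param seed integer seed.
#' @return list with `n_classes` (chosen C), `bic_table` (data.frame
#'   `n_classes`, `bic`, `loglik`) and `models` (the fitted models).
#' @export
select_n_classes <- function(m, c_max, seed = 1L, ...) {
  if (c_max < 1) stop("c_max must be >= 1")
  models <- list()
  rows <- list()
  for (C in seq_len(c_max)) {
    fit <- tryCatch(suppressWarnings(
      lca_fit(m, n_classes = C, seed = seed + C, ...)),
      error = function(e) NULL)
    if (is.null(fit)) next
    models[[as.character(C)]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(n_classes = C, bic = fit$bic,
                                            loglik = fit$loglik)
  }
  tab <- do.call(rbind, rows)
  list(n_classes = tab$n_classes[which.min(tab$bic)], bic_table = tab,
       models = models)
}
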