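#' Fit a latent class model to binary disease indicators
#'
#' Conditional-independence (local-independence) latent class analysis of an
#' `n x D` binary matrix, estimated by expectation-maximization. Class `k`
#' has mixing proportion `pi_k` and item-response probabilities `rho_kj`;
#' given class, diseases are independent Bernoulli. The best of `n_starts`
#' random initializations (item probabilities drawn by perturbing the
#' observed prevalences) is returned, with classes re-ordered by descending
#' `pi` so labels are stable across refits.
#'
#' @param Y binary matrix (participants x diseases); every column should have
#'   both 0s and 1s (enforce upstream with [eligible_diseases()]).
#' @param K number of latent classes (>= 1).
#' @param n_starts random restarts (ignored for `K = 1`, which is closed
#'   form).
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap per start.
#' @param seed integer seed for the restarts.
#' @param trace keep the per-iteration log-likelihood of the best start
#'   (useful for checking EM monotonicity).
#' @return Object of class `lca_model`: `K`, `pi`, `rho` (`K x D`, smoothed
#'   into `[1e-6, 1 - 1e-6]`), `loglik`, `n_params = K - 1 + K * D`, `n_obs`,
#'   `converged`, `n_iter`, and optionally `trace`.
#' @export
fit_lca <- function(Y, K, n_starts = 10, tol = 1e-8, max_iter = 5000,
                    seed = NULL, trace = FALSE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y); D <- ncol(Y)
  if (K < 1) stop("K must be at least 1")
  if (n <= K) stop("need more observations than classes")
  if (D < 2) stop("need at least 2 diseases")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  eps <- 1e-6

  if (K == 1L) {
    rho <- matrix(pmin(pmax(colMeans(Y), eps), 1 - eps), 1L, D,
                  dimnames = list(NULL, colnames(Y)))
    ll <- sum(Y %*% t(log(rho)) + (1 - Y) %*% t(log(1 - rho)))
    return(structure(list(K = 1L, pi = 1, rho = rho, loglik = ll,
                          n_params = D, n_obs = n, converged = TRUE,
                          n_iter = 0L,
                          trace = if (trace) ll else NULL),
                     class = "lca_model"))
  }

  if (!is.null(seed)) set.seed(seed)
  prev <- colMeans(Y)
  best <- NULL
  any_converged <- FALSE

  for (s in seq_len(n_starts)) {
    rho <- matrix(pmin(pmax(rep(prev, each = K) +
                              stats::runif(K * D, -0.2, 0.2), eps), 1 - eps), K, D)
    pi_k <- as.vector(stats::rexp(K) + 1); pi_k <- pi_k / sum(pi_k)
    ll_old <- -Inf
    tr <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      L <- sweep(Y %*% t(log(rho)) + (1 - Y) %*% t(log(1 - rho)),
                 2L, log(pi_k), "+")
      ls <- logsumexp_rows(L)
      ll <- sum(ls)
      if (trace) tr <- c(tr, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      post <- exp(L - ls)
      Nk <- colSums(post)
      pi_k <- Nk / n
      rho <- pmin(pmax((t(post) %*% Y) / Nk, eps), 1 - eps)
    }
    any_converged <- any_converged || converged
    if (is.null(best) || ll > best$loglik)
      best <- list(pi = pi_k, rho = rho, loglik = ll, converged = converged,
                   n_iter = it, trace = tr)
  }
  if (!any_converged)
    warning("no EM start converged within max_iter; returning best-likelihood model")

  ord <- order(best$pi, decreasing = TRUE)
  rho <- best$rho[ord, , drop = FALSE]
  colnames(rho) <- colnames(Y)
  structure(list(K = as.integer(K), pi = best$pi[ord], rho = rho,
                 loglik = best$loglik,
                 n_params = K - 1L + K * D, n_obs = n,
                 converged = best$converged, n_iter = best$n_iter,
                 trace = if (trace) best$trace else NULL),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat("latent class model: K =", x$K, "classes,", ncol(x$rho), "diseases,",
      x$n_obs, "observations\n")
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat(sprintf("  loglik %.2f (%s after %d EM iterations)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Bayes posterior `p_ik` proportional to
#' `pi_k prod_j rho_kj^y_ij (1 - rho_kj)^(1 - y_ij)`, rows normalized to the
#' simplex.
#'
#' @param model an `lca_model`.
#' @param Y binary matrix with the model's number of diseases.
#' @return `n x K` matrix; each row sums to 1.
#' @export
posterior_membership <- function(model, Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (ncol(Y) != ncol(model$rho))
    stop("Y has ", ncol(Y), " columns but the model has ", ncol(model$rho),
         " diseases")
  L <- sweep(Y %*% t(log(model$rho)) + (1 - Y) %*% t(log(1 - model$rho)),
             2L, log(model$pi), "+")
  exp(L - logsumexp_rows(L))
}

#' Sample-size-adjusted BIC of a latent class model
#'
#' `-2 loglik + n_params * log((n + 2) / 24)`, the adjusted BIC with Sclove's
#' `n* = (n + 2)/24` sample-size correction conventional in LCA class
#' enumeration.
#'
#' @param model an `lca_model`.
#' @export
abic <- function(model) {
  -2 * model$loglik + model$n_params * log((model$n_obs + 2) / 24)
}

#' Relative entropy of a posterior matrix
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`: 1 for perfectly separated
#' (degenerate) posteriors, 0 for uniform posteriors. Undefined at `K = 1`.
#'
#' @param post posterior matrix with rows on the simplex.
#' @export
relative_entropy <- function(post) {
  post <- as.matrix(post)
  K <- ncol(post)
  if (K < 2L) stop("relative entropy is undefined for K = 1")
  plogp <- post * log(post)
  plogp[post == 0] <- 0
  1 - sum(-plogp) / (nrow(post) * log(K))
}

#' Modal class assignment
#'
#' Assigns each row to its highest-posterior class. Exact ties are broken
#' toward the class with the larger mixing proportion (or lower index if
#' `pi` is not supplied) and reported via a message.
#'
#' @param post posterior matrix.
#' @param pi optional mixing proportions used for tie-breaking.
#' @return integer vector of class labels.
#' @export
modal_assignment <- function(post, pi = NULL) {
  post <- as.matrix(post)
  if (is.null(pi)) pi <- rev(seq_len(ncol(post)))  # lower index wins ties
  n_ties <- 0L
  lab <- vapply(seq_len(nrow(post)), function(i) {
    p <- post[i, ]
    cand <- which(p == max(p))
    if (length(cand) > 1L) {
      n_ties <<- n_ties + 1L
      cand <- cand[which.max(pi[cand])]
    }
    cand
  }, integer(1L))
  if (n_ties > 0L)
    message(n_ties, " posterior tie(s) broken toward the larger class")
  lab
}

# Optimal class matching between two item-probability matrices: the
# permutation `perm` of B's rows minimizing total variation distance to A's
# rows, so that B-class perm[k] corresponds to A-class k. Exhaustive for
# K <= 8, greedy beyond.
match_classes <- function(rho_a, rho_b) {
  K <- nrow(rho_a)
  stopifnot(nrow(rho_b) == K)
  cost <- outer(seq_len(K), seq_len(K),
                Vectorize(function(i, j) 0.5 * sum(abs(rho_a[i, ] - rho_b[j, ]))))
  if (K <= 8L) {
    perms <- permutations_of(K)
    tot <- vapply(perms, function(p) sum(cost[cbind(seq_len(K), p)]), numeric(1L))
    perms[[which.min(tot)]]
  } else {
    perm <- integer(K)
    free <- seq_len(K)
    for (i in seq_len(K)) {
      j <- free[which.min(cost[i, free])]
      perm[i] <- j
      free <- setdiff(free, j)
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) for (pos in 0:(K - 1L)) {
    i <- i + 1L
    out[[i]] <- append(p, K, after = pos)
  }
  out
}

#' Choose the number of latent classes
#'
#' Fits the latent class model for every `K` in `k_range` and reports, per
#' `K`: log-likelihood, BIC, adjusted BIC, relative entropy, and a five-fold
#' cross-validated assignment accuracy — each fold's held-out rows are
#' modally assigned by the fold-trained model and compared, after optimal
#' class matching of the fold model to the full-data model, with the
#' full-data modal assignments. The chosen `K` minimizes the adjusted BIC.
#'
#' @param Y binary matrix.
#' @param k_range integer vector of candidate class counts.
#' @param n_starts,tol,max_iter EM settings passed to [fit_lca()].
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed (restarts and fold assignment).
#' @return Object of class `lca_selection`: `report` data.frame and
#'   `chosen_K`; the fitted models are kept in `$models`.
#' @export
select_k <- function(Y, k_range, n_starts = 5, tol = 1e-8, max_iter = 2000,
                     n_folds = 5, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (length(k_range) == 0L) stop("k_range is empty")
  if (any(k_range < 1) || any(k_range >= n)) stop("k_range must lie within [1, n)")

  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  models <- list()
  rows <- lapply(seq_along(k_range), function(i) {
    K <- k_range[i]
    fit <- fit_lca(Y, K, n_starts = n_starts, tol = tol, max_iter = max_iter,
                   seed = child_seed(seed, K))
    models[[i]] <<- fit
    post <- posterior_membership(fit, Y)
    full_lab <- suppressMessages(modal_assignment(post, fit$pi))
    ent <- if (K >= 2) relative_entropy(post) else NA_real_

    acc <- if (K == 1L) 1 else {
      agree <- logical(n)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit_f <- fit_lca(Y[tr, , drop = FALSE], K, n_starts = n_starts,
                         tol = tol, max_iter = max_iter,
                         seed = child_seed(seed, 100L * K + f))
        perm <- match_classes(fit$rho, fit_f$rho)
        # fold-model class perm[k] corresponds to full-model class k
        map <- integer(K); map[perm] <- seq_len(K)
        lab_f <- suppressMessages(modal_assignment(
          posterior_membership(fit_f, Y[!tr, , drop = FALSE]), fit_f$pi))
        agree[!tr] <- map[lab_f] == full_lab[!tr]
      }
      mean(agree)
    }
    data.frame(K = K, loglik = fit$loglik,
               bic = -2 * fit$loglik + fit$n_params * log(n),
               abic = abic(fit), entropy = ent, cv_accuracy = acc)
  })
  report <- do.call(rbind, rows)
  chosen <- report$K[which.min(report$abic)]
  structure(list(report = report, chosen_K = chosen,
                 models = stats::setNames(models, paste0("K", k_range))),
            class = "lca_selection")
}

#' @export
print.lca_selection <- function(x, ...) {
  cat("latent-class model selection (chosen K =", x$chosen_K, "by adjusted BIC)\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
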