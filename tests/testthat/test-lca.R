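test_that("K = 1 collapses to the product-Bernoulli MLE", {
  set.seed(4)
  Y <- matrix(rbinom(200 * 5, 1, rep(c(0.2, 0.4, 0.5, 0.7, 0.9), each = 200)), 200)
  fit <- fit_lca(Y, 1)
  expect_equal(as.vector(fit$rho), colMeans(Y), tolerance = 1e-9)
  # closed-form independent-Bernoulli log-likelihood, computed directly
  p <- colMeans(Y)
  ll <- sum(t(Y) * log(p) + t(1 - Y) * log(1 - p))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$n_params, 5L)
  expect_lte(fit$loglik, 0)
  # posteriors are exactly 1 for a single class
  expect_identical(unique(as.vector(posterior_membership(fit, Y))), 1)
})

test_that("duplicating every observation doubles the log-likelihood only", {
  set.seed(11)
  g <- generate_cohort(small_config(n = 250, K = 2, D = 8, seed = 11))
  Y <- diseases(g$cohort)
  f1 <- fit_lca(Y, 2, n_starts = 5, seed = 7)
  f2 <- fit_lca(rbind(Y, Y), 2, n_starts = 5, seed = 7)
  expect_equal(f2$pi, f1$pi, tolerance = 1e-6)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and classes sort by size", {
  g <- generate_cohort(small_config(n = 400, K = 2, D = 8, seed = 2))
  fit <- fit_lca(diseases(g$cohort), 2, n_starts = 3, seed = 5, trace = TRUE)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_true(all(diff(fit$pi) <= 0))
  expect_true(fit$converged)
  expect_true(all(fit$rho >= 1e-6 & fit$rho <= 1 - 1e-6))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
})

test_that("posterior membership is a Bayes rule on the simplex", {
  g <- generate_cohort(small_config(n = 150, K = 2, D = 8, seed = 6))
  Y <- diseases(g$cohort)
  fit <- fit_lca(Y, 2, n_starts = 3, seed = 6)
  post <- posterior_membership(fit, Y)
  expect_true(all(abs(rowSums(post) - 1) < 1e-10))
  expect_true(all(post >= 0 & post <= 1))
  # direct Bayes-rule computation on one fixture row
  y <- Y[1, ]
  comp <- fit$pi * apply(fit$rho^rep(y, each = 2) *
                           (1 - fit$rho)^rep(1 - y, each = 2), 1, prod)
  expect_equal(post[1, ], comp / sum(comp), tolerance = 1e-10)
  expect_error(posterior_membership(fit, Y[, 1:3]), "diseases")
})

test_that("a symmetric two-class model gives split posteriors on symmetric data", {
  model <- structure(list(K = 2L, pi = c(0.5, 0.5),
                          rho = rbind(c(0.8, 0.2), c(0.2, 0.8)),
                          loglik = -1, n_params = 5L, n_obs = 10L,
                          converged = TRUE, n_iter = 1L),
                     class = "lca_model")
  post <- posterior_membership(model, matrix(c(1, 1), 1))
  expect_equal(as.vector(post), c(0.5, 0.5))
  # a prototypical class-1 vector on a well-separated model is near-certain
  model$rho <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  expect_gt(posterior_membership(model, matrix(c(1, 0), 1))[1, 1], 0.99)
})

test_that("adjusted BIC follows the (n + 2)/24 sample-size correction", {
  mk <- function(ll, npar, n) structure(list(loglik = ll, n_params = npar,
                                             n_obs = n), class = "lca_model")
  expect_equal(abic(mk(-100, 5, 238)), 200 + 5 * log(10))
  expect_equal(abic(mk(-100, 5, 22)), 200)      # penalty vanishes at n = 22
  expect_gt(abic(mk(-100, 8, 238)), abic(mk(-100, 5, 238)))
})

test_that("relative entropy spans [0, 1] between uniform and degenerate", {
  deg <- diag(3)[rep(1:3, 4), ]
  expect_equal(relative_entropy(deg), 1.0)
  unif <- matrix(1 / 3, 12, 3)
  expect_equal(relative_entropy(unif), 0.0)
  expect_equal(relative_entropy(rbind(deg[1:6, ], unif[1:6, ])), 0.5)
  expect_error(relative_entropy(matrix(1, 5, 1)), "K = 1")
})

test_that("modal assignment breaks exact ties toward the larger class", {
  expect_equal(modal_assignment(matrix(c(0.9, 0.1), 1)), 1L)
  expect_message(lab <- modal_assignment(matrix(c(0.5, 0.5), 1), pi = c(0.6, 0.4)),
                 "tie")
  expect_equal(lab, 1L)
  expect_message(lab2 <- modal_assignment(matrix(c(0.5, 0.5), 1), pi = c(0.4, 0.6)),
                 "tie")
  expect_equal(lab2, 2L)
})

test_that("permuting disease columns permutes item probabilities and nothing else", {
  g <- generate_cohort(small_config(n = 300, K = 2, D = 8, seed = 9))
  Y <- diseases(g$cohort)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  f1 <- fit_lca(Y, 2, n_starts = 4, seed = 3)
  f2 <- fit_lca(Y[, perm], 2, n_starts = 4, seed = 3)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$pi, f1$pi, tolerance = 1e-4)
  expect_equal(unname(f2$rho), unname(f1$rho[, perm]), tolerance = 1e-3)
})

test_that("planted two-class structure is recovered", {
  cfg <- small_config(n = 800, K = 2, D = 10, seed = 13)
  g <- generate_cohort(cfg)
  fit <- fit_lca(diseases(g$cohort), 2, n_starts = 5, seed = 1)
  perm <- true_class_map(cfg$item_probs, fit$rho)
  expect_lt(max(abs(cfg$item_probs - fit$rho[perm, ])), 0.07)
  expect_lt(max(abs(cfg$class_proportions - fit$pi[perm])), 0.05)
})

test_that("select_k reports the forced and the degenerate choices", {
  g <- generate_cohort(small_config(n = 250, K = 2, D = 8, seed = 21))
  Y <- diseases(g$cohort)
  one <- select_k(Y, c(2, 2), seed = 2)
  expect_equal(nrow(one$report), 2L)
  expect_equal(one$chosen_K, 2)
  # independent-disease data (no class structure) chooses K = 1
  set.seed(3)
  Y1 <- matrix(rbinom(300 * 6, 1, 0.3), 300)
  sel <- select_k(Y1, 1:3, seed = 4)
  expect_equal(sel$chosen_K, 1)
  expect_error(select_k(Y1, integer(0)), "empty")
  expect_error(fit_lca(Y1, 0), "at least 1")
})
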