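# The forward-backward recursions are checked against brute-force
# enumeration of all S^T status sequences, then the full fitter against
# structural properties (monotone EM, nesting, constraint enforcement)
# and parameter recovery on well-separated synthetic truths.

test_that("the scaled forward pass reproduces the enumerated likelihood", {
  S <- 3L; T_occ <- 3L; J <- 2L
  par <- make_params(S, T_occ, J, seed = 101)
  rows <- rbind(
    c(1L, 2L, 2L, 1L, 1L, 1L),
    c(2L, 2L, 1L, 1L, 2L, 2L),
    c(1L, NA, 2L, 2L, NA, 1L),   # scattered item missingness
    c(1L, 1L, NA, NA, NA, NA),   # drop-out after the first occasion
    c(NA, NA, NA, NA, 1L, 2L))   # late entry
  w <- c(3, 1, 2, 5, 1)
  run <- fixed_param_estep(rows, w, par, S, T_occ, J)
  oracle <- enumerate_loglik(rows, par$delta, par$tau, par$rho_list)
  expect_equal(run$loglik, sum(w * oracle), tolerance = 1e-10)
})

test_that("smoothed marginals match enumeration and are self-consistent", {
  S <- 2L; T_occ <- 4L; J <- 2L
  par <- make_params(S, T_occ, J, seed = 7)
  rows <- rbind(
    c(1L, 1L, 2L, 1L, 1L, 2L, 2L, 2L),
    c(2L, 1L, NA, NA, 1L, 1L, 2L, 1L),
    c(1L, 2L, 1L, 1L, NA, 2L, NA, NA))
  run <- fixed_param_estep(rows, rep(1, 3), par, S, T_occ, J)
  oracle <- enumerate_posteriors(rows, par$delta, par$tau, par$rho_list)
  for (t in seq_len(T_occ))
    expect_equal(unname(run$gamma[[t]]), unname(oracle[, , t]),
                 tolerance = 1e-10)
  # each pairwise joint marginalizes to its adjacent occasion marginals
  for (t in seq_len(T_occ - 1L)) {
    expect_equal(apply(run$xi[[t]], c(1, 2), sum), run$gamma[[t]],
                 tolerance = 1e-10)
    expect_equal(apply(run$xi[[t]], c(1, 3), sum), run$gamma[[t + 1L]],
                 tolerance = 1e-10)
    expect_true(all(run$xi[[t]] >= -1e-12))
  }
  for (t in seq_len(T_occ))
    expect_equal(rowSums(run$gamma[[t]]), rep(1, 3), tolerance = 1e-10)
})

test_that("the fitted log-likelihood agrees with enumeration at the estimates", {
  truth <- crisp_truth(S = 2L, T_occ = 3L, J = 3L, N = 250)
  panel <- simulate_panel(truth, seed = 31)$panel
  pt <- pattern_frequencies(panel, "joint")
  fit <- fit_lta(pt, lta_spec(2L, starts = 4L, seed = 2))
  oracle <- enumerate_loglik(pt$patterns, fit$delta, fit$tau,
                             rep(list(fit$rho), 3L))
  expect_equal(fit$loglik, sum(pt$freq * oracle), tolerance = 1e-8)
  # and the G2 on file is twice the gap to the saturated reference
  expect_equal(fit$stats$G2, 2 * (saturated_loglik(pt) - fit$loglik),
               tolerance = 1e-8)
})

test_that("EM iterations never decrease the log-likelihood", {
  truth <- crisp_truth(S = 3L, T_occ = 3L, J = 4L, N = 300)
  panel <- simulate_panel(truth, seed = 17)$panel
  fit <- suppressWarnings(
    fit_lta(pattern_frequencies(panel, "joint"),
            lta_spec(3L, starts = 3L, seed = 5)))
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  expect_true(fit$convergence$converged)
})

test_that("a one-status chain collapses to independent item margins", {
  truth <- crisp_truth(S = 2L, T_occ = 2L, J = 2L, N = 150, hi = 0.7,
                       lo = 0.45)
  panel <- simulate_panel(truth, seed = 9)$panel
  pt <- pattern_frequencies(panel, "joint")
  fit <- suppressWarnings(
    fit_lta(pt, lta_spec(1L, measurement_invariance = FALSE,
                         starts = 2L, seed = 1)))
  ll <- 0
  for (t in 1:2) for (j in 1:2) {
    cnt <- tabulate(panel$responses[, t, j], 2L)
    ll <- ll + sum(cnt * log(cnt / sum(cnt)))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$stats$P, 4L)   # one binary rho per item-occasion only
})

test_that("restricted fits never beat their nesting free fits", {
  truth <- crisp_truth(S = 2L, T_occ = 3L, J = 3L, N = 400)
  pt <- pattern_frequencies(simulate_panel(truth, seed = 23)$panel, "joint")
  free <- suppressWarnings(
    fit_lta(pt, lta_spec(2L, measurement_invariance = FALSE,
                         starts = 6L, seed = 3)))
  inv <- suppressWarnings(fit_lta(pt, lta_spec(2L, starts = 6L, seed = 3)))
  ti <- suppressWarnings(
    fit_lta(pt, lta_spec(2L, transition_invariance = TRUE,
                         starts = 6L, seed = 3)))
  expect_lte(inv$loglik, free$loglik + 1e-6)
  expect_lte(ti$loglik, inv$loglik + 1e-6)
  # the comparison machinery sees consistent G2 / P gaps
  cmp <- lrdt(inv, free)
  expect_equal(cmp$G2_delta, 2 * (free$loglik - inv$loglik),
               tolerance = 1e-8)
  expect_equal(cmp$df_delta, free$stats$P - inv$stats$P)
  cmp2 <- lrdt(ti, inv)
  expect_equal(cmp2$df_delta, 2L)   # one extra 2x2 transition matrix
})

test_that("invariance constraints are enforced exactly in the output", {
  truth <- crisp_truth(S = 2L, T_occ = 3L, J = 3L, N = 300)
  pt <- pattern_frequencies(simulate_panel(truth, seed = 41)$panel, "joint")
  inv <- suppressWarnings(fit_lta(pt, lta_spec(2L, starts = 3L, seed = 4)))
  expect_true(is.array(inv$rho) && length(dim(inv$rho)) == 3L)
  free <- suppressWarnings(
    fit_lta(pt, lta_spec(2L, measurement_invariance = FALSE,
                         starts = 3L, seed = 4)))
  expect_true(is.list(free$rho) && length(free$rho) == 3L)
  ti <- suppressWarnings(
    fit_lta(pt, lta_spec(2L, transition_invariance = TRUE,
                         starts = 3L, seed = 4)))
  expect_identical(ti$tau[[1L]], ti$tau[[2L]])
})

test_that("fixed and equality rho constraints hold in the solution", {
  truth <- crisp_truth(S = 2L, T_occ = 2L, J = 4L, N = 300)
  pt <- pattern_frequencies(simulate_panel(truth, seed = 13)$panel, "joint")
  spec_fx <- lta_spec(2L, rho_constraints = list(list(
    cells = data.frame(status = 2L, item = 1L), fixed = c(0.5, 0.5))),
    starts = 3L, seed = 6)
  fx <- suppressWarnings(fit_lta(pt, spec_fx))
  # the fixed cell sits at exactly (0.5, 0.5) in one of the statuses
  # (status order is decided by prevalence after fitting)
  held <- apply(fx$rho[, 1L, ], 1L, function(p) all(p == c(0.5, 0.5)))
  expect_true(any(held))
  expect_equal(fx$stats$P, count_parameters(spec_fx, rep(2L, 4L), 2L))
  spec_eq <- lta_spec(2L, rho_constraints = list(list(
    cells = data.frame(status = c(1L, 1L), item = c(1L, 2L)))),
    starts = 3L, seed = 6)
  eq <- suppressWarnings(fit_lta(pt, spec_eq))
  tied <- apply(eq$rho, 1L, function(m) max(abs(m[1L, ] - m[2L, ])))
  expect_lt(min(tied), 1e-10)
})

test_that("parameters of a separated truth are recovered at N = 800", {
  truth <- crisp_truth(S = 3L, T_occ = 3L, J = 6L, N = 800)
  panel <- simulate_panel(truth, seed = 77)$panel
  fit <- fit_lta(pattern_frequencies(panel, "joint"),
                 lta_spec(3L, starts = 6L, seed = 7))
  mae <- aligned_mae(fit, truth)
  expect_lt(mae[["rho"]], 0.08)
  expect_lt(mae[["delta"]], 0.08)
  expect_lt(mae[["tau"]], 0.08)
  # reported statuses are in descending first-occasion prevalence
  expect_true(all(diff(fit$occupancy[1L, ]) <= 1e-8))
})

test_that("attrition rows are absorbed, not dropped", {
  truth <- crisp_truth(S = 2L, T_occ = 3L, J = 3L, N = 400)
  truth$attrition <- c(0, 0.1, 0.3)
  panel <- simulate_panel(truth, seed = 19)$panel
  pt <- pattern_frequencies(panel, "joint")
  fit <- fit_lta(pt, lta_spec(2L, starts = 4L, seed = 8))
  expect_equal(fit$stats$N_effective, 400)
  expect_true(is.finite(fit$loglik))
  # parameters are still recoverable from the partial records
  expect_lt(aligned_mae(fit, truth)[["rho"]], 0.1)
})

test_that("status_posteriors scores new patterns like the oracle", {
  truth <- crisp_truth(S = 2L, T_occ = 2L, J = 3L, N = 200)
  pt <- pattern_frequencies(simulate_panel(truth, seed = 3)$panel, "joint")
  fit <- suppressWarnings(fit_lta(pt, lta_spec(2L, starts = 3L, seed = 9)))
  new_rows <- rbind(c(1L, 1L, 1L, 2L, 1L, 2L),
                    c(2L, NA, 2L, NA, NA, 2L))
  post <- status_posteriors(fit, as_pattern_table(new_rows, 2, 2))
  oracle <- enumerate_posteriors(new_rows, fit$delta, fit$tau,
                                 rep(list(fit$rho), 2L))
  expect_equal(unname(post$marginals), unname(oracle), tolerance = 1e-8)
})

test_that("align_statuses undoes a known permutation exactly", {
  set.seed(55)
  rho <- array(stats::runif(4 * 3 * 2), dim = c(4, 3, 2))
  perm <- c(3L, 1L, 4L, 2L)
  al <- align_statuses(rho, rho[perm, , , drop = FALSE])
  # applying the reported permutation to the shuffled copy restores rho
  expect_equal(rho[perm, , ][al$permutation, , ], rho[, , ])
  expect_equal(al$distance, 0)
  expect_error(align_statuses(rho, rho[1:3, , , drop = FALSE]), "mismatched")
  p4 <- all_permutations(4L)
  expect_equal(nrow(unique(p4)), 24L)
  expect_true(all(apply(p4, 1L, function(r) all(sort(r) == 1:4))))
})

test_that("a pattern table with one occasion is refused", {
  pt <- as_pattern_table(rbind(c(1L, 2L)), 2, 1)
  expect_error(fit_lta(pt, lta_spec(2L)), "T >= 2")
})
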