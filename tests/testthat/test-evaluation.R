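# Parameter counts, degrees of freedom, information criteria, entropy and
# the likelihood-ratio difference test, checked against hand arithmetic.

test_that("cross-sectional parameter counts follow S * sum(C - 1) + S - 1", {
  # six binary items: P = 6S + (S - 1) = 7S - 1
  for (S in 2:7) {
    spec <- lta_spec(S)
    P <- count_parameters(spec, rep(2L, 6L), n_occasions = 1L)
    expect_equal(P, 7L * S - 1L)
  }
  expect_equal(count_parameters(lta_spec(3L), rep(2L, 6L), 1L), 20L)
  expect_equal(count_parameters(lta_spec(4L), rep(2L, 6L), 1L), 27L)
  expect_equal(count_parameters(lta_spec(5L), rep(2L, 6L), 1L), 34L)
  # polytomous items contribute C_j - 1 each
  expect_equal(count_parameters(lta_spec(2L), c(3L, 4L, 2L), 1L),
               2L * (2L + 3L + 1L) + 1L)
})

test_that("cross-sectional residual df runs 50 down to 15 for 2-7 classes", {
  dfs <- vapply(2:7, function(S)
    residual_df(lta_spec(S), rep(2L, 6L), 1L), numeric(1))
  expect_equal(dfs, c(50, 43, 36, 29, 22, 15))
  # W = 2^6 = 64 cells in all cases
  expect_equal(dfs, 64 - (7 * (2:7) - 1) - 1)
})

test_that("longitudinal df reflects invariance structure at W = 262144", {
  cj <- rep(2L, 6L); T3 <- 3L
  df_of <- function(spec) residual_df(spec, cj, T3)
  expect_equal(prod(cj)^T3, 262144)
  # measurement-invariant, free transitions
  expect_equal(df_of(lta_spec(3L)), 262111)   # P = 18 + 2 + 12 = 32
  expect_equal(df_of(lta_spec(4L)), 262092)   # P = 24 + 3 + 24 = 51
  # occasion-specific rho
  expect_equal(df_of(lta_spec(3L, measurement_invariance = FALSE)), 262075)
  expect_equal(df_of(lta_spec(4L, measurement_invariance = FALSE)), 262044)
  # shared transition matrix
  expect_equal(df_of(lta_spec(4L, transition_invariance = TRUE)), 262104)
  # nesting gaps used by the invariance tests
  expect_equal(262111 - 262075, 36)
  expect_equal(262092 - 262044, 48)
  expect_equal(262104 - 262092, 12)
})

test_that("constraints, covariates and groups adjust the count", {
  cj <- rep(2L, 6L)
  base <- count_parameters(lta_spec(4L), cj, 3L)          # 51
  # tying two rho cells to one distribution frees one binary parameter
  eq <- lta_spec(4L, rho_constraints = list(list(
    cells = data.frame(status = c(1L, 2L), item = c(1L, 1L)))))
  expect_equal(count_parameters(eq, cj, 3L), base - 1L)
  # fixing one cell removes its full distribution
  fx <- lta_spec(4L, rho_constraints = list(list(
    cells = data.frame(status = 1L, item = 2L), fixed = c(0.5, 0.5))))
  expect_equal(count_parameters(fx, cj, 3L), base - 1L)
  # one prevalence covariate adds (S - 1) slopes
  cv <- lta_spec(4L, covariates = "x")
  expect_equal(count_parameters(cv, cj, 3L), base + 3L)
  # covariate on transitions doubles each matrix's S(S-1) block
  cvt <- lta_spec(4L, covariates = "x", covariate_on_transitions = TRUE)
  expect_equal(count_parameters(cvt, cj, 3L), base + 3L + 24L)
  # group-varying delta and tau multiply those blocks by the group count
  gr <- lta_spec(4L, group = list(delta_varies = TRUE, tau_varies = TRUE))
  expect_equal(count_parameters(gr, cj, 3L, n_groups = 2L),
               24L + 2L * 3L + 2L * 24L)
})

test_that("an over-parameterized specification is refused a df", {
  expect_error(residual_df(lta_spec(22L), rep(2L, 6L), 1L), "negative")
})

test_that("information criteria reproduce hand-computed values and identities", {
  ic <- information_criteria(35, 27, 1180)
  expect_equal(unname(ic["AIC"]), 89)                     # 35 + 2 * 27
  expect_equal(unname(ic["BIC"]), 35 + log(1180) * 27)
  expect_equal(unname(ic["CAIC"] - ic["BIC"]), 27)
  expect_equal(unname(ic["ABIC"]), 35 + log(1182 / 24) * 27)
  for (P in c(5, 20, 51)) {
    ic2 <- information_criteria(100, P, 500)
    expect_equal(unname(ic2["AIC"] - 100), 2 * P)
    expect_equal(unname(ic2["CAIC"] - ic2["BIC"]), P)
  }
})

test_that("G-squared equals the closed form on complete data", {
  rows <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  freq <- c(30L, 20L, 10L, 40L)
  pt <- as_pattern_table(rows, 2, 1, freq = freq)
  pi_hat <- c(0.3, 0.2, 0.1, 0.4)   # some model's fitted cell probabilities
  ll <- sum(freq * log(pi_hat))
  expect_equal(gsquared(ll, pt),
               2 * sum(freq * log(freq / (100 * pi_hat))),
               tolerance = 1e-12)
  # the saturated model itself has G2 = 0
  expect_equal(gsquared(saturated_loglik(pt), pt), 0)
  expect_warning(gsquared(saturated_loglik(pt) + 1, pt), "negative G-squared")
})

test_that("the saturated reference is stratified by missingness pattern", {
  rows <- rbind(c(1L, 1L), c(2L, 2L), c(1L, NA), c(2L, NA))
  pt <- as_pattern_table(rows, 2, 1, freq = c(3L, 1L, 2L, 2L))
  # strata: complete (n = 4) and item-2-missing (n = 4)
  expect_equal(saturated_loglik(pt),
               3 * log(3 / 4) + 1 * log(1 / 4) +
                 2 * log(2 / 4) + 2 * log(2 / 4),
               tolerance = 1e-12)
})

test_that("relative entropy is 1 for crisp, 0 for uninformative posteriors", {
  crisp <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(relative_entropy(crisp), 1)
  flat <- matrix(0.5, 4, 2)
  expect_equal(relative_entropy(flat), 0)
  # half crisp, half flat: exactly 0.5 for S = 2
  half <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(relative_entropy(half), 0.5)
  # weights replicate rows
  expect_equal(relative_entropy(half, weights = c(2, 2)),
               relative_entropy(rbind(half, half)))
  # three classes normalize by ln 3
  p3 <- matrix(1 / 3, 2, 3)
  expect_equal(relative_entropy(p3), 0)
  e1 <- relative_entropy(matrix(1, 5, 1))
  expect_true(is.na(e1))
  expect_match(attr(e1, "undefined"), "S = 1")
})

test_that("the difference test reproduces hand-checked chi-square p-values", {
  mk <- function(G2, P) list(G2 = G2, P = P)
  a <- lrdt(mk(149.74, 32), mk(100, 68))
  expect_equal(a$G2_delta, 49.74)
  expect_equal(a$df_delta, 36L)
  expect_equal(a$p_value, 0.063492, tolerance = 5e-5)
  expect_equal(a$decision, "restricted_retained")
  b <- lrdt(mk(156.24, 51), mk(100, 99))
  expect_equal(b$p_value, 0.193694, tolerance = 5e-5)
  d <- lrdt(mk(121.84, 39), mk(100, 51))
  expect_equal(d$df_delta, 12L)
  expect_equal(round(d$p_value, 3), 0.039)
  expect_equal(d$decision, "free_preferred")
  # independent check of the chi-square tail by numeric integration
  dens <- function(x) stats::dchisq(x, df = 36)
  expect_equal(a$p_value,
               stats::integrate(dens, 49.74, Inf, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
})

test_that("the difference test guards nesting and records conflicts", {
  mk <- function(G2, P, ...) c(list(G2 = G2, P = P), list(...))
  expect_error(lrdt(mk(100, 50), mk(90, 40)), "not nested")
  expect_error(lrdt(mk(100, 30), mk(101, 40)), "negative likelihood-ratio")
  # significant test but AIC prefers restricted -> conflict is flagged
  cmp <- lrdt(mk(140, 30, AIC = 200, BIC = 250),
              mk(100, 40, AIC = 180, BIC = 260))
  expect_equal(cmp$by_criterion[["lrdt"]], "free_preferred")
  expect_equal(cmp$by_criterion[["bic"]], "restricted_retained")
  expect_true(cmp$conflict)
  # the arbiter switches the decision without changing the evidence
  cmp_bic <- lrdt(mk(140, 30, AIC = 200, BIC = 250),
                  mk(100, 40, AIC = 180, BIC = 260), arbiter = "bic")
  expect_equal(cmp_bic$decision, "restricted_retained")
  expect_equal(cmp_bic$p_value, cmp$p_value)
  # zero-df comparison degenerates to p = 1
  expect_equal(lrdt(mk(100, 40), mk(100, 40))$p_value, 1)
})
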