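test_that("a minimal one-row wide file reads into a 1x1x2 panel", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a_t1,b_t1", "1,2"), f)
  lay <- panel_layout(items = c("a", "b"), occasions = 1, n_categories = 2)
  panel <- read_panel(f, lay)
  expect_equal(dim(panel), c(1L, 1L, 2L))
  expect_equal(as.vector(panel$responses), c(1L, 2L))
})

test_that("write_panel / read_panel round-trips simulator output exactly", {
  truth <- crisp_truth(S = 3, T_occ = 3, J = 6, N = 20)
  panel <- simulate_panel(truth, seed = 21)$panel
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  lay <- panel_layout(items = panel$items, occasions = 3, n_categories = 2,
                      id = "id")
  back <- read_panel(f, lay)
  expect_identical(back$responses, panel$responses)
  # and the file itself is reproduced byte-identically on re-write
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("out-of-range codes are rejected with the offending cell named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a_t1,b_t1", "1,2", "5,1"), f)
  lay <- panel_layout(items = c("a", "b"), occasions = 1, n_categories = 4)
  expect_error(read_panel(f, lay), "a_t1.*row 2")
})

test_that("long files pivot to the wide canonical form", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,occasion,item,response",
               "r1,1,a,1", "r1,1,b,2", "r1,2,a,2", "r1,2,b,1",
               "r2,1,a,2", "r2,2,b,2"), f)
  lay <- panel_layout(items = c("a", "b"), occasions = 2, n_categories = 2,
                      id = "id", format = "long")
  panel <- read_panel(f, lay)
  expect_equal(dim(panel), c(2L, 2L, 2L))
  expect_equal(unname(panel$responses[1L, , ]),
               matrix(c(1L, 2L, 2L, 1L), 2L))
  expect_true(is.na(panel$responses[2L, 1L, 2L]))  # r2 never answered b at t1
})

test_that("category merging recodes, keeps missing, and updates counts", {
  arr <- array(c(1L, 4L, 2L, 3L, NA, 1L), dim = c(3, 1, 2))
  panel <- response_panel(arr, n_categories = 4)
  merged <- collapse_categories(panel, c(1L, 1L, 2L, 2L))
  expect_equal(merged$n_categories, c(2L, 2L))
  expect_equal(merged$responses[2L, 1L, 1L], 2L)  # old "very much" -> yes
  expect_true(is.na(merged$responses[2L, 1L, 2L]))
  # identity map leaves the panel unchanged
  ident <- collapse_categories(panel, 1:4)
  expect_identical(ident$responses, panel$responses)
  # non-surjective maps are configuration errors
  expect_error(collapse_categories(panel, c(1L, 1L, 3L, 3L)), "surjection")
})

test_that("dichotomizing six four-category items collapses the cell count", {
  arr <- array(sample(1:4, 5 * 3 * 6, replace = TRUE), dim = c(5, 3, 6))
  panel <- response_panel(arr, n_categories = 4)
  expect_equal(pattern_frequencies(panel, "joint")$W, (4^6)^3)
  merged <- collapse_categories(panel, c(1L, 1L, 2L, 2L))
  expect_equal(pattern_frequencies(merged, "joint")$W, (2^6)^3)
  expect_equal((2^6)^3, 262144)
})

test_that("marginal proportions count non-missing responses only", {
  arr <- array(c(2L, 2L, 2L, 1L, NA, NA), dim = c(3, 1, 2))
  panel <- response_panel(arr, n_categories = 2)
  mp <- marginal_proportions(panel)
  yes_item1 <- mp$proportion[mp$item == "item1" & mp$category == 2]
  expect_equal(yes_item1, 1.0)
  expect_equal(mp$n_obs[mp$item == "item2"][1L], 1L)
  # an all-answer-one item gives proportion 1 and rows sum to 1
  sums <- tapply(mp$proportion, paste(mp$item, mp$occasion), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("an unobserved item-occasion is flagged undefined, not zero", {
  arr <- array(c(1L, 2L, NA, NA), dim = c(2, 1, 2))
  panel <- response_panel(arr, n_categories = 2)
  mp <- marginal_proportions(panel)
  expect_true(all(is.na(mp$proportion[mp$item == "item2"])))
  expect_match(attr(mp, "undefined"), "item2")
})

test_that("marginals of a simulated panel approach the mixture marginals", {
  truth <- crisp_truth(S = 2, T_occ = 1, J = 4, N = 4000, hi = 0.8, lo = 0.3)
  sim <- simulate_panel(truth, seed = 33)
  mp <- marginal_proportions(sim$panel)
  p_yes <- truth$rho[[1L]][, , 2L]           # S x J
  expected <- as.numeric(truth$delta %*% p_yes)
  got <- mp$proportion[mp$category == 2]
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_true(all(abs(got - expected) < 3 * se))
})

test_that("pattern frequencies match a naive per-row tally", {
  truth <- crisp_truth(S = 3, T_occ = 2, J = 3, N = 50)
  panel <- simulate_panel(truth, seed = 8)$panel
  pt <- pattern_frequencies(panel, "joint")
  expect_equal(sum(pt$freq), 50L)
  flat <- matrix(aperm(panel$responses, c(1, 3, 2)), nrow = 50)
  # naive tally: count each respondent's stringified row
  keys <- apply(panel$responses, 1L, function(m)
    paste(ifelse(is.na(t(m)), ".", t(m)), collapse = ""))
  tally <- table(keys)
  got <- setNames(pt$freq, pattern_strings(pt))
  expect_equal(sort(unname(got[names(tally)])), sort(unname(c(tally))))
  expect_equal(length(unique(pattern_strings(pt))), nrow(pt$patterns))
})

test_that("identical complete rows collapse to one pattern of frequency N", {
  arr <- array(1L, dim = c(7, 2, 3))
  panel <- response_panel(arr, n_categories = 2)
  pt <- pattern_frequencies(panel, "joint")
  expect_equal(nrow(pt$patterns), 1L)
  expect_equal(pt$freq, 7L)
})

test_that("merging categories commutes with pattern tabulation", {
  truth <- crisp_truth(S = 2, T_occ = 2, J = 3, N = 40)
  panel <- simulate_panel(truth, seed = 12)$panel
  # 2-category items with identity-then-merge vs merge-then-tabulate
  arr4 <- panel$responses
  arr4[!is.na(arr4)] <- arr4[!is.na(arr4)] * 2L - sample(0:1, sum(!is.na(arr4)), TRUE)
  panel4 <- response_panel(arr4, n_categories = 4)
  map <- c(1L, 1L, 2L, 2L)
  a <- pattern_frequencies(collapse_categories(panel4, map), "joint")
  b <- pattern_frequencies(panel4, "joint")
  # induced merge on the tabulated patterns
  merged_pat <- b$patterns
  merged_pat[!is.na(merged_pat)] <- map[merged_pat[!is.na(merged_pat)]]
  key <- apply(merged_pat, 1L, paste, collapse = "|")
  induced <- tapply(b$freq, key, sum)
  got <- setNames(a$freq, apply(a$patterns, 1L, paste, collapse = "|"))
  expect_equal(sort(unname(got)), sort(unname(c(induced))))
})

test_that("pattern tables export as two-column CSV", {
  arr <- array(c(1L, 2L, 1L, NA), dim = c(2, 1, 2))
  panel <- response_panel(arr, n_categories = 2)
  pt <- pattern_frequencies(panel, "occasion", 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pattern_table(pt, f)
  out <- read.csv(f, colClasses = "character")
  expect_equal(names(out), c("pattern", "frequency"))
  expect_setequal(out$pattern, c("11", "2."))
})
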