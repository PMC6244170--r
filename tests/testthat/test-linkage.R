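# Item linkage: correlations, subscale selection, linking regressions and
# optimal-profile projection.

mk_resp <- function(m, prefix = "v") {
  data.frame(respondent_id = sprintf("r%02d", seq_len(nrow(m))),
             m, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("correlate_items matches the direct Pearson formula", {
  # 5-respondent hand-computable table
  a <- matrix(c(1, 2, 3, 4, 5,
                2, 2, 3, 5, 4), ncol = 2,
              dimnames = list(NULL, c("a1", "a2")))
  b <- matrix(c(5, 4, 3, 2, 1,
                1, 3, 2, 4, 5,
                2, 2, 2, 3, 3), ncol = 3,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  ct <- correlate_items(mk_resp(a), mk_resp(b))
  for (i in 1:2) for (j in 1:3)
    expect_equal(ct[i, j], pearson_oracle(a[, i], b[, j]), tolerance = 1e-12)
  # duplicated item correlates 1 with itself
  dup <- mk_resp(cbind(t1 = a[, 1]))
  expect_equal(correlate_items(mk_resp(a), dup)["a1", "t1"], 1)
  # independent noise at n = 10000 is near zero
  set.seed(31)
  x <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "a1"))
  y <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "t1"))
  expect_lt(abs(correlate_items(mk_resp(x), mk_resp(y))[1, 1]), 0.05)
  # zero-variance item flagged missing, disjoint respondents error
  z <- mk_resp(cbind(t1 = rep(2, 5)))
  expect_true(is.na(suppressWarnings(
    correlate_items(mk_resp(a), z)["a1", "t1"])))
  b2 <- mk_resp(b)
  b2$respondent_id <- paste0("x", b2$respondent_id)
  expect_error(correlate_items(mk_resp(a), b2), "overlapping")
})

test_that("subscale selection equals a sort-then-take-k oracle", {
  set.seed(17)
  for (rep in 1:10) {
    r <- round(stats::runif(20, -0.9, 0.9), 3)
    ct <- matrix(r, nrow = 1,
                 dimnames = list("a1", sprintf("t%02d", 1:20)))
    sel <- select_subscale_items(ct, k = 8, r_min = 0)
    oracle <- colnames(ct)[order(-abs(r), seq_along(r))][1:8]
    expect_equal(sel$target_item, oracle)
    expect_equal(sel$r, as.numeric(r[match(oracle, colnames(ct))]))
  }
})

test_that("selection honors the threshold rule and tie-breaking", {
  ct <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.45, 0.4, 0.35, 0.1, 0.05),
               nrow = 1, dimnames = list("a1", paste0("t", 1:10)))
  sel <- select_subscale_items(ct, k = 8, r_min = 0.3)
  expect_true(attr(sel, "created")["a1"])
  expect_equal(nrow(sel), 8)
  expect_true(all(abs(sel$r) >= 0.3))
  # only 5 items reach the threshold: no subscale is created
  ct2 <- matrix(c(0.6, 0.5, 0.45, 0.4, 0.35, rep(0.1, 5)),
                nrow = 1, dimnames = list("a1", paste0("t", 1:10)))
  sel2 <- select_subscale_items(ct2, k = 8, r_min = 0.3)
  expect_false(attr(sel2, "created")["a1"])
  expect_equal(nrow(sel2), 0)
  # reversed indicators qualify through |r|
  ct3 <- matrix(c(-0.9, -0.8, 0.7, 0.6, 0.5, 0.45, 0.4, 0.35, 0.1, 0),
                nrow = 1, dimnames = list("a1", paste0("t", 1:10)))
  sel3 <- select_subscale_items(ct3, k = 8, r_min = 0.3)
  expect_true(attr(sel3, "created")["a1"])
  expect_equal(sel3$r[1], -0.9)
  # signed statistic drops them
  sel4 <- select_subscale_items(ct3, k = 8, r_min = 0.3,
                                statistic = "signed")
  expect_false(attr(sel4, "created")["a1"])
  # ties at the k-th rank break by column order
  ct5 <- matrix(rep(0.5, 10), nrow = 1,
                dimnames = list("a1", paste0("t", 1:10)))
  sel5 <- select_subscale_items(ct5, k = 8, r_min = 0.3)
  expect_equal(sel5$target_item, paste0("t", 1:8))
  expect_error(select_subscale_items(ct5, k = 11), "exceeds")
})

test_that("selection is invariant to target column order", {
  set.seed(23)
  r <- stats::runif(15, 0.2, 0.9)
  ct <- matrix(r, nrow = 1, dimnames = list("a1", sprintf("t%02d", 1:15)))
  perm <- sample(15)
  sel_a <- select_subscale_items(ct, k = 6, r_min = 0.3)
  sel_b <- select_subscale_items(ct[, perm, drop = FALSE], k = 6,
                                 r_min = 0.3)
  expect_setequal(sel_a$target_item, sel_b$target_item)
})

test_that("linking regressions match the closed-form OLS oracle", {
  # identity regression
  a <- mk_resp(cbind(a1 = c(1, 2, 3, 4, 5)))
  sel <- data.frame(anchor_item = "a1", target_item = "t1",
                    stringsAsFactors = FALSE)
  fit <- fit_item_links(a, mk_resp(cbind(t1 = c(1, 2, 3, 4, 5))), sel)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  # constant target: a = c, b = 0
  fit2 <- fit_item_links(a, mk_resp(cbind(t1 = rep(2.5, 5))), sel)
  expect_equal(fit2$a, 2.5)
  expect_equal(fit2$b, 0)
  # 4-point hand dataset vs normal equations
  x <- c(1, 2, 4, 5); y <- c(2.1, 2.9, 4.3, 5.2)
  b_or <- (4 * sum(x * y) - sum(x) * sum(y)) / (4 * sum(x^2) - sum(x)^2)
  a_or <- mean(y) - b_or * mean(x)
  fit3 <- fit_item_links(mk_resp(cbind(a1 = x)), mk_resp(cbind(t1 = y)),
                         sel)
  expect_equal(fit3$a, a_or, tolerance = 1e-12)
  expect_equal(fit3$b, b_or, tolerance = 1e-12)
  # zero anchor variance errors
  expect_error(fit_item_links(mk_resp(cbind(a1 = rep(3, 5))),
                              mk_resp(cbind(t1 = y[c(1:4, 4)])), sel),
               "zero variance")
})

test_that("profile projection evaluates the fitted line and clips", {
  lm0 <- data.frame(anchor_item = c("a1", "a2"),
                    target_item = c("t1", "t2"),
                    a = c(1.0, 2.0), b = c(1.0, 0.0),
                    stringsAsFactors = FALSE)
  em <- data.frame(item = c("a1", "a2"), mean = c(4.7, 3.0))
  prof <- project_optimal_profile(lm0, em, bounds = c(1, 5))
  # 1.0 + 1.0 * 4.7 = 5.7 clips to 5.0
  expect_equal(prof$optimal[1], 5.0)
  expect_equal(prof$raw[1], 5.7)
  # b = 0: the intercept regardless of the expert mean
  expect_equal(prof$optimal[2], 2.0)
  expect_error(project_optimal_profile(
    lm0, data.frame(item = c("a1", "a2"), mean = c(5.4, 3))), "bounds")
  expect_error(project_optimal_profile(
    lm0, data.frame(item = "a1", mean = 4)), "missing")
})

test_that("on noise-free data projection passes through the sample means", {
  spec <- population_spec(seed = 12)
  hs <- generate_honest_sample(spec, n = 500, discretize = FALSE, noise = 0)
  lk <- build_linkage(hs$anchor, hs$target)
  # with all residual noise removed every target item lies exactly on its
  # line (r = 1), so every work style forms a subscale
  expect_equal(unname(sum(attr(lk, "created"))), 16)
  # OLS passes through the means: projecting at the anchor sample mean
  # returns the target sample mean
  one <- lk[lk$anchor_item == "wsq_leadership", ][1, , drop = FALSE]
  mx <- mean(hs$anchor$wsq_leadership)
  em <- data.frame(item = "wsq_leadership", mean = mx)
  prof <- project_optimal_profile(one, em)
  expect_equal(prof$optimal, mean(hs$target[[one$target_item]]),
               tolerance = 1e-10)
  # and the fitted lines equal the generating lines exactly
  j <- match(one$target_item, hs$links$item)
  expect_equal(one$b, hs$links$b[j], tolerance = 1e-10)
  expect_equal(one$a, hs$links$a[j], tolerance = 1e-10)
})
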