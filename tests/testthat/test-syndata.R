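# Synthetic-data generator: expert panels, faked responses, cognitive
# parcels, determinism and bounds.

test_that("population_spec validates its invariants", {
  expect_error(population_spec(n_respondents = 0), "positive")
  expect_error(population_spec(n_experts_per_job = 10), "25")
  expect_error(population_spec(gamma_shape = c(g = 0.9, gc = 0.8, ep = 0)),
               "orthogonal")
})

test_that("expert panels centre on the true optimal profile", {
  spec0 <- population_spec(noise_sd = list(rater = 0, honest = 1,
                                           faking = 1.8))
  panel <- generate_expert_panel(spec0, "pilot")
  means <- expert_panel_means(panel)
  truth <- spec0$true_profiles[, "pilot"]
  expect_equal(stats::setNames(means$mean, NULL), unname(truth))
  # zero noise: all experts identical
  expect_equal(unname(unlist(panel[1, -1])), unname(truth))
  # the administered target-task anchors for the pilot carry the published
  # mean expert ratings
  sub <- paste0("wsq_", c("self_control", "persistence",
                          "concern_for_others", "innovation"))
  expect_equal(means$mean[match(sub, means$item)], c(4.7, 4.1, 4.1, 3.5))

  # with rater noise the panel mean stays within the 3-sigma CLT band
  spec <- population_spec(seed = 21)
  p2 <- generate_expert_panel(spec, "tour_guide")
  m2 <- expert_panel_means(p2)
  truth2 <- spec$true_profiles[, "tour_guide"]
  expect_true(all(abs(m2$mean - truth2) < 3 * 0.5 / sqrt(25)))
  # ratings in bounds, means rational (non-integer in general)
  expect_true(all(as.matrix(p2[, -1]) >= 1 & as.matrix(p2[, -1]) <= 5))
  expect_true(any(m2$mean != round(m2$mean)))
  expect_error(generate_expert_panel(spec, "astronaut"), "astronaut")
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- simulate_study(population_spec(n_respondents = 40,
                                       n_attention_fail = 8, seed = 5))
  s2 <- simulate_study(population_spec(n_respondents = 40,
                                       n_attention_fail = 8, seed = 5))
  expect_identical(s1$faked, s2$faked)
  expect_identical(s1$cognitive, s2$cognitive)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expert_panels, s2$expert_panels)
  s3 <- simulate_study(population_spec(n_respondents = 40,
                                       n_attention_fail = 8, seed = 6))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("faked responses respect the slider bounds and perfect-faker limits", {
  st <- default_study()
  for (task in st$faked) {
    m <- as.matrix(task[, -1])
    expect_true(all(m >= 1 & m <= 50))
  }
  # perfect shape faker: blend weight saturates at 1, zero noise
  spec <- population_spec()
  opt <- stats::setNames(spec$true_profiles[, "pilot"],
                         paste0("wsq_", rownames(spec$true_profiles)))
  ab <- data.frame(respondent_id = c("a", "b"),
                   elevation = c(50, 0), shape = c(50, 0))
  resp <- generate_faked_responses(spec, opt, ab, "wsq_pilot",
                                   discretize = FALSE, zero_noise = TRUE)
  on_anchor <- as.numeric(resp[1, -1]) / 10   # slider back to anchor units
  sc <- shape_score(on_anchor, unname(opt))
  expect_equal(sc, 1, tolerance = 1e-6)
  # perfect elevation faker: mean offset decays to zero
  el <- elevation_score(on_anchor, unname(opt), transform = FALSE)
  expect_lt(el, 1e-10)
  # dimension mismatch errors
  expect_error(generate_faked_responses(spec, opt,
                                        ab[, c("respondent_id", "shape")],
                                        "wsq_pilot"), "columns")
})

test_that("higher ability latents yield better profile-similarity scores", {
  st <- big_study()
  sc <- scored_big_study()
  sw <- scores_wide(sc, "shape")
  ew <- scores_wide(sc, "elevation")
  tr <- st$truth
  # generator fidelity: latent shape ability vs computed shape score
  r_shape <- stats::cor(sw$s_neo_pilot, tr$shape, use = "complete.obs")
  expect_gt(r_shape, 0.5)
  # elevation: lower score = higher ability, so correlation is negative
  r_elev <- stats::cor(ew$e_neo_pilot, tr$elevation)
  expect_lt(r_elev, -0.5)
  # monotonicity across ability quartiles for every task
  q <- cut(tr$shape, stats::quantile(tr$shape, c(0, 0.25, 0.75, 1)),
           include.lowest = TRUE, labels = FALSE)
  for (tk in unique(sc$task)) {
    s <- sw[[paste0("s_", tk)]]
    expect_gt(mean(s[q == 3], na.rm = TRUE), mean(s[q == 1], na.rm = TRUE))
  }
})

test_that("cognitive parcels converge to the closed-form bifactor covariance", {
  spec <- population_spec(seed = 42)
  n <- 50000
  set.seed(99)
  fs <- data.frame(respondent_id = seq_len(n), g = rnorm(n), gc = rnorm(n),
                   ep = rnorm(n))
  parc <- generate_cognitive_scores(spec, fs)
  S_emp <- stats::cov(as.matrix(parc[, -1]))
  S_th <- fakability:::bifactor_implied_cov()
  expect_lt(max(abs(S_emp - S_th)), 0.02)
  # determinism
  parc2 <- generate_cognitive_scores(spec, fs)
  expect_identical(parc, parc2)
  # degenerate bifactor: no nested loadings leaves a single-factor structure
  ld <- fakability:::default_parcel_loadings()
  ld$gc <- 0
  ld$ep <- 0
  S1 <- fakability:::bifactor_implied_cov(ld)
  off <- S1 - diag(diag(S1))
  expect_equal(off, outer(ld$g, ld$g) - diag(ld$g^2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # inadmissible loadings are rejected
  ld_bad <- fakability:::default_parcel_loadings()
  ld_bad$g[4] <- 0.9
  ld_bad$gc[4] <- 0.6
  expect_error(generate_cognitive_scores(spec, fs, ld_bad), "unique variance")
})

test_that("honest linkage sample carries its declared generating lines", {
  spec <- population_spec(seed = 8)
  hs <- generate_honest_sample(spec, n = 4000, discretize = FALSE,
                               noise = 0)
  links <- hs$links
  # with zero residual noise the regression recovers each line exactly
  for (j in sample(which(links$in_true_subscale), 10)) {
    x <- hs$anchor[[paste0("wsq_", links$work_style[j])]]
    y <- hs$target[[links$item[j]]]
    b <- stats::cov(x, y) / stats::var(x)
    expect_equal(b, links$b[j], tolerance = 1e-10)
    expect_equal(mean(y) - b * mean(x), links$a[j], tolerance = 1e-10)
  }
  # responses stay inside the anchor scale
  expect_true(all(as.matrix(hs$target[, -1]) >= 1 &
                    as.matrix(hs$target[, -1]) <= 5))
})
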