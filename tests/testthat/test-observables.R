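test_that("infection probability is the identified occupancy probability", {
  hm <- demo_model(2, 3, delta = 1)
  tt <- c(0, 1, 10)
  traj <- solve_master(hm, tt)
  pi_traj <- infection_probability(traj)
  expect_equal(pi_traj$probability, traj$probability)
  expect_true(all(pi_traj$probability >= 0 & pi_traj$probability <= 1))
  expect_equal(pi_traj$quantity, rep("infection", 3))
})

test_that("herd immunity is the complement and grows monotonically", {
  hm <- demo_model(2, 3, delta = 1)
  tt <- c(0, log_time_grid(0.01, 1e6, 80))
  pi_traj <- infection_probability(solve_return_closed(hm, tt))
  imm <- herd_immunity(pi_traj)
  expect_equal(imm$probability, 1 - pi_traj$probability)
  expect_equal(imm$probability[1], 0)
  expect_true(all(diff(imm$probability) >= -1e-14))
  expect_equal(imm$probability[length(tt)], 1 - 1 / 8, tolerance = 1e-9)
})

test_that("theoretical exponent is ln(p)/Delta with its scalings", {
  B <- 2 * log(2)
  expect_equal(theoretical_exponent(2, B), 0.5)
  expect_equal(theoretical_exponent(2, 5 * B), 0.1)
  expect_equal(theoretical_exponent(2, 50 * B), 0.01)
  expect_equal(theoretical_exponent(3, 1), log(3))
  # doubling the barrier halves the exponent
  expect_equal(theoretical_exponent(2, 2 * 1.3),
               theoretical_exponent(2, 1.3) / 2)
})

test_that("spreading entropy is Shannon entropy in nats", {
  expect_equal(spreading_entropy(rep(1 / 4, 4)), log(4))
  expect_equal(spreading_entropy(c(1, 0, 0)), 0)
  expect_error(spreading_entropy(c(0.5, 0.2)), "sum to 1")
  expect_error(spreading_entropy(c(-0.5, 1.5)), "nonnegative")
  # Jensen bound over random distributions
  set.seed(1)
  for (p in c(2, 3, 7)) {
    for (i in 1:20) {
      q <- stats::rgamma(p, 1); q <- q / sum(q)
      expect_lte(spreading_entropy(q), log(p) + 1e-12)
    }
  }
})

test_that("uniform spreading entropy over Delta equals the decay exponent", {
  for (p in 2:10) {
    for (Delta in c(0.5, 2)) {
      expect_equal(spreading_entropy(rep(1 / p, p)) / Delta,
                   theoretical_exponent(p, Delta))
    }
  }
  # nonuniform splits are flagged as conjectured
  ee <- entropy_exponent(c(0.7, 0.3), delta = 1)
  expect_true(ee$conjectured)
  expect_lt(ee$exponent, log(2))
  expect_false(entropy_exponent(c(0.5, 0.5), delta = 1)$conjectured)
})

test_that("a synthetic pure power law is recovered to machine precision", {
  plateau <- 2^-10
  tt <- log_time_grid(1, 1e8, 120)
  df <- tibble::tibble(time = tt, probability = tt^-0.5 + plateau,
                       subject = "state:0", origin = "0")
  class(df) <- c("uw_trajectory", class(df))
  fit <- suppressWarnings(fit_power_law(df, plateau = plateau)) # exact input: lm flags a perfect fit
  expect_equal(fit$exponent_hat, 0.5, tolerance = 1e-6)
  expect_lt(fit$stderr, 1e-6)
})

test_that("the fitted exponent tracks ln(p)/Delta on deep trees", {
  for (p in c(2, 3)) {
    B <- 2 * log(p)
    hats <- sapply(c(1, 5), function(k) {
      hm <- hop_model(social_tree(p, 12), barrier_profile(delta = k * B))
      fit_power_law(solve_return_closed(hm, recommended_time_grid(hm, 400)))$exponent_hat
    })
    expect_equal(hats[1], theoretical_exponent(p, B), tolerance = 0.15)
    expect_equal(hats[2], theoretical_exponent(p, 5 * B), tolerance = 0.15)
    expect_gt(hats[1], hats[2]) # exponent decreases as Delta increases
  }
})

test_that("power-law fit refuses an empty window with a diagnostic", {
  hm <- demo_model(2, 2, delta = 1)
  expect_error(fit_power_law(solve_return_closed(hm, c(1, 2, 3))),
               "infeasible")
})

test_that("mean distance starts at 0 and saturates at the uniform average", {
  hm <- demo_model(2, 3, delta = 1)
  tt <- c(0, log_time_grid(0.01, 1e7, 80))
  md <- mean_distance_exact(hm, tt)
  expect_equal(md$mean_distance[1], 0)
  expect_true(all(diff(md$mean_distance) >= -1e-12))
  # brute-force uniform average over the 8 states of the binary 3-level tree
  cm <- enumerate_coords(2, 3)
  brute_avg <- mean(apply(cm, 1, function(r) brute_dist(cm[1, ], r)))
  expect_equal(uniform_mean_distance(hm$tree), brute_avg)
  expect_equal(md$mean_distance[length(tt)], brute_avg, tolerance = 1e-8)
  # matches the dense oracle expectation sum_y d(0, y) P(y, t)
  Q <- build_generator(hm)
  d0 <- label_dist(hm$tree, rep(0, 8), 0:7)
  for (t in c(0.5, 4)) {
    expect_equal(md$mean_distance[which.min(abs(md$time - t))],
                 sum(d0 * brute_expm_probs(Q, 0, md$time[which.min(abs(md$time - t))])),
                 tolerance = 1e-10)
  }
})

test_that("a synthetic logarithmic growth curve recovers slope 1/Delta", {
  Delta <- 1.7
  tt <- log_time_grid(10, 1e9, 60)
  df <- tibble::tibble(time = tt, mean_distance = log(tt) / Delta)
  fit <- suppressWarnings(fit_log_growth(df, saturation = max(df$mean_distance) / 0.7))
  expect_equal(fit$slope_hat, 1 / Delta, tolerance = 1e-10)
})

test_that("mean distance grows like log(t)/Delta before saturation", {
  slopes <- sapply(c(1, 2), function(D) {
    hm <- hop_model(social_tree(2, 14), barrier_profile(delta = D))
    md <- mean_distance_exact(hm, recommended_time_grid(hm, 300))
    attr(md, "model") <- hm
    fit_log_growth(md)$slope_hat
  })
  expect_equal(slopes[1], 1, tolerance = 0.25)
  expect_equal(slopes[2], 0.5, tolerance = 0.25)
  # doubling Delta halves the slope
  expect_equal(slopes[1] / slopes[2], 2, tolerance = 0.1)
})

test_that("log-growth fit refuses a saturated window", {
  hm <- demo_model(2, 2, delta = 1)
  md <- mean_distance_exact(hm, c(1e5, 1e6, 1e7))
  attr(md, "model") <- hm
  expect_error(fit_log_growth(md), "infeasible")
})

test_that("fit objects expose broom-style views and a JSON report", {
  hm <- hop_model(social_tree(2, 10), barrier_profile(delta = 2 * log(2)))
  fit <- fit_power_law(solve_return_closed(hm, recommended_time_grid(hm)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[td$term == "exponent"], fit$exponent_hat)
  gl <- glance(fit)
  expect_equal(gl$theory, 0.5)
  expect_lt(gl$rel.error, 0.15)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$exponent_hat, fit$exponent_hat)
  expect_equal(parsed$theoretical_exponent, 0.5)
  # log-growth fit views
  md <- mean_distance_exact(hm, recommended_time_grid(hm, 200))
  attr(md, "model") <- hm
  lf <- fit_log_growth(md)
  expect_equal(tidy(lf)$term, "slope")
  expect_true(all(c("slope_hat", "r.squared") %in% names(glance(lf))))
})
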