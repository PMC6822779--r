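scored_fixture <- function(d, accuracy, confidence) {
  tibble::tibble(I = 1, d = d, e_I = 1, choice = 1,
                 accuracy = as.integer(accuracy), confidence = confidence)
}

test_that("confidence curves group by exact level with per-accuracy means", {
  tab <- scored_fixture(d = c(0, 0, 1, 1),
                        accuracy = c(1, 0, 1, 0),
                        confidence = c(0.5, 0.5, 0.9, 0.8))
  cv <- confidence_curve(tab)
  expect_equal(cv$level, c(0, 1))
  expect_equal(cv$mean_conf_correct, c(0.5, 0.9))
  expect_equal(cv$mean_conf_incorrect, c(0.5, 0.8))
  expect_equal(cv$n_correct + cv$n_incorrect, c(2L, 2L))
})

test_that("continuous binning uses equal-width bins with midpoint labels and conserves counts", {
  cfg <- experiment_config(prior_cunif(0, 4), n_trials = 2e4, seed = 21)
  tab <- score_table(posterior_engine(cfg$prior, 1), simulate_trials(cfg))
  cv <- confidence_curve(tab, bins = 10)
  expect_equal(nrow(cv), 10)
  w <- max(tab$d) / 10
  expect_equal(cv$level, w / 2 + w * (0:9))
  expect_equal(sum(cv$n_correct + cv$n_incorrect), nrow(tab))
  expect_error(confidence_curve(simulate_trials(cfg)), "scored")
})

test_that("empty level-by-accuracy cells are NA, not zero", {
  tab <- scored_fixture(d = c(0, 0, 2), accuracy = c(1, 0, 1),
                        confidence = c(0.5, 0.5, 0.99))
  cv <- confidence_curve(tab)
  expect_true(is.na(cv$mean_conf_incorrect[cv$level == 2]))
  expect_equal(cv$n_incorrect[cv$level == 2], 0L)
})

test_that("pattern classification thresholds count-weighted slopes", {
  up_down <- confidence_curve(scored_fixture(
    d = rep(c(0, 1, 2), each = 2),
    accuracy = rep(c(1, 0), 3),
    confidence = c(0.6, 0.6, 0.7, 0.55, 0.8, 0.5)))
  expect_equal(classify_pattern(up_down)$label, "folded_X")
  both_up <- confidence_curve(scored_fixture(
    d = rep(c(0, 1, 2), each = 2),
    accuracy = rep(c(1, 0), 3),
    confidence = c(0.6, 0.55, 0.7, 0.6, 0.8, 0.65)))
  expect_equal(classify_pattern(both_up)$label, "double_increase")
  flat_incorrect <- confidence_curve(scored_fixture(
    d = rep(c(0, 1, 2), each = 2),
    accuracy = rep(c(1, 0), 3),
    confidence = c(0.6, 0.6, 0.7, 0.6, 0.8, 0.6)))
  expect_equal(classify_pattern(flat_incorrect)$label, "flat")
  expect_equal(classify_pattern(up_down)$slope_correct, 0.1, tolerance = 1e-12)
  expect_equal(classify_pattern(up_down)$slope_incorrect, -0.05, tolerance = 1e-12)
})

test_that("classification drops empty cells with a warning and degrades to NA", {
  tab <- scored_fixture(d = c(0, 0, 2, 2, 4), accuracy = c(1, 0, 1, 0, 1),
                        confidence = c(0.6, 0.6, 0.8, 0.5, 0.99))
  expect_warning(pc <- classify_pattern(confidence_curve(tab)), "dropped")
  expect_false(is.na(pc$slope_incorrect))
  one_sided <- scored_fixture(d = c(0, 0, 2, 4), accuracy = c(1, 0, 1, 1),
                              confidence = c(0.6, 0.6, 0.8, 0.99))
  expect_warning(pc2 <- classify_pattern(confidence_curve(one_sided)))
  expect_true(is.na(pc2$label))
})

test_that("pattern calls are invariant to relabeling the identities", {
  cfg <- experiment_config(prior_discrete(0:2), n_trials = 2e4, seed = 17)
  eng <- posterior_engine(cfg$prior, 1)
  tab <- score_table(eng, simulate_trials(cfg))
  flipped <- tab
  flipped$I <- -tab$I
  flipped$e_I <- -tab$e_I
  flipped$choice <- -tab$choice
  flipped <- score_table(eng, flipped)
  p1 <- classify_pattern(confidence_curve(tab))
  p2 <- classify_pattern(confidence_curve(flipped))
  expect_identical(p1$label, p2$label)
  expect_equal(p1$slope_correct, p2$slope_correct, tolerance = 1e-12)
  expect_equal(p1$slope_incorrect, p2$slope_incorrect, tolerance = 1e-12)
})

test_that("conditional entropy matches closed forms exactly", {
  perfect <- scored_fixture(d = 1, accuracy = c(1, 1), confidence = c(1, 1))
  expect_equal(accuracy_entropy(perfect), 0, tolerance = 1e-12)
  guessing <- scored_fixture(d = 1, accuracy = c(1, 0, 1, 0), confidence = rep(0.5, 4))
  expect_equal(accuracy_entropy(guessing), log(2), tolerance = 1e-12)
  two <- scored_fixture(d = 1, accuracy = c(1, 0), confidence = c(0.9, 0.9))
  expect_equal(accuracy_entropy(two), -(log(0.9) + log(0.1)) / 2, tolerance = 1e-12)
})

test_that("entropy raises a domain error identifying a zero-probability trial", {
  bad <- scored_fixture(d = 1, accuracy = c(1, 0), confidence = c(0.9, 1))
  expect_error(accuracy_entropy(bad), "trial\\(s\\) 2")
})

test_that("the true posterior minimizes conditional entropy among tested scorers", {
  cfg <- experiment_config(prior_discrete(0:2), n_trials = 1e5, seed = 33)
  tab <- score_table(posterior_engine(cfg$prior, 1), simulate_trials(cfg))
  h_true <- accuracy_entropy(tab)
  squashed <- tab
  squashed$confidence <- (tab$confidence + 1) / 2
  expect_gt(accuracy_entropy(squashed), h_true)
  constant <- tab
  constant$confidence <- 0.75
  expect_gt(accuracy_entropy(constant), h_true)
})

test_that("reliable discriminability evidence lowers the entropy of accuracy given confidence", {
  cfg <- experiment_config(prior_discrete(0:1), sigma_d = 0.1, n_trials = 1e5, seed = 6)
  es <- entropy_comparison(cfg)
  expect_lt(es$H_with_discriminability, es$H_identity_only)
  expect_gt(es$H_identity_only - es$H_with_discriminability, 3 * es$se_diff)
  expect_identical(entropy_comparison(cfg), es)
  expect_error(entropy_comparison(
    experiment_config(prior_discrete(0:1), n_trials = 100, seed = 1)), "general")
})
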