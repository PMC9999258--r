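fake_features <- function(amp = 1, mean = 1, rms = 1, jerk = 1,
                          strength = 1, available = TRUE) {
  structure(list(amp = amp, mean = mean, rms = rms, jerk = jerk,
                 strength = strength, strength_available = available),
            class = "feature_vector")
}

unit_template <- function(difficulty = "hard", ...) {
  reference_template("bobath_handshake", difficulty,
                     c(amp = 1, mean = 1, rms = 1, jerk = 1, strength = 1),
                     ...)
}

test_that("feature similarity follows the relative-error kernel", {
  expect_equal(feature_similarity(2, 2), 1)
  expect_equal(feature_similarity(0, 3), 0)
  expect_equal(feature_similarity(0.75 * 4, 4), 0.75)
  expect_equal(feature_similarity(8, 4), 0)          # clipped at 0
  expect_equal(feature_similarity(-0.3, 0), 0.7)     # absolute scale at ref 0
  expect_error(feature_similarity(Inf, 1), "finite")
})

test_that("combined score is the weighted similarity over the active set", {
  tpl <- unit_template("hard")
  expect_equal(combined_score(fake_features(), tpl), 1)
  # sims (1, .5, .5, .5, .5) x weights (.5, .2, .1, .1, .1) = 0.75
  f <- fake_features(amp = 1, mean = 1.5, rms = 1.5, jerk = 1.5,
                     strength = 1.5)
  expect_equal(combined_score(f, tpl), 0.75)
  f0 <- fake_features(amp = 0, mean = 3, rms = 9, jerk = 99, strength = 2)
  expect_equal(combined_score(f0, tpl), 0)
  # simple mode: amp alone decides
  easy <- unit_template("easy")
  expect_equal(combined_score(fake_features(amp = 0.8, mean = 0), easy), 0.8)
})

test_that("invalid weight vectors are rejected", {
  expect_error(unit_template(weights = c(amp = 0.5, mean = 0.2, rms = 0.1,
                                         jerk = 0.1, strength = 0.2)),
               "sum to 1")
  expect_error(unit_template(weights = c(amp = 1.5, mean = -0.5, rms = 0,
                                         jerk = 0, strength = 0)),
               "non-negative")
  expect_error(reference_template("bobath_handshake", "easy", c(amp = 0)),
               "amp")
})

test_that("unavailable strength drops out with weight renormalization", {
  tpl <- unit_template("hard")
  f <- fake_features(strength = 0, available = FALSE)
  expect_equal(combined_score(f, tpl), 1)  # others perfect, renormalized
  f2 <- fake_features(amp = 2, strength = 0, available = FALSE)
  # sims (0, 1, 1, 1, -) weights renorm (5,2,1,1)/9
  expect_equal(combined_score(f2, tpl), 4 / 9)
})

test_that("validity threshold comparison is inclusive", {
  expect_true(is_valid(0.80, "hard"))
  expect_false(is_valid(0.79, "hard"))
  expect_true(is_valid(0.60, "moderate"))
  expect_true(is_valid(0.40, "easy"))
  for (d in c("easy", "moderate", "hard")) expect_true(is_valid(1.0, d))
  expect_equal(difficulty_threshold("easy"), 0.40)
  expect_equal(difficulty_threshold("moderate"), 0.60)
  expect_equal(difficulty_threshold("hard"), 0.80)
})

test_that("game score increments on valid actions only", {
  expect_equal(update_game(3, TRUE), 4)
  expect_equal(update_game(3, FALSE), 3)
  expect_equal(update_game(0, TRUE), 1)
})

test_that("combined score stays in [0,1] for random convex templates", {
  set.seed(21)
  for (i in 1:30) {
    w <- stats::runif(5)
    w <- stats::setNames(w / sum(w), c("amp", "mean", "rms", "jerk",
                                       "strength"))
    refs <- stats::setNames(stats::runif(5, 0.5, 3),
                            c("amp", "mean", "rms", "jerk", "strength"))
    tpl <- reference_template("bobath_handshake", "hard", refs, weights = w)
    f <- fake_features(stats::rnorm(1, 1, 2), stats::rnorm(1, 1, 2),
                       stats::rnorm(1, 1, 2), stats::rnorm(1, 1, 2),
                       stats::rnorm(1, 1, 2))
    s <- combined_score(f, tpl)
    expect_gte(s, 0)
    expect_lte(s, 1)
    # moving any one feature onto its reference never lowers the score
    for (k in c("amp", "mean", "rms", "jerk", "strength")) {
      f2 <- f
      f2[[k]] <- refs[[k]]
      expect_gte(combined_score(f2, tpl), s - 1e-12)
    }
  }
})

test_that("a full session at reference amplitude scores perfectly", {
  st <- limb_stream(n_reps = 5)
  tpl <- template_from_reference(st, "easy")
  res <- score_session(st, tpl)
  expect_equal(res$valid_count, 5)
  expect_equal(res$game_score, 5)
  expect_equal(res$session_score, 100)
})

test_that("a degraded repetition fails the hard threshold", {
  st <- limb_stream(n_reps = 5)
  tpl <- template_from_reference(st, "hard")
  res <- score_session(degrade_repetitions(st, 2, 0.3), tpl, "hard")
  expect_equal(nrow(res$rep_results), 5)
  expect_equal(res$valid_count, 4)
  expect_false(res$rep_results$valid[2])
  expect_lt(res$rep_results$similarity[2],
            min(res$rep_results$similarity[-2]))
})

test_that("an empty stream scores zero", {
  st <- limb_stream(n_reps = 0)
  tpl <- template_from_reference(limb_stream(n_reps = 3), "easy")
  res <- score_session(st, tpl)
  expect_equal(nrow(res$rep_results), 0)
  expect_equal(res$session_score, 0)
  expect_equal(res$game_score, 0)
})

test_that("template/exercise mismatch is an error", {
  st <- limb_stream(n_reps = 2)
  tpl <- template_from_reference(
    generate_session("squat", synth_params(n_reps = 2, noise_sd = 0)),
    "easy")
  expect_error(score_session(st, tpl), "template")
})

test_that("valid count is monotone non-increasing in difficulty", {
  st <- limb_stream(n_reps = 6, noise_sd = 0.04, seed = 3)
  st <- degrade_repetitions(st, c(2, 5), 0.55)
  tpl <- template_from_reference(limb_stream(n_reps = 6), "hard")
  counts <- vapply(c("easy", "moderate", "hard"), function(d) {
    res <- score_session(st, tpl, d)
    expect_equal(res$game_score, res$valid_count)
    res$valid_count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("templates round-trip through JSON and YAML catalogs", {
  recs <- list(list(
    exercise_id = "bobath_handshake", difficulty = "hard",
    ref_features = list(amp = 2, mean = 1, rms = 1.2, jerk = 0.002,
                        strength = 0.4)))
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(recs, jpath, auto_unbox = TRUE, digits = NA)
  tj <- read_templates(jpath)[["bobath_handshake/hard"]]
  expect_s3_class(tj, "reference_template")
  expect_equal(unname(tj$weights),
               c(0.5, 0.2, 0.1, 0.1, 0.1))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(recs, ypath)
  ty <- read_templates(ypath)[["bobath_handshake/hard"]]
  expect_equal(ty$ref_features, tj$ref_features)
})
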