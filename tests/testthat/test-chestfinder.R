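test_that("three-level fit matches the exhaustive oracle", {
  set.seed(11)
  # full enumeration on short profiles
  for (n in c(3, 5, 8, 12)) {
    for (rep in 1:6) {
      p <- round(runif(n), 2)
      fit <- fit_three_levels(p)
      oracle <- brute_three_levels(p)
      expect_equal(fit$sse, oracle$sse, tolerance = 1e-10)
      expect_identical(fit$breakpoints, c(oracle$b1, oracle$b2))
    }
  }
  # longer random profiles: sse agreement
  for (rep in 1:50) {
    p <- runif(30)
    expect_equal(fit_three_levels(p)$sse, brute_three_levels(p)$sse,
                 tolerance = 1e-10)
  }
})

test_that("three-level fit handles canonical profiles and ties", {
  f <- fit_three_levels(rep(0.7, 10))
  expect_identical(f$breakpoints, c(0L, 0L))
  expect_equal(f$levels, rep(0.7, 3))
  expect_equal(f$sse, 0)
  f2 <- fit_three_levels(c(0, 0, 0, 1, 1, 1, 0, 0, 0))
  expect_identical(f2$breakpoints, c(3L, 6L))
  expect_equal(f2$levels, c(0, 1, 0))
  expect_equal(f2$sse, 0)
  expect_error(fit_three_levels(c(0.2, 0.8)), "at least 3")
  # greedy mode exists and is at least as bad as the global optimum
  p <- runif(40)
  expect_gte(fit_three_levels(p, method = "greedy")$sse,
             fit_three_levels(p)$sse - 1e-10)
})

test_that("chest interval applies the strict 0.5 rule with merging", {
  mk <- function(levels, b, n) {
    structure(list(breakpoints = b, levels = levels, sse = 0, n = n,
                   slice_offset = 0L, method = "exhaustive"),
              class = "three_level_fit")
  }
  iv <- chest_interval(mk(c(0.1, 0.9, 0.2), c(10L, 40L), 50L))
  expect_identical(c(iv$start, iv$end), c(10L, 40L))
  iv2 <- chest_interval(mk(c(0.6, 0.9, 0.2), c(10L, 40L), 50L))
  expect_identical(c(iv2$start, iv2$end), c(0L, 40L))
  iv3 <- chest_interval(mk(c(0.4, 0.5, 0.3), c(10L, 40L), 50L))
  expect_false(iv3$found) # 0.5 is not strictly above the threshold
  iv4 <- chest_interval(mk(c(0.8, 0.2, 0.7), c(10L, 40L), 50L))
  expect_true(iv4$flagged)
  # both outer segments have 10 slices; the tie goes to the first
  expect_identical(c(iv4$start, iv4$end), c(0L, 10L))
})

test_that("score_stack clips ranges and errors on empty ranges", {
  ph <- generate_phantom(phantom_spec(n_slices = 30, seed = 3))
  model <- make_tiny_classifier()
  expect_warning(pr <- score_stack(model, ph$volume, c(0L, 800L)), "clipped")
  expect_identical(nrow(pr), 30L)
  expect_identical(attr(pr, "slice_offset"), 0L)
  pr2 <- suppressWarnings(score_stack(model, ph$volume, c(10L, 20L)))
  expect_identical(pr2$slice, 10:19)
  expect_error(score_stack(model, ph$volume, c(35L, 40L)), "empty")
  # inference determinism
  p1 <- predict_chest_prob(model, ph$volume$hu[, , 5])
  p2 <- predict_chest_prob(model, ph$volume$hu[, , 5])
  expect_identical(p1, p2)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("slice classifier training contract holds", {
  expect_error(train_slice_classifier(array(0, c(16, 16, 4)), rep(1L, 4),
                                      widths = c(2L, 2L, 2L), epochs = 1L),
               "both chest and not-chest")
  ds <- phantom_classification_dataset(24, phantom_spec(), seed = 5)
  expect_true(all(ds$chest %in% 0:1) && length(unique(ds$chest)) == 2L)
  m <- train_slice_classifier(ds$images, ds$chest, widths = c(4L, 6L, 8L),
                              epochs = 3L, seed = 1)
  expect_true(all(is.finite(m$loss_history)))
  expect_lte(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("the reduced-width classifier separates chest from non-chest slices", {
  cm <- make_chest_model()
  p <- predict_chest_prob(cm$model, cm$holdout$images)
  expect_gte(mean((p > 0.5) == (cm$holdout$chest == 1)), 0.95)
})

test_that("end-to-end chest intervals land within 2 slices of ground truth", {
  cm <- make_chest_model()
  # phantoms at the default geometry, differing in their noise realisation
  phantoms <- lapply(1:4, function(s) {
    generate_phantom(phantom_spec(seed = 6000 + s))
  })
  for (ph in phantoms) {
    pr <- suppressWarnings(score_stack(cm$model, ph$volume, c(0L, 120L)))
    iv <- chest_interval(fit_three_levels(pr))
    expect_true(iv$found)
    expect_lte(abs(iv$start - ph$truth$chest_interval[1]), 2)
    expect_lte(abs(iv$end - ph$truth$chest_interval[2]), 2)
  }
})

test_that("an all-air stack is scored below threshold by a trained model", {
  cm <- make_chest_model()
  air <- array(-1000 + rnorm(64 * 64 * 10, 0, 10), c(64, 64, 10))
  expect_true(all(predict_chest_prob(cm$model, air) < 0.5))
})
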