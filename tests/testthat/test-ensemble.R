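# shared fixture: a small split plus untrained (iteration-0) models of each
# regime — deterministic scorers that exercise the full ensemble machinery
make_model_set <- function(seed = 20) {
  sp <- tiny_split(n_genera = 2, per_genus = 6, seed = seed)
  arch <- tiny_arch()
  g <- train_general(sp, arch, fast_hp(iterations = 10, seed = seed))
  specific <- list(); transfer <- list()
  for (v in mv_views()) {
    specific[[v]] <- train_specific(sp, v, arch,
                                    fast_hp(iterations = 5, seed = seed))
    transfer[[v]] <- train_transfer(g, sp, v,
                                    fast_hp(iterations = 5, seed = seed))
  }
  list(split = sp, general = g, specific = specific, transfer = transfer)
}

ms <- make_model_set()

test_that("ensemble kinds resolve to the documented member lists", {
  eg <- build_ensemble("G", general = ms$general)
  expect_equal(nrow(eg$members), 3L)
  expect_equal(eg$members$view, mv_views())
  # one weight set applied three times
  expect_identical(eg$members$model[[1]], eg$members$model[[3]])

  es <- build_ensemble("S", specific = ms$specific)
  expect_equal(nrow(es$members), 3L)
  expect_equal(unique(es$members$regime), "specific")

  eall <- build_ensemble("All", general = ms$general,
                         specific = ms$specific, transfer = ms$transfer)
  expect_equal(nrow(eall$members), 9L)
  expect_equal(table(eall$members$regime)[["general"]], 3L)

  expect_error(build_ensemble("S", specific = ms$specific[c("head", "dorsum")]),
               "specific, profile")
  expect_error(build_ensemble("G"), "general")
  expect_error(build_ensemble("T", transfer = ms$specific),
               "not a trained transfer model")
})

test_that("score aggregation sums element-wise and keeps total mass", {
  agg <- aggregate_scores(list(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3)))
  expect_equal(as.numeric(agg), c(0.8, 0.8, 0.4))
  expect_equal(attr(agg, "member_count"), 2L)
  expect_equal(top_t(as.numeric(agg), 1), 1L)  # tie -> lower index

  single <- aggregate_scores(list(c(0.5, 0.5)))
  expect_equal(as.numeric(single), c(0.5, 0.5))

  k <- aggregate_scores(rep(list(c(0.2, 0.7, 0.1)), 4))
  expect_equal(sum(k), 4, tolerance = 1e-9)
  expect_equal(top_t(as.numeric(k), 3), top_t(c(0.2, 0.7, 0.1), 3))

  expect_error(aggregate_scores(list(1:2 / 3, 1:3 / 6)), "differing lengths")
  expect_error(aggregate_scores(list()), "no score vectors")
})

test_that("specimen prediction sums member views and enforces the contract", {
  eg <- build_ensemble("G", general = ms$general)
  spec <- ms$split$test$specimens[[1]]
  pred <- predict_specimen(eg, spec, t = 2)
  # manual: the general model scores each view's image once
  manual <- Reduce(`+`, lapply(mv_views(), function(v)
    score_image(ms$general, spec$images[[v]][[1]])))
  expect_equal(pred, top_t(as.numeric(manual), 2))

  spec$images$dorsum <- list()
  expect_error(predict_specimen(eg, spec), "dorsum")
})

test_that("an ensemble of one repeated member reproduces that member", {
  # the three G members share one weight set; on a specimen whose three
  # images are identical, the ranking equals the single-model ranking
  eg <- build_ensemble("G", general = ms$general)
  img <- ms$split$test$specimens[[1]]$images$head[[1]]
  spec <- new_specimen("twin", 1L,
                       stats::setNames(rep(list(list(img)), 3), mv_views()))
  expect_equal(predict_specimen(eg, spec, 2),
               top_t(score_image(ms$general, img), 2))
})

test_that("member order does not change ensemble predictions", {
  eall <- build_ensemble("All", general = ms$general,
                         specific = ms$specific, transfer = ms$transfer)
  shuffled <- eall
  shuffled$members <- shuffled$members[rev(seq_len(nrow(shuffled$members))), ]
  spec <- ms$split$test$specimens[[1]]
  expect_equal(predict_specimen(eall, spec, 2),
               predict_specimen(shuffled, spec, 2))
})

test_that("ensemble evaluation reports per-specimen metrics, monotone in t", {
  eall <- build_ensemble("All", general = ms$general,
                         specific = ms$specific, transfer = ms$transfer)
  rep <- evaluate_ensemble(eall, ms$split$test, ts = c(1, 2))
  expect_equal(rep$ensemble, c("All", "All"))
  expect_true(all(diff(rep$accuracy) >= 0))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_error(evaluate_ensemble(eall, mv_dataset(list(), character(0))),
               "empty test set")
})

test_that("evaluation refuses specimens with extra pictures in a view", {
  eall <- build_ensemble("G", general = ms$general)
  bad <- ms$split$test
  bad$specimens[[1]]$images$head <-
    c(bad$specimens[[1]]$images$head, list(gray_img(0.1)))
  expect_error(evaluate_ensemble(eall, bad), "exactly one picture per view")
})

test_that("member correctness vectors feed the diversity report", {
  members <- list(
    g_head = list(model = ms$general, view = "head"),
    s_head = list(model = ms$specific$head, view = "head"),
    t_dorsum = list(model = ms$transfer$dorsum, view = "dorsum")
  )
  cv <- member_correctness(members, ms$split$validation, t = 1)
  expect_named(cv, names(members))
  expect_true(all(lengths(cv) == n_specimens(ms$split$validation)))
  div <- ensemble_diversity(cv, t = 1)
  expect_equal(nrow(div), 3L)
  avg <- diversity_average(div)
  expect_equal(avg$sc, avg$bc + avg$oc, tolerance = 1e-12)
})
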