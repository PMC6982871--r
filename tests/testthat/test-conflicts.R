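# oracle_winner() and random_case() live in helper-oracle.R (shared with
# the acceptance suite).

test_that("conflict detection counts main-class claimants", {
  specs <- toy_specs()
  one <- toy_outputs(specs, claim = 3, p1s = rep(0.8, 4))
  expect_false(detect_conflict(one)$conflict)
  expect_equal(detect_conflict(one)$claimants, 3L)
  two <- toy_outputs(specs, claim = c(1, 4), p1s = rep(0.8, 4))
  case <- detect_conflict(two)
  expect_true(case$conflict)
  expect_equal(case$claimants, c(1L, 4L))
  none <- toy_outputs(specs, claim = integer(), p1s = rep(0.8, 4))
  expect_equal(length(detect_conflict(none)$claimants), 0)
})

test_that("the published margin example picks the stronger model", {
  # claimant A's two largest outputs are 0.56 and 0.54 (a weak, near-tied
  # prediction); claimant B is less confident (0.48) but has a clear margin.
  # The highest-posterior rule prefers A, the margin rule B.
  specs <- toy_specs()
  outs <- list(
    make_output(1, c(m1 = 0.56, m2 = 0.54, complement = 0)),
    make_output(2, c(a1 = 0.48, complement = 0.10)), # illustrative, unnormalised
    make_output(3, c(e1 = 0.1, complement = 0.9)),
    make_output(4, c(x1 = 0.2, x2 = 0.1, complement = 0.7))
  )
  case <- detect_conflict(outs)
  expect_equal(case$claimants, c(1L, 2L))
  expect_equal(resolve_highest(case)$winner, 1L)     # 0.56 > 0.48/0.58
  expect_equal(outs[[1]]$p1 - outs[[1]]$p2, 0.02)
  expect_gt(outs[[2]]$p1 - outs[[2]]$p2, 0.02)
  expect_equal(resolve_margin(case)$winner, 2L)
})

test_that("the published class-weighting example favours the larger model", {
  # a 2-class model at 0.9 loses to an 8-class model at 0.3 (1.8 < 2.4)
  specs <- build_model_specs(ucami_restructured_counts())
  outs <- list(
    make_output(1, c(Act24 = 0.1, ActN3 = 0.1, complement = 0.8)),
    make_output(2, c(ActN4 = 0.9, complement = 0.1)),
    make_output(3, c(Act23 = 0.1, ActN5 = 0.1, complement = 0.8)),
    make_output(4, stats::setNames(c(0.3, rep(0.075, 6), 0.25),
                                   c(specs[[4]]$main_classes, complement_token())))
  )
  case <- detect_conflict(outs)
  expect_equal(case$claimants, c(2L, 4L))
  dec <- resolve_class_weighted(case, specs)
  expect_equal(dec$winner, 4L)
  expect_equal(unname(dec$scores), c(0.9 * 2, 0.3 * 8))
  # the unweighted rule prefers the confident small model
  expect_equal(resolve_highest(case)$winner, 2L)
})

test_that("accuracy weighting breaks ties between equal posteriors", {
  specs <- toy_specs()
  outs <- toy_outputs(specs, claim = c(1, 3), p1s = c(0.8, 0.7, 0.8, 0.7))
  models <- list(list(train_accuracy = 0.9), NULL, list(train_accuracy = 0.6), NULL)
  # m_1 = 3, m_3 = 2: scores 0.8*3*0.9 = 2.16 vs 0.8*2*0.6 = 0.96
  dec <- resolve_acc_weighted(detect_conflict(outs), specs, models)
  expect_equal(dec$winner, 1L)
  # equal everything: lowest model index wins
  models_eq <- list(list(train_accuracy = 0.7), NULL, list(train_accuracy = 0.7), NULL)
  specs_eq <- specs
  specs_eq[[1]]$m <- 2L; specs_eq[[3]]$m <- 2L
  dec_eq <- resolve_acc_weighted(detect_conflict(outs), specs_eq, models_eq)
  expect_equal(dec_eq$winner, 1L)
  expect_error(resolve_acc_weighted(detect_conflict(outs), specs, NULL), "train")
})

test_that("resolvers agree with the brute-force oracle on random cases", {
  specs <- toy_specs()
  models <- lapply(1:4, function(j) list(train_accuracy = 0.5 + 0.1 * j))
  set.seed(100)
  for (rep in 1:400) {
    n_claim <- sample(2:3, 1)
    case <- random_case(specs, n_claim)
    if (length(case$claimants) < 2) next
    for (strategy in c("alg2", "alg3", "alg4", "alg5")) {
      got <- switch(strategy,
        alg2 = resolve_highest(case),
        alg3 = resolve_margin(case),
        alg4 = resolve_class_weighted(case, specs),
        alg5 = resolve_acc_weighted(case, specs, models))
      expect_identical(got$winner, oracle_winner(case, strategy, specs, models))
      expect_true(got$y %in% specs[[got$winner]]$main_classes)
    }
  }
})

test_that("limit equivalences hold: alg4 -> alg2 for equal m, alg5 -> alg4 for equal accuracy", {
  specs <- toy_specs()
  specs_eqm <- lapply(specs, function(s) { s$m <- 3L; s })
  models_eqa <- lapply(1:4, function(j) list(train_accuracy = 0.8))
  set.seed(200)
  for (rep in 1:200) {
    case <- random_case(specs, sample(2:4, 1))
    if (length(case$claimants) < 2) next
    expect_identical(resolve_class_weighted(case, specs_eqm)$winner,
                     resolve_highest(case)$winner)
    expect_identical(resolve_acc_weighted(case, specs, models_eqa)$winner,
                     resolve_class_weighted(case, specs)$winner)
  }
})

test_that("decide() routes single claimants, conflicts and fallback", {
  specs <- toy_specs()
  single <- toy_outputs(specs, claim = 3, p1s = rep(0.8, 4))
  d1 <- decide(single, specs, strategy = "alg2")
  expect_equal(d1$route, "single_claimant")
  expect_equal(d1$y, specs[[3]]$main_classes[1])
  conflict <- toy_outputs(specs, claim = c(1, 2), p1s = c(0.6, 0.9, 0.7, 0.7))
  d2 <- decide(conflict, specs, strategy = "alg2")
  expect_equal(d2$route, "resolved_alg2")
  expect_equal(d2$winner, 2L)
  none <- toy_outputs(specs, claim = integer(), p1s = c(0.6, 0.55, 0.9, 0.7))
  d3 <- decide(none, specs, strategy = "alg3")
  expect_equal(d3$route, "fallback_no_claimant")
  # fallback picks the largest main-class probability over all models,
  # which can never be the complement token
  expect_false(d3$y == complement_token())
  best <- which.max(vapply(none, function(o) {
    max(o$probabilities[names(o$probabilities) != complement_token()])
  }, 0))
  expect_equal(d3$winner, best)
  # exact score ties resolve to the lowest model index
  tie <- toy_outputs(specs, claim = c(2, 3), p1s = c(0.5, 0.7, 0.7, 0.5))
  expect_equal(decide(tie, specs, strategy = "alg2")$winner, 2L)
})

test_that("the final label is never the complement token over a simulated batch", {
  sim <- small_sim()
  specs <- build_model_specs(sim$catalog)
  ens <- suppressWarnings(train_ensemble(sim$data, specs, "class_level",
                                         fast_control(), seed = 6))
  for (strategy in c("alg2", "alg3", "alg4", "alg5")) {
    log <- decide_batch(ens, sim$data$X[1:60, ], strategy)
    expect_false(any(log$y == complement_token()))
    expect_true(all(log$route %in% c("single_claimant", "fallback_no_claimant",
                                     paste0("resolved_", strategy))))
  }
})
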