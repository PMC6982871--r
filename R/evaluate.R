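# Evaluation harness. Mirrors the published accounting: per-fold conflict
# counts, the split of errors into "incorrect" (the target model — the one
# whose main classes contain the truth — got it wrong, so no resolution rule
# could save it) and "right but incorrect" (the target model predicted the
# truth but lost the final decision), and accuracy per resolution strategy.
# "Folds" are independent repetitions — fresh split, complement sample and
# network initialisation — not cross-validation partitions.

#' Target base model of a class
#'
#' @param class_id Activity class id.
#' @param specs The 4 `base_model_spec`s.
#' @return Index of the unique model whose main classes contain `class_id`.
#' @export
target_model_of <- function(class_id, specs) {
  hit <- which(vapply(specs, function(s) class_id %in% s$main_classes, TRUE))
  if (length(hit) != 1) stop("class ", class_id, " maps to ", length(hit), " models")
  hit
}

#' Verdict for one classified instance
#'
#' `correct` if the final decision equals the truth; otherwise
#' `right_but_incorrect` when the target model had predicted the truth but
#' lost the decision, else `incorrect` (the target model itself was wrong,
#' so the case was unwinnable by any resolution rule).
#'
#' @param final_y Final decided class.
#' @param target_pred The target model's predicted class (`k_hat`).
#' @param truth True class.
#' @return One of `"correct"`, `"incorrect"`, `"right_but_incorrect"`.
#' @export
classify_case <- function(final_y, target_pred, truth) {
  if (final_y == truth) return("correct")
  if (target_pred == truth) return("right_but_incorrect")
  "incorrect"
}

#' Proportion of correct decisions
#'
#' @param decisions Character vector of decided classes.
#' @param truths Character vector of true classes, same length.
#' @return Fraction equal, in \[0, 1\].
#' @export
accuracy <- function(decisions, truths) {
  if (length(decisions) == 0) stop("empty decision vector")
  stopifnot(length(decisions) == length(truths))
  mean(decisions == truths)
}

#' One evaluation fold
#'
#' Splits the data, trains the ensemble under `scheme`, classifies the test
#' set under every requested strategy and tallies the accounting.
#'
#' @param data `har_dataset` over the full catalogue.
#' @param catalog `class_counts` catalogue (for the model partition).
#' @param scheme Complement scheme, `"class_level"` or `"model_level"`.
#' @param strategies Character vector of strategies (default all four).
#' @param control [mlp_control()] record.
#' @param seed Integer seed for this fold (split, sampling, initialisation).
#' @param test_fraction Held-out proportion (default 0.15).
#' @return A `fold_result`: list with `conflicts`, `n_test`,
#'   `baseline_accuracy` (all conflict cases scored wrong) and `per_strategy`
#'   (data frame: strategy, accuracy, incorrect, right_but_incorrect,
#'   correct).
#' @export
evaluate_fold <- function(data, catalog, scheme = c("class_level", "model_level"),
                          strategies = .STRATEGIES, control = mlp_control(),
                          seed = 0, test_fraction = 0.15) {
  scheme <- match.arg(scheme)
  specs <- build_model_specs(catalog)
  sp <- split_train_test(data, test_fraction, seed = derive_seed(seed, 1))
  ens <- train_ensemble(sp$train, specs, scheme = scheme, control = control,
                        seed = derive_seed(seed, 2))
  test <- sp$test
  probs <- ensemble_probabilities(ens, test$X)
  target <- vapply(test$y, target_model_of, 1L, specs = specs)

  n <- test$n
  n_claim <- integer(n)
  target_pred <- character(n)
  outputs_list <- vector("list", n)
  for (i in seq_len(n)) {
    outs <- outputs_at(ens, probs, i)
    outputs_list[[i]] <- outs
    n_claim[i] <- length(detect_conflict(outs)$claimants)
    target_pred[i] <- outs[[target[i]]]$k_hat
  }
  conflict <- n_claim >= 2

  per <- lapply(strategies, function(strategy) {
    y_hat <- vapply(seq_len(n), function(i) {
      decide(outputs_list[[i]], specs, ens$models, strategy)$y
    }, "")
    verdict <- vapply(seq_len(n), function(i) {
      classify_case(y_hat[i], target_pred[i], test$y[i])
    }, "")
    data.frame(strategy = strategy,
               accuracy = accuracy(y_hat, test$y),
               correct = sum(verdict == "correct"),
               incorrect = sum(verdict == "incorrect"),
               right_but_incorrect = sum(verdict == "right_but_incorrect"),
               stringsAsFactors = FALSE)
  })
  # Baseline: resolution withheld, every conflict case scored as an error.
  y_nores <- vapply(seq_len(n), function(i) {
    if (conflict[i]) return("__conflict__")
    decide(outputs_list[[i]], specs, ens$models, "alg2")$y
  }, "")
  structure(list(seed = seed, scheme = scheme,
                 conflicts = sum(conflict), n_test = n,
                 baseline_accuracy = accuracy(y_nores, test$y),
                 per_strategy = do.call(rbind, per),
                 ensemble = ens),
            class = "fold_result")
}

#' Repeated-fold experiment
#'
#' Runs `folds` independent repetitions (fresh split, complement sample and
#' network seeds derived from `seed`) for each requested complement scheme
#' and reports per-fold rows plus averages, in the layout of the published
#' conflict and incorrect/right-but-incorrect tables.
#'
#' @inheritParams evaluate_fold
#' @param schemes Character vector of complement schemes to compare.
#' @param folds Number of repetitions (default 10).
#' @param seed Base seed; fold k uses a seed derived from `(seed, k)`.
#' @return A `har_experiment`: list with `results` (long data frame: scheme,
#'   fold, strategy, conflicts, accuracy, baseline_accuracy, incorrect,
#'   right_but_incorrect) and `summary` (averages per scheme x strategy).
#' @export
run_experiment <- function(data, catalog,
                           schemes = c("class_level", "model_level"),
                           strategies = .STRATEGIES,
                           folds = 10, seed = 0, control = mlp_control(),
                           test_fraction = 0.15) {
  stopifnot(folds >= 1)
  rows <- list()
  for (scheme in schemes) {
    for (k in seq_len(folds)) {
      fr <- evaluate_fold(data, catalog, scheme = scheme,
                          strategies = strategies, control = control,
                          seed = derive_seed(seed, k), test_fraction = test_fraction)
      df <- fr$per_strategy
      df$scheme <- scheme
      df$fold <- k
      df$conflicts <- fr$conflicts
      df$baseline_accuracy <- fr$baseline_accuracy
      df$n_test <- fr$n_test
      rows[[length(rows) + 1]] <- df
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[, c("conflicts", "accuracy", "baseline_accuracy",
                "incorrect", "right_but_incorrect")],
    by = list(scheme = results$scheme, strategy = results$strategy), mean)
  structure(list(results = results, summary = summary, folds = folds,
                 seed = seed),
            class = "har_experiment")
}

#' @export
print.har_experiment <- function(x, ...) {
  cat("<har_experiment> ", x$folds, " folds\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Standard synthetic benchmark
#'
#' The package's stock end-to-end experiment: a fresh simulated home per
#' seed (12-class catalogue, class imbalance, shared sensors, noise), one
#' evaluation fold per seed and complement scheme. Sized for a single CPU:
#' 6 simulated days and a reduced network (16 hidden units, 120 epochs);
#' the simulated world itself is the paper-like default.
#'
#' @param n_seeds Number of independent seeds (default 20).
#' @param seed Base seed.
#' @param config `sim_config` to simulate from (default
#'   `default_sim_config("paper_like", days = 6)`).
#' @param control Network hyperparameters (default reduced, see above).
#' @param schemes Complement schemes to compare.
#' @return A long data frame: one row per seed x scheme x strategy with
#'   `conflicts`, `accuracy`, `baseline_accuracy`, `incorrect`,
#'   `right_but_incorrect`.
#' @export
run_benchmark <- function(n_seeds = 20, seed = 0, config = NULL,
                          control = mlp_control(hidden = 16, epochs = 120),
                          schemes = c("class_level", "model_level")) {
  if (is.null(config)) config <- default_sim_config("paper_like", days = 6)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    sim_seed <- derive_seed(seed, 1000 + s)
    ds <- simulate_dataset(config, seed = sim_seed)
    for (scheme in schemes) {
      fr <- evaluate_fold(ds$data, ds$catalog, scheme = scheme,
                          control = control, seed = derive_seed(seed, 2000 + s))
      df <- fr$per_strategy
      df$scheme <- scheme
      df$seed_index <- s
      df$conflicts <- fr$conflicts
      df$baseline_accuracy <- fr$baseline_accuracy
      df$n_test <- fr$n_test
      rows[[length(rows) + 1]] <- df
    }
  }
  do.call(rbind, rows)
}
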