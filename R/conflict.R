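# Conflict detection and resolution. A model "claims" an instance when its
# predicted class is one of its own main classes (predicting the complement
# is self-elimination). A conflict exists when two or more models claim the
# same instance; four rules resolve it, each reducible to an argmax of a
# per-claimant score:
#   rule 2 (highest):        p1
#   rule 3 (margin):         p1 - p2
#   rule 4 (class-weighted): p1 * m_j
#   rule 5 (acc-weighted):   p1 * m_j * train_accuracy_j
# The pairwise if/else forms generalise to >= 3 claimants as the argmax of
# the same score; ties go to the lowest model index. The final label is
# always a main class of the winning model, never the complement token.

.STRATEGIES <- c("alg2", "alg3", "alg4", "alg5")

#' Detect a conflict among base-model outputs
#'
#' @param outputs List of `base_model_output`s, one per model, in index
#'   order.
#' @return A `conflict_case`: list with `claimants` (model indices asserting
#'   a main class), `conflict` (`TRUE` iff at least two claimants) and
#'   `outputs`.
#' @export
detect_conflict <- function(outputs) {
  claimants <- which(vapply(outputs, `[[`, TRUE, "is_main"))
  structure(list(claimants = claimants,
                 conflict = length(claimants) >= 2,
                 outputs = outputs),
            class = "conflict_case")
}

# Score of one claimant output under a strategy. `m` and `acc` are the
# output count and training accuracy of the claimant's model.
claimant_score <- function(out, strategy, m = NULL, acc = NULL) {
  switch(strategy,
    alg2 = out$p1,
    alg3 = out$p1 - out$p2,
    alg4 = out$p1 * m,
    alg5 = out$p1 * m * acc,
    stop("unknown strategy: ", strategy)
  )
}

resolve_generic <- function(case, strategy, specs = NULL, models = NULL) {
  stopifnot(length(case$claimants) >= 2)
  scores <- vapply(case$claimants, function(j) {
    out <- case$outputs[[j]]
    m <- if (!is.null(specs)) specs[[j]]$m
    acc <- if (strategy == "alg5") {
      if (is.null(models)) stop("strategy alg5 needs trained models (train accuracy)")
      models[[j]]$train_accuracy
    }
    claimant_score(out, strategy, m = m, acc = acc)
  }, 0)
  winner <- case$claimants[which.max(scores)] # first max => lowest index ties
  structure(list(y = case$outputs[[winner]]$k_hat,
                 winner = winner,
                 route = paste0("resolved_", strategy),
                 scores = stats::setNames(scores, case$claimants)),
            class = "final_decision")
}

#' Resolve a conflict by the highest posterior (rule 2)
#' @param case A `conflict_case` with at least two claimants.
#' @return A `final_decision` (`y`, `winner`, `route`, `scores`).
#' @export
resolve_highest <- function(case) resolve_generic(case, "alg2")

#' Resolve a conflict by the posterior margin (rule 3)
#'
#' The winner is the claimant with the largest difference between its
#' highest and second-highest output probabilities — the model with the
#' strongest class prediction. The second-highest is taken over the full
#' output vector, complement included.
#'
#' @inheritParams resolve_highest
#' @return A `final_decision`.
#' @export
resolve_margin <- function(case) resolve_generic(case, "alg3")

#' Resolve a conflict by class-count weighting (rule 4)
#'
#' Each claimant's top probability is multiplied by the number of classes of
#' its model (`m_j`): a model solving a harder, many-class problem gets a
#' proportionally higher weight.
#'
#' @inheritParams resolve_highest
#' @param specs The 4 `base_model_spec`s.
#' @return A `final_decision`.
#' @export
resolve_class_weighted <- function(case, specs) resolve_generic(case, "alg4", specs = specs)

#' Resolve a conflict by class-count and training-accuracy weighting (rule 5)
#'
#' As rule 4, additionally multiplied by each claimant model's training
#' accuracy.
#'
#' @inheritParams resolve_class_weighted
#' @param models The 4 `trained_base_model`s (for `train_accuracy`).
#' @return A `final_decision`.
#' @export
resolve_acc_weighted <- function(case, specs, models) {
  resolve_generic(case, "alg5", specs = specs, models = models)
}

#' Final decision for one instance
#'
#' Routes: a single claimant wins outright; two or more claimants go to the
#' chosen resolution rule; if no model claims the instance, the fallback
#' picks the largest main-class probability across all models (complement
#' entries excluded), so the final label is always a real activity class.
#'
#' @param outputs List of `base_model_output`s, one per model.
#' @param specs The 4 `base_model_spec`s.
#' @param models The 4 `trained_base_model`s (required for `"alg5"`).
#' @param strategy One of `"alg2"`, `"alg3"`, `"alg4"`, `"alg5"`.
#' @return A `final_decision` with `route` one of `single_claimant`,
#'   `resolved_alg2..5`, `fallback_no_claimant`.
#' @export
decide <- function(outputs, specs, models = NULL,
                   strategy = c("alg2", "alg3", "alg4", "alg5")) {
  strategy <- match.arg(strategy)
  case <- detect_conflict(outputs)
  nc <- length(case$claimants)
  if (nc == 1) {
    j <- case$claimants
    return(structure(list(y = outputs[[j]]$k_hat, winner = j,
                          route = "single_claimant", scores = NULL),
                     class = "final_decision"))
  }
  if (nc == 0) {
    best_j <- 0L; best_p <- -Inf; best_cl <- NA_character_
    for (j in seq_along(outputs)) {
      pr <- outputs[[j]]$probabilities
      pr <- pr[names(pr) != complement_token()]
      k <- which.max(pr)
      if (pr[k] > best_p) { best_p <- pr[k]; best_j <- j; best_cl <- names(pr)[k] }
    }
    return(structure(list(y = best_cl, winner = best_j,
                          route = "fallback_no_claimant", scores = NULL),
                     class = "final_decision"))
  }
  switch(strategy,
    alg2 = resolve_highest(case),
    alg3 = resolve_margin(case),
    alg4 = resolve_class_weighted(case, specs),
    alg5 = resolve_acc_weighted(case, specs, models)
  )
}

#' Batch decisions with a per-instance log
#'
#' @param ensemble A `har_ensemble`.
#' @param X Feature matrix of instances to classify.
#' @param strategy Resolution strategy (see [decide()]).
#' @return A data frame log: `instance`, `n_claimants`, `claimants`
#'   (comma-separated model indices), `route`, `winner`, `y`.
#' @export
decide_batch <- function(ensemble, X, strategy = c("alg2", "alg3", "alg4", "alg5")) {
  strategy <- match.arg(strategy)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  probs <- ensemble_probabilities(ensemble, X)
  n <- nrow(X)
  log <- data.frame(instance = seq_len(n), n_claimants = 0L,
                    claimants = "", route = "", winner = 0L, y = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    outs <- outputs_at(ensemble, probs, i)
    case <- detect_conflict(outs)
    dec <- decide(outs, ensemble$specs, ensemble$models, strategy)
    log$n_claimants[i] <- length(case$claimants)
    log$claimants[i] <- paste(case$claimants, collapse = ",")
    log$route[i] <- dec$route
    log$winner[i] <- dec$winner
    log$y[i] <- dec$y
  }
  log
}
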