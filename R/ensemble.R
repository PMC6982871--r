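# Base-model training and the per-instance support functions. Each base
# model is a shallow network over its main classes plus the complement
# class; its output vector is the support function fused at integration
# time. p1 is the largest output probability, p2 the second largest
# (complement included), and the predicted class is the argmax with ties
# broken toward the lowest class index.

#' Train one base model
#'
#' @param spec A `base_model_spec`.
#' @param main_data `har_dataset` whose labels are all main classes of
#'   `spec`; every main class must be represented.
#' @param complement_data `har_dataset` labelled with [complement_token()]
#'   (as produced by [sample_complement()]).
#' @param control A [mlp_control()] record.
#' @param seed Integer seed (weight initialisation).
#' @return A `trained_base_model`: `spec`, `fit`, `train_accuracy`,
#'   `classes` (main classes in catalogue order, complement last).
#' @export
train_base_model <- function(spec, main_data, complement_data,
                             control = mlp_control(), seed = 0) {
  bad <- setdiff(unique(main_data$y), spec$main_classes)
  if (length(bad) > 0) {
    stop("main data contains non-main class(es): ", paste(bad, collapse = ", "))
  }
  absent <- setdiff(spec$main_classes, unique(main_data$y))
  if (length(absent) > 0) {
    stop("main class(es) with zero training instances: ", paste(absent, collapse = ", "))
  }
  if (!all(complement_data$y == complement_token())) {
    stop("complement data must be labelled with the complement token")
  }
  X <- rbind(main_data$X, complement_data$X)
  classes <- c(spec$main_classes, complement_token())
  y <- factor(c(main_data$y, complement_data$y), levels = classes)
  fit <- mlp_fit(X, y, control = control, seed = seed)
  P <- predict(fit, X)
  pred <- classes[max.col(P, ties.method = "first")]
  structure(list(spec = spec, fit = fit, classes = classes,
                 train_accuracy = mean(pred == as.character(y)),
                 control = control, seed = seed),
            class = "trained_base_model")
}

#' @export
print.trained_base_model <- function(x, ...) {
  cat("<trained_base_model> M", x$spec$index, " (", x$spec$name, "), m = ",
      x$spec$m, ", train accuracy = ", sprintf("%.3f", x$train_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Support-function output of a base model for one instance
#'
#' @param model A `trained_base_model`.
#' @param x Feature vector with the training dimensionality.
#' @return A `base_model_output`: `index`, `probabilities` (named, sums to
#'   1), `p1`, `p2`, `k_hat` (argmax class, possibly the complement token),
#'   `is_main` (`TRUE` iff `k_hat` is a main class).
#' @export
predict_base <- function(model, x) {
  P <- predict(model$fit, x)
  base_output_from_probs(model$spec$index, P[1, ], model$classes)
}

base_output_from_probs <- function(index, probs, classes) {
  probs <- stats::setNames(as.numeric(probs), classes)
  k <- which.max(probs) # first max => lowest class index on ties
  sorted <- sort(probs, decreasing = TRUE)
  structure(list(index = index,
                 probabilities = probs,
                 p1 = unname(sorted[1]),
                 p2 = if (length(sorted) > 1) unname(sorted[2]) else 0,
                 k_hat = classes[k],
                 is_main = classes[k] != complement_token()),
            class = "base_model_output")
}

#' Outputs of all base models for one instance
#'
#' @param models List of 4 `trained_base_model`s (index order).
#' @param x Feature vector.
#' @return List of 4 `base_model_output`s, ordered by model index.
#' @export
predict_all <- function(models, x) {
  lapply(models, predict_base, x = x)
}

#' Train the full ensemble
#'
#' Splits the training data into each model's main-class slice, computes the
#' complement allocation from the realised training counts under the chosen
#' scheme, samples each complement, and trains the four base networks. Seeds
#' for complement sampling and for each network are derived deterministically
#' from `seed`.
#'
#' @param train `har_dataset` of training instances over the full catalogue.
#' @param specs The 4 `base_model_spec`s (see [build_model_specs()]).
#' @param scheme Complement generation scheme: `"class_level"` (default) or
#'   `"model_level"`.
#' @param control A [mlp_control()] record.
#' @param seed Integer base seed.
#' @return A `har_ensemble`: list with `models`, `specs`, `scheme`,
#'   `allocations`, `seed`.
#' @export
train_ensemble <- function(train, specs, scheme = c("class_level", "model_level"),
                           control = mlp_control(), seed = 0) {
  scheme <- match.arg(scheme)
  classes <- unlist(lapply(specs, `[[`, "main_classes"))
  counts <- dataset_counts(train, classes)
  allocations <- list()
  models <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    alloc <- complement_allocation_for(spec, specs, counts, scheme)
    comp <- sample_complement(alloc, train, seed = derive_seed(seed, 100 + j))
    main <- dataset_slice(train, which(train$y %in% spec$main_classes))
    models[[j]] <- train_base_model(spec, main, comp, control = control,
                                    seed = derive_seed(seed, 200 + j))
    allocations[[spec$name]] <- alloc
  }
  structure(list(models = models, specs = specs, scheme = scheme,
                 allocations = allocations, seed = seed),
            class = "har_ensemble")
}

#' @export
print.har_ensemble <- function(x, ...) {
  cat("<har_ensemble> 4 base models, complement scheme = ", x$scheme, "\n", sep = "")
  for (m in x$models) print(m)
  invisible(x)
}

# Probability matrices of every base model over a feature matrix; the
# per-instance outputs used by the decision loop are built from these.
ensemble_probabilities <- function(ensemble, X) {
  lapply(ensemble$models, function(m) predict(m$fit, X))
}

# Outputs of all models for row i of precomputed probability matrices.
outputs_at <- function(ensemble, probs, i) {
  lapply(seq_along(ensemble$models), function(j) {
    base_output_from_probs(j, probs[[j]][i, ], ensemble$models[[j]]$classes)
  })
}
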