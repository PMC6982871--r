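# Shared fixtures, all built in code.

# Two-sensor toy registry.
toy_registry <- function() {
  load_registry(paste(
    "sensor_id,object,type,states",
    "D01,Refrigerator,Contact,Open/Close",
    "C14,Bed,Pressure,Pressure/No pressure",
    sep = "\n"
  ))
}

# Hand-built base-model output from a named probability vector.
make_output <- function(index, probs) {
  harensemble:::base_output_from_probs(index, probs, names(probs))
}

# Four toy model specs over 6 classes: Morning {m1,m2}, Afternoon {a1},
# Evening {e1}, Mixed {x1,x2}; m = (3, 2, 2, 3).
toy_specs <- function() {
  catalog <- data.frame(
    class_id = c("m1", "m2", "a1", "e1", "x1", "x2"),
    name = c("m1", "m2", "a1", "e1", "x1", "x2"),
    count = c(10, 20, 30, 15, 25, 25),
    routines = c("M", "M", "A", "E", "M;E", "A;E"),
    stringsAsFactors = FALSE
  )
  build_model_specs(structure(catalog, class = c("class_counts", "data.frame")))
}

# Outputs for the 4 toy models where `claim` lists the models that assert
# their FIRST main class with top probability p1s[j]; the others put p1s[j]
# on the complement. The remaining mass is spread over the other outputs,
# slightly tilted so p2 is unambiguous.
toy_outputs <- function(specs, claim, p1s) {
  lapply(seq_along(specs), function(j) {
    spec <- specs[[j]]
    classes <- c(spec$main_classes, complement_token())
    m <- length(classes)
    p1 <- p1s[j]
    rest <- (1 - p1) * rev(seq_len(m - 1)) / sum(seq_len(m - 1))
    top <- if (j %in% claim) 1L else m
    probs <- numeric(m)
    probs[top] <- p1
    probs[-top] <- rest
    make_output(j, stats::setNames(probs, classes))
  })
}

# Small linearly separable dataset: each class activates its own sensor
# block. `d` total features, last one is the routine code.
separable_dataset <- function(n_per_class = 30, classes = c("A", "B"), d = 5,
                              seed = 1) {
  set.seed(seed)
  X <- NULL; y <- character()
  for (k in seq_along(classes)) {
    block <- matrix(0, n_per_class, d)
    block[, k] <- 1
    block[, d] <- stats::runif(n_per_class, 0, 1) # uninformative routine-ish
    X <- rbind(X, block)
    y <- c(y, rep(classes[k], n_per_class))
  }
  colnames(X) <- c(paste0("S", seq_len(d - 1)), "routine")
  har_dataset(X, y)
}

# Fast network hyperparameters for tests.
fast_control <- function() mlp_control(hidden = 8, epochs = 80)

# Cached small simulated dataset shared across test files.
small_sim <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache)) {
      cache <<- simulate_dataset(default_sim_config("small"), seed = seed)
    }
    cache
  }
})
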