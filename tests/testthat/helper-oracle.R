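# Independent brute-force oracle for conflict resolution: enumerate every
# claimant and take the maximum of the published comparison expression
# directly (what the pairwise if/else computes for two models), independent
# of the package's resolver code path.
oracle_winner <- function(case, strategy, specs = NULL, models = NULL) {
  best <- NULL; best_score <- -Inf
  for (j in case$claimants) {
    out <- case$outputs[[j]]
    score <- switch(strategy,
      alg2 = out$p1,
      alg3 = out$p1 - out$p2,
      alg4 = out$p1 * specs[[j]]$m,
      alg5 = out$p1 * specs[[j]]$m * models[[j]]$train_accuracy)
    if (score > best_score) { best_score <- score; best <- j }
  }
  best
}

# Random claimant outputs over a spec list: models in `claim` put their top
# probability mass on one of their main classes, the rest on the complement.
random_case <- function(specs, n_claim) {
  claim <- sort(sample(seq_along(specs), n_claim))
  outs <- lapply(seq_along(specs), function(j) {
    classes <- c(specs[[j]]$main_classes, complement_token())
    m <- length(classes)
    w <- -log(runif(m))
    p <- w / sum(w)
    top <- if (j %in% claim) sample.int(m - 1, 1) else m
    k <- which.max(p)
    tmp <- p[top]; p[top] <- p[k]; p[k] <- tmp
    make_output(j, stats::setNames(p, classes))
  })
  detect_conflict(outs)
}
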