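# Base-model class partitions and complement-class allocation. The ensemble
# partitions the activity catalogue into four base models by time routine:
# classes occurring only in the morning go to the Morning model, likewise
# Afternoon and Evening, and every multi-routine class goes to the Mixed
# model. Each model is additionally trained on one catch-all "complement"
# class sampled from all classes outside the model, so that it can eliminate
# itself from decisions it should not take part in.

.COMPLEMENT <- "complement"

#' Complement-class token
#'
#' The reserved label under which sampled out-of-model instances are pooled
#' during base-model training.
#'
#' @return The string `"complement"`.
#' @export
complement_token <- function() .COMPLEMENT

#' Build the four base-model specifications
#'
#' @param catalog A `class_counts` data frame (columns `class_id`,
#'   `routines`; `;`-separated routine tags M/A/E) — typically
#'   [ucami_restructured_counts()] or a synthetic catalogue.
#' @return List of 4 `base_model_spec` objects (Morning, Afternoon, Evening,
#'   Mixed), each with fields `index`, `name`, `main_classes`,
#'   `complement_classes`, `m` (`= length(main_classes) + 1`).
#' @examples
#' specs <- build_model_specs(ucami_restructured_counts())
#' vapply(specs, `[[`, 1L, "m")   # 3 2 3 8
#' @export
build_model_specs <- function(catalog) {
  rt <- strsplit(catalog$routines, ";", fixed = TRUE)
  tag <- vapply(rt, function(r) {
    r <- sort(unique(r))
    if (identical(r, "M")) "Morning"
    else if (identical(r, "A")) "Afternoon"
    else if (identical(r, "E")) "Evening"
    else "Mixed"
  }, "")
  all_classes <- catalog$class_id
  specs <- lapply(seq_along(c("Morning", "Afternoon", "Evening", "Mixed")), function(j) {
    name <- c("Morning", "Afternoon", "Evening", "Mixed")[j]
    main <- all_classes[tag == name]
    structure(list(index = j, name = name,
                   main_classes = main,
                   complement_classes = setdiff(all_classes, main),
                   m = length(main) + 1L),
              class = "base_model_spec")
  })
  empty <- vapply(specs, function(s) length(s$main_classes) == 0, TRUE)
  if (any(empty)) {
    stop("no class assigned to base model(s): ",
         paste(vapply(specs[empty], `[[`, "", "name"), collapse = ", "))
  }
  if (!setequal(unlist(lapply(specs, `[[`, "main_classes")), all_classes)) {
    stop("class assigned to no base model")
  }
  specs
}

#' @export
print.base_model_spec <- function(x, ...) {
  cat("<base_model_spec> M", x$index, " (", x$name, "): ",
      length(x$main_classes), " main classes + complement, m = ", x$m, "\n",
      sep = "")
  invisible(x)
}

#' Average number of main-class training instances of a base model
#'
#' The complement-class budget for a model: the arithmetic mean of its main
#' classes' training-pool counts. Counts may be fractional (e.g. an 85%
#' training share of the catalogue counts).
#'
#' @param spec A `base_model_spec`.
#' @param train_counts Named numeric vector of per-class training counts.
#' @return The mean count (numeric scalar).
#' @export
average_main_instances <- function(spec, train_counts) {
  if (length(spec$main_classes) == 0) stop("base model has no main classes")
  missing <- setdiff(spec$main_classes, names(train_counts))
  if (length(missing) > 0) {
    stop("main class(es) missing from training counts: ", paste(missing, collapse = ", "))
  }
  mean(train_counts[spec$main_classes])
}

#' Class-level complement allocation
#'
#' Balances the complement-class data equally between the remaining classes:
#' the model's average main-class count is divided by the number of donor
#' classes and multiplied by 2 (the doubling gives each donor class a firmer
#' representation); the result is rounded half-up to an integer count that is
#' identical for every donor class.
#'
#' @param avg Average main-class training count of the receiving model.
#' @param remaining_classes Character vector of donor class ids (the
#'   receiving model's complement classes).
#' @param donor_specs Optional list of `base_model_spec` for the donor
#'   models, used to report per-model subtotals.
#' @return A `complement_allocation`: list with `scheme`, `per_class` (named
#'   integer vector, uniform), `per_class_raw` (the pre-rounding value),
#'   `per_model` (named subtotals, if `donor_specs` given) and `total`.
#' @examples
#' a <- allocate_class_level(74, paste0("K", 1:10))
#' a$per_class_raw   # 14.8
#' a$per_class[[1]]  # 15
#' @export
allocate_class_level <- function(avg, remaining_classes, donor_specs = NULL) {
  stopifnot(avg > 0, length(remaining_classes) > 0)
  raw <- 2 * avg / length(remaining_classes)
  per <- as.integer(round_half_up(raw))
  if (per == 0) warning("degenerate class-level allocation: 0 instances per donor class")
  per_class <- stats::setNames(rep(per, length(remaining_classes)), remaining_classes)
  structure(list(scheme = "class_level",
                 per_class = per_class,
                 per_class_raw = raw,
                 per_model = allocation_subtotals(per_class, donor_specs),
                 total = sum(per_class)),
            class = "complement_allocation")
}

#' Model-level complement allocation
#'
#' Balances the complement-class data equally between the remaining models:
#' the receiving model's average main-class count (floored to an integer
#' total) is apportioned across the donor models by largest remainder, and
#' each model's share is then split across its main classes, again by
#' largest remainder. Uniform across models, generally non-uniform across
#' classes — the structural weakness that inflates conflicts relative to the
#' class-level scheme.
#'
#' @param avg_total Average main-class training count of the receiving model.
#' @param remaining_specs List of `base_model_spec` for the donor models.
#' @return A `complement_allocation` with per-class counts, per-model
#'   subtotals and the integer `total`.
#' @examples
#' specs <- build_model_specs(ucami_restructured_counts())
#' allocate_model_level(73.525, specs[-1])$per_model  # 24 24 25
#' @export
allocate_model_level <- function(avg_total, remaining_specs) {
  stopifnot(length(remaining_specs) > 0)
  total <- as.integer(floor(avg_total))
  model_names <- vapply(remaining_specs, `[[`, "", "name")
  shares <- largest_remainder(total, length(remaining_specs))
  per_class <- integer(0)
  for (k in seq_along(remaining_specs)) {
    cls <- remaining_specs[[k]]$main_classes
    cl_shares <- largest_remainder(shares[k], length(cls))
    per_class <- c(per_class, stats::setNames(cl_shares, cls))
  }
  structure(list(scheme = "model_level",
                 per_class = per_class,
                 per_model = stats::setNames(as.integer(shares), model_names),
                 total = total),
            class = "complement_allocation")
}

allocation_subtotals <- function(per_class, donor_specs) {
  if (is.null(donor_specs)) return(NULL)
  sub <- vapply(donor_specs, function(s) {
    sum(per_class[intersect(names(per_class), s$main_classes)])
  }, 0)
  stats::setNames(as.integer(sub), vapply(donor_specs, `[[`, "", "name"))
}

#' @export
print.complement_allocation <- function(x, ...) {
  cat("<complement_allocation> scheme = ", x$scheme, ", total = ", x$total, "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' Allocation table in the published layout
#'
#' Per-donor-class complement counts for all four models under one scheme,
#' as a long data frame (`model`, `donor_model`, `class_id`, `count`).
#'
#' @param specs The 4 `base_model_spec`s.
#' @param train_counts Named per-class training counts.
#' @param scheme `"class_level"` or `"model_level"`.
#' @return A data frame, one row per (receiving model, donor class).
#' @export
allocation_table <- function(specs, train_counts,
                             scheme = c("class_level", "model_level")) {
  scheme <- match.arg(scheme)
  rows <- lapply(specs, function(spec) {
    donors <- specs[vapply(specs, `[[`, 1L, "index") != spec$index]
    alloc <- complement_allocation_for(spec, specs, train_counts, scheme)
    donor_of <- function(cls) {
      vapply(cls, function(cl) {
        donors[[which(vapply(donors, function(d) cl %in% d$main_classes, TRUE))]]$name
      }, "")
    }
    data.frame(model = spec$name,
               donor_model = donor_of(names(alloc$per_class)),
               class_id = names(alloc$per_class),
               count = as.integer(alloc$per_class),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Allocation for one receiving model under either scheme.
complement_allocation_for <- function(spec, specs, train_counts, scheme) {
  avg <- average_main_instances(spec, train_counts)
  donors <- specs[vapply(specs, `[[`, 1L, "index") != spec$index]
  if (scheme == "class_level") {
    allocate_class_level(avg, spec$complement_classes, donor_specs = donors)
  } else {
    allocate_model_level(avg, donors)
  }
}

#' Sample a model's complement training data
#'
#' Draws, per donor class, exactly the allocated number of instances from the
#' training pool without replacement, and relabels them with the complement
#' token. If a donor class has fewer pool instances than allocated, the
#' deficit is drawn with replacement and a warning is emitted.
#'
#' @param allocation A `complement_allocation`.
#' @param train_pool A `har_dataset` (the training data).
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @return A `har_dataset` whose labels are all [complement_token()].
#' @export
sample_complement <- function(allocation, train_pool, seed = 0) {
  idx <- with_seed(seed, {
    unlist(lapply(names(allocation$per_class), function(cl) {
      want <- allocation$per_class[[cl]]
      pool <- which(train_pool$y == cl)
      if (want == 0) return(integer())
      if (length(pool) == 0) stop("no training instances available for donor class ", cl)
      if (length(pool) >= want) {
        pool[sample.int(length(pool), want)]
      } else {
        warning("complement pool shortfall for class ", cl, ": have ",
                length(pool), ", need ", want, "; topping up with replacement")
        c(pool, pool[sample.int(length(pool), want - length(pool), replace = TRUE)])
      }
    }), use.names = FALSE)
  })
  out <- dataset_slice(train_pool, idx)
  out$source_class <- train_pool$y[idx]
  out$y <- rep(.COMPLEMENT, length(idx))
  out
}
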