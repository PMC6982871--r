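# Synthetic smart-home event simulator. Generates labelled binary-sensor
# event streams with the statistical structure the ensemble assumes: a
# single inhabitant performing routine-scheduled activities, per-activity
# sensor signatures with controllable overlap between similar activities
# (shared bed / kitchen / door sensors and the like), class imbalance, and
# two noise channels (dropped firings, spurious stray events). Every other
# module is testable against this generator without any external dataset.

#' Construct an activity template
#'
#' @param class_id Class label.
#' @param routines `;`-separated routine tags (`"M"`, `"A;E"`, `"M;A;E"`...)
#'   in which the activity may be scheduled.
#' @param weight Relative scheduling frequency (class imbalance knob).
#' @param private_sensors Sensors unique to this activity; the FIRST is the
#'   primary sensor, which fires in every activity window when overlap and
#'   noise are zero.
#' @param shared_sensors Sensors deliberately shared with this activity's
#'   similarity group (inter-class similarity knob).
#' @param duration_meanlog,duration_sdlog Log-normal activity duration
#'   parameters, seconds (defaults: median 180 s, sdlog 0.4).
#' @return An `activity_template` list.
#' @export
activity_template <- function(class_id, routines, weight = 1,
                              private_sensors, shared_sensors = character(),
                              duration_meanlog = log(180), duration_sdlog = 0.4) {
  stopifnot(weight >= 0, length(private_sensors) >= 1)
  structure(list(class_id = class_id, routines = routines, weight = weight,
                 private_sensors = private_sensors,
                 shared_sensors = shared_sensors,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog),
            class = "activity_template")
}

#' Default simulation configuration
#'
#' `"paper_like"` emulates the reference deployment: the 12 restructured
#' activity classes with their routine tags and imbalance (scheduling
#' weights proportional to the published window counts), six similarity
#' pairs sharing a sensor (bed, kitchen motion, cutlery, door, bathroom
#' motion, sofa motion) over the full 30-sensor registry, 10 simulated
#' days. `"small"` is a 4-class, 2-day configuration for fast tests.
#'
#' @param scale `"paper_like"` or `"small"`.
#' @param days Number of simulated days (defaults: 10 paper_like, 2 small).
#' @param overlap Fraction of signature mass moved from private onto shared
#'   sensors, in \[0, 1\] (default 0.4). See [set_overlap()].
#' @param miss_rate Probability that a due sensor firing is dropped.
#' @param spurious_rate Expected stray events per 30-s window.
#' @param gap_mean Mean idle gap between activities, seconds.
#' @return A `sim_config` list (`templates`, `registry`, `days`, `overlap`,
#'   `miss_rate`, `spurious_rate`, `gap_mean`, `window_seconds`).
#' @export
default_sim_config <- function(scale = c("paper_like", "small"), days = NULL,
                               overlap = 0.4, miss_rate = 0.05,
                               spurious_rate = 0.1, gap_mean = NULL) {
  scale <- match.arg(scale)
  registry <- ucami_registry()
  if (scale == "paper_like") {
    counts <- ucami_restructured_counts()
    w <- stats::setNames(counts$count, counts$class_id)
    rt <- stats::setNames(counts$routines, counts$class_id)
    # (class, private sensors, shared sensor) per similarity pair
    spec <- list(
      Act24 = list(p = c("C13", "SM4"), s = "C14"),
      Act23 = list(p = c("D03", "C05"), s = "C14"),
      ActN3 = list(p = c("H01", "D04"), s = "SM1"),
      ActN4 = list(p = c("D01", "D02"), s = "SM1"),
      ActN5 = list(p = c("C04", "D05"), s = "C03"),
      Act01 = list(p = c("C01", "C02"), s = "C03"),
      Act15 = list(p = c("C08", "C12"), s = "M01"),
      ActN1 = list(p = c("D08", "D09"), s = "M01"),
      Act17 = list(p = c("C09", "C15"), s = "SM3"),
      Act18 = list(p = c("D07", "C10"), s = "SM3"),
      Act22 = list(p = c("D10", "C07"), s = "SM5"),
      ActN2 = list(p = c("S09", "TV0"), s = "SM5")
    )
    templates <- lapply(names(spec), function(cl) {
      activity_template(cl, rt[[cl]], weight = w[[cl]],
                        private_sensors = spec[[cl]]$p,
                        shared_sensors = spec[[cl]]$s)
    })
    days <- days %||% 10
    gap_mean <- gap_mean %||% 2700
  } else {
    templates <- list(
      activity_template("SynM", "M", weight = 3,
                        private_sensors = c("C13", "SM4"), shared_sensors = "C14"),
      activity_template("SynE", "E", weight = 2,
                        private_sensors = c("D03", "C05"), shared_sensors = "C14"),
      activity_template("SynA", "A", weight = 2,
                        private_sensors = c("D01", "D02"), shared_sensors = "SM1"),
      activity_template("SynX", "M;A;E", weight = 1,
                        private_sensors = c("C08", "C12"), shared_sensors = "SM1")
    )
    days <- days %||% 2
    gap_mean <- gap_mean %||% 1800
  }
  all_sensors <- unlist(lapply(templates, function(t) c(t$private_sensors, t$shared_sensors)))
  stopifnot(all(all_sensors %in% registry$sensor_id))
  structure(list(templates = templates, registry = registry, days = days,
                 overlap = overlap, miss_rate = miss_rate,
                 spurious_rate = spurious_rate, gap_mean = gap_mean,
                 window_seconds = 30),
            class = "sim_config")
}

#' Set the inter-class sensor-overlap amount
#'
#' At 0 every activity's signature is disjoint from every other (its primary
#' private sensor fires in every window); at 1 paired activities share all
#' their sensors and are indistinguishable except through the routine
#' feature.
#'
#' @param config A `sim_config`.
#' @param amount Overlap fraction in \[0, 1\].
#' @return The modified `sim_config`.
#' @export
set_overlap <- function(config, amount) {
  stopifnot(amount >= 0, amount <= 1)
  config$overlap <- amount
  config
}

# Per-window firing probabilities of a template under the config's overlap:
# private sensors keep (1 - overlap) of their base mass (primary base 1.0,
# secondary 0.6), shared sensors receive overlap * 0.9.
effective_signature <- function(template, overlap) {
  base_priv <- c(1.0, rep(0.6, length(template$private_sensors) - 1))
  p <- stats::setNames(base_priv * (1 - overlap), template$private_sensors)
  if (length(template$shared_sensors) > 0) {
    p <- c(p, stats::setNames(rep(0.9 * overlap, length(template$shared_sensors)),
                              template$shared_sensors))
  }
  p[p > 0]
}

.BIN_HOURS <- list(Morning = c(6, 12), Afternoon = c(12, 18), Evening = c(18, 24))

#' Simulate a labelled smart-home event stream
#'
#' Days are partitioned into the three routine bins; within each bin,
#' activities are scheduled sequentially with exponential idle gaps,
#' log-normal durations and template choice proportional to weight among the
#' templates allowed in that bin. Events are drawn windowwise from each
#' activity's effective sensor signature; dropped firings and spurious
#' stray events are then applied. Deterministic given the seed.
#'
#' @param config A `sim_config` (see [default_sim_config()]).
#' @param seed Integer seed.
#' @param start_date First simulated day (`"YYYY-MM-DD"`).
#' @return List with `events` (`sensor_events`), `annotations`
#'   (`activity_annotations`), `registry` and `catalog` (a `class_counts`
#'   data frame of the simulated classes with realised annotation counts).
#' @export
simulate_home <- function(config, seed = 0, start_date = "2017-11-01") {
  stopifnot(inherits(config, "sim_config"))
  registry <- config$registry
  w <- config$window_seconds
  day0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = .TZ)
  active_state <- function(id) registry_states(registry, id)[1]

  out <- with_seed(seed, {
    ann_class <- character(); ann_s <- numeric(); ann_e <- numeric(); ann_k <- integer()
    ev_t <- numeric(); ev_id <- character(); ev_state <- character()
    allowed <- lapply(config$templates, function(t) strsplit(t$routines, ";")[[1]])
    # weight = target share of occurrences; divided by the number of bins a
    # class competes in so realised counts stay proportional to the weights
    weights <- vapply(config$templates, `[[`, 0, "weight") /
      vapply(allowed, length, 1L)
    sigs <- lapply(config$templates, effective_signature, overlap = config$overlap)

    draw_duration <- function(tmpl) {
      min(900, max(45, stats::rlnorm(1, tmpl$duration_meanlog, tmpl$duration_sdlog)))
    }
    # record one occurrence of template k on [s, e) and emit its events
    place <- function(k, s, e) {
      ann_class <<- c(ann_class, config$templates[[k]]$class_id)
      ann_s <<- c(ann_s, s); ann_e <<- c(ann_e, e); ann_k <<- c(ann_k, k)
      sig <- sigs[[k]]
      for (wi in seq(floor(s / w), floor((e - 1) / w))) {
        ws <- max(s, wi * w); we <- min(e, (wi + 1) * w)
        if (we - ws < 1) next
        fire <- names(sig)[stats::runif(length(sig)) < sig]
        if (config$miss_rate > 0 && length(fire) > 0) {
          fire <- fire[stats::runif(length(fire)) >= config$miss_rate]
        }
        for (id in fire) {
          ev_t <<- c(ev_t, ws + floor(stats::runif(1) * (we - ws)))
          ev_id <<- c(ev_id, id)
          ev_state <<- c(ev_state, active_state(id))
        }
      }
    }

    for (day in seq_len(config$days) - 1) {
      d0 <- day * 86400
      for (bin in names(.BIN_HOURS)) {
        tag <- substr(bin, 1, 1)
        elig <- which(vapply(allowed, function(a) tag %in% a, TRUE))
        if (length(elig) == 0) next
        bin_s <- d0 + .BIN_HOURS[[bin]][1] * 3600
        bin_e <- d0 + .BIN_HOURS[[bin]][2] * 3600
        t <- bin_s
        repeat {
          t <- t + stats::rexp(1, 1 / config$gap_mean)
          k <- elig[sample.int(length(elig), 1, prob = weights[elig])]
          dur <- draw_duration(config$templates[[k]])
          s <- floor(t); e <- floor(t + dur)
          if (e >= bin_e) break
          place(k, s, e)
          t <- e
        }
      }
      if (config$spurious_rate > 0) {
        span_s <- d0 + 6 * 3600; span_e <- d0 + 24 * 3600
        n_spur <- stats::rpois(1, config$spurious_rate * (span_e - span_s) / w)
        if (n_spur > 0) {
          ids <- registry$sensor_id[sample.int(nrow(registry), n_spur, replace = TRUE)]
          ts <- span_s + floor(stats::runif(n_spur) * (span_e - span_s))
          sts <- vapply(ids, function(id) {
            sample(registry_states(registry, id), 1)
          }, "")
          ev_t <- c(ev_t, ts); ev_id <- c(ev_id, ids); ev_state <- c(ev_state, sts)
        }
      }
    }

    # Coverage pass: a lived-in routine repeats every activity eventually, so
    # each class is guaranteed >= 2 occurrences; rare classes are inserted
    # into free slots of their allowed bins.
    for (k in seq_along(config$templates)) {
      deficit <- 2 - sum(ann_k == k)
      tries <- 0
      while (deficit > 0 && tries < 200) {
        tries <- tries + 1
        day <- sample.int(config$days, 1) - 1
        tag <- sample(allowed[[k]], 1)
        bin <- names(.BIN_HOURS)[vapply(names(.BIN_HOURS), function(b) substr(b, 1, 1) == tag, TRUE)]
        bin_s <- day * 86400 + .BIN_HOURS[[bin]][1] * 3600
        bin_e <- day * 86400 + .BIN_HOURS[[bin]][2] * 3600
        dur <- draw_duration(config$templates[[k]])
        s <- floor(bin_s + stats::runif(1) * (bin_e - bin_s - dur - 2))
        e <- floor(s + dur)
        busy <- any(ann_s < e + 1 & ann_e > s - 1)
        if (!busy) {
          place(k, s, e)
          deficit <- deficit - 1
        }
      }
    }

    list(ann_class = ann_class, ann_s = ann_s, ann_e = ann_e,
         ev_t = ev_t, ev_id = ev_id, ev_state = ev_state)
  })

  ann <- annotations(out$ann_class, day0 + out$ann_s, day0 + out$ann_e)
  events <- sensor_events(day0 + out$ev_t, out$ev_id, out$ev_state,
                          inhabitant = "SimResident", registry = registry)
  tab <- table(out$ann_class)
  catalog <- data.frame(
    class_id = vapply(config$templates, `[[`, "", "class_id"),
    name = vapply(config$templates, `[[`, "", "class_id"),
    count = as.integer(tab[vapply(config$templates, `[[`, "", "class_id")]),
    routines = vapply(config$templates, `[[`, "", "routines"),
    stringsAsFactors = FALSE
  )
  catalog$count[is.na(catalog$count)] <- 0L
  catalog <- structure(catalog, class = c("class_counts", "data.frame"))
  list(events = events, annotations = ann, registry = registry, catalog = catalog)
}

#' Simulate and prepare a labelled dataset in one call
#'
#' Runs [simulate_home()] and the windowing/feature/labelling pipeline.
#'
#' @inheritParams simulate_home
#' @param window_seconds Window width (default the config's, 30 s).
#' @param mode Feature mode for [extract_features()].
#' @return List with `data` (`har_dataset`), `catalog`, `events`,
#'   `annotations`.
#' @export
simulate_dataset <- function(config, seed = 0, window_seconds = NULL,
                             mode = c("indicator", "fraction"),
                             start_date = "2017-11-01") {
  sim <- simulate_home(config, seed = seed, start_date = start_date)
  ds <- prepare_dataset(sim$events, sim$annotations, sim$registry,
                        window_seconds = window_seconds %||% config$window_seconds,
                        mode = mode)
  cat_realised <- sim$catalog
  real <- table(ds$y)
  cat_realised$count <- as.integer(real[cat_realised$class_id])
  cat_realised$count[is.na(cat_realised$count)] <- 0L
  list(data = ds, catalog = cat_realised, events = sim$events,
       annotations = sim$annotations)
}
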