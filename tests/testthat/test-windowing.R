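origin <- as.POSIXct("2017-11-10 00:00:00", tz = "UTC")

events_at <- function(secs, sensor = "D01", state = "Open") {
  sensor_events(origin + secs, rep(sensor, length(secs)), rep(state, length(secs)))
}

test_that("segmentation tiles with half-open windows and conserves events", {
  seg <- segment_events(events_at(c(0, 29, 31)), 30, origin)
  expect_equal(nrow(seg$windows), 2)
  expect_equal(seg$windows$n_events, c(2, 1))
  # boundary event belongs to the NEXT window
  seg2 <- segment_events(events_at(c(0, 30)), 30, origin)
  expect_equal(seg2$assignment, c(1L, 2L))
  # empty stream is fine
  empty <- segment_events(events_at(numeric()), 30, origin)
  expect_equal(nrow(empty$windows), 0)
})

test_that("a simulated hour tiles into 120 windows conserving all events", {
  sim <- simulate_home(default_sim_config("small", days = 1), seed = 3)
  seg <- segment_events(sim$events, 30)
  expect_equal(sum(seg$windows$n_events), nrow(sim$events))
  expect_equal(length(seg$assignment), nrow(sim$events))
  # one-hour slice of the grid holds exactly 120 windows
  span <- as.numeric(difftime(max(seg$windows$end), min(seg$windows$start), units = "secs"))
  expect_equal(nrow(seg$windows), span / 30)
  hour <- seg$windows$start < min(seg$windows$start) + 3600
  expect_equal(sum(hour), 120)
})

test_that("routine bins cover the day as decided", {
  expect_equal(routine_of(origin + 8 * 3600), "Morning")
  expect_equal(routine_of(origin + 13.5 * 3600), "Afternoon")
  expect_equal(routine_of(origin + 21 * 3600), "Evening")
  expect_equal(routine_of(origin + 2 * 3600), "Evening")  # night folds in
  expect_equal(routine_of(origin + 12 * 3600), "Afternoon") # boundary
  expect_equal(routine_code(c("Morning", "Afternoon", "Evening")), c(0, 0.5, 1))
})

test_that("features are 31-dimensional indicators in [0,1]", {
  reg <- ucami_registry()
  ev <- sensor_events(origin + c(10, 12, 40), c("D01", "D01", "C14"),
                      c("Open", "Close", "Pressure"))
  seg <- segment_events(ev, 30, origin)
  X <- extract_features(ev, seg, reg)
  expect_equal(dim(X), c(2, 31))
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(unname(X[1, "D01"]), 1)
  expect_equal(sum(X[1, setdiff(colnames(X), "routine")]), 1)
  expect_equal(unname(X[2, "C14"]), 1)
  # empty window: all sensor components zero, routine code present
  ev2 <- sensor_events(origin + 40, "C14", "Pressure")
  seg2 <- segment_events(ev2, 30, origin)
  X2 <- extract_features(ev2, seg2, reg)
  expect_equal(sum(X2[1, setdiff(colnames(X2), "routine")]), 0)
  expect_equal(unname(X2[1, "routine"]), routine_code(routine_of(origin)))
})

test_that("feature extraction is invariant to event order within a window", {
  reg <- ucami_registry()
  ids <- c("D01", "C14", "SM1", "D01")
  states <- c("Open", "Pressure", "Movement", "Close")
  ev_a <- sensor_events(origin + c(1, 2, 3, 4), ids, states)
  perm <- c(3, 1, 4, 2)
  ev_b <- sensor_events(origin + c(1, 2, 3, 4), ids[perm], states[perm])
  for (mode in c("indicator", "fraction")) {
    Xa <- extract_features(ev_a, segment_events(ev_a, 30, origin), reg, mode)
    Xb <- extract_features(ev_b, segment_events(ev_b, 30, origin), reg, mode)
    expect_equal(Xa, Xb)
  }
})

test_that("fraction mode stays in [0,1] and reflects event shares", {
  reg <- ucami_registry()
  ev <- sensor_events(origin + c(1, 2, 3, 4), c("D01", "D01", "D01", "C14"),
                      c("Open", "Close", "Open", "Pressure"))
  X <- extract_features(ev, segment_events(ev, 30, origin), reg, "fraction")
  expect_equal(unname(X[1, "D01"]), 0.75)
  expect_equal(unname(X[1, "C14"]), 0.25)
})

test_that("windows are labelled by majority overlap, ties to the earlier annotation", {
  reg <- ucami_registry()
  ev <- events_at(c(5, 35, 65))
  seg <- segment_events(ev, 30, origin)
  X <- extract_features(ev, seg, reg)
  # window 2 [30, 60) overlaps A for 20 s and B for 10 s
  ann <- annotations(c("A", "B"), origin + c(0, 50), origin + c(50, 95))
  ds <- label_windows(seg, X, ann)
  expect_equal(ds$y, c("A", "A", "B"))
  # exact 15/15 tie goes to earlier-starting annotation
  ann_tie <- annotations(c("A", "B"), origin + c(0, 45), origin + c(45, 90))
  ds_tie <- label_windows(seg, X, ann_tie)
  expect_equal(ds_tie$y[2], "A")
  # windows with no overlap are discarded and reported
  ann_gap <- annotations("A", origin, origin + 40)
  ds_gap <- label_windows(seg, X, ann_gap)
  expect_equal(ds_gap$n, 2)
  expect_equal(ds_gap$discarded, 3L)
})

test_that("labels match the generator schedule at zero noise", {
  cfg <- set_overlap(default_sim_config("small", miss_rate = 0, spurious_rate = 0), 0)
  sim <- simulate_home(cfg, seed = 11)
  ds <- prepare_dataset(sim$events, sim$annotations, sim$registry)
  # oracle: schedule lookup at window midpoint
  mid <- as.numeric(ds$windows$start) + 15
  truth <- vapply(mid, function(t) {
    hit <- which(as.numeric(sim$annotations$start) <= t &
                 as.numeric(sim$annotations$end) > t)
    if (length(hit) == 0) NA_character_ else sim$annotations$class_id[hit[1]]
  }, "")
  ok <- !is.na(truth)
  expect_gte(mean(ds$y[ok] == truth[ok]), 0.95)
})
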