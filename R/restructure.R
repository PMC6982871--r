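# Dataset restructuring: merging of near-identical activity classes (those
# sharing the same sensors), removal of under-represented classes, and the
# random held-out test split. The merge step MUST precede the minimum-count
# filter: several merge sources individually fall below the threshold yet
# survive inside their merged class.

#' Built-in activity class-count table (original 24-class catalogue)
#'
#' Instance counts per activity class for the combined 10 days of the
#' reference single-inhabitant dataset, with the routine tags (M/A/E) in
#' which each activity occurs. Window-level instances; total 1304.
#'
#' @return A `class_counts` data frame with columns `class_id`, `name`,
#'   `count`, `routines`.
#' @export
ucami_class_counts <- function() {
  txt <- "class_id,name,count,routines
Act01,Take Medication,52,A;E
Act02,Prepare Breakfast,63,M
Act03,Prepare lunch,118,A
Act04,Prepare Dinner,76,E
Act05,Breakfast,78,M
Act06,Lunch,101,A
Act07,Dinner,86,E
Act08,Eat a snack,12,A
Act09,Watch TV,70,A;E
Act10,Enter Smart Lab,21,A;E
Act11,Play a videogame,28,M;E
Act12,Relax on the sofa,85,M;A;E
Act13,Leave Smart Lab,33,M;A
Act14,Visitor to Smart Lab,7,M;A
Act15,Put waste in the bin,75,A;E
Act16,Wash hands,22,M
Act17,Brush teeth,132,M;A;E
Act18,Use the toilet,44,M;A;E
Act19,Wash dishes,13,A;E
Act20,Put washing in machine,20,M;A
Act21,Work at the table,20,M
Act22,Dressing,86,M;A;E
Act23,Go to bed,30,E
Act24,Wake up,32,M"
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  structure(df, class = c("class_counts", "data.frame"))
}

#' Built-in class merge map
#'
#' Groups of activities that produce near-identical sensor signatures and are
#' merged into one class each: the three door activities into `ActN1`, the
#' two sofa/TV activities into `ActN2`, and the prepare-meal/eat-meal pairs
#' into `ActN3` (breakfast), `ActN4` (lunch) and `ActN5` (dinner).
#'
#' @return Named list: new class id -> character vector of source class ids.
#' @export
ucami_merge_map <- function() {
  list(
    ActN1 = c("Act10", "Act13", "Act14"),
    ActN2 = c("Act09", "Act12"),
    ActN3 = c("Act02", "Act05"),
    ActN4 = c("Act03", "Act06"),
    ActN5 = c("Act04", "Act07")
  )
}

# Routine tags of the merged classes (union of their sources collapses to
# the dominant routine of the merged activity).
.MERGED_ROUTINES <- c(ActN1 = "M;A;E", ActN2 = "M;A;E", ActN3 = "M",
                      ActN4 = "A", ActN5 = "E")

#' Merge similar classes in a count table
#'
#' Each merged class's count is the sum of its sources; sources are removed,
#' untouched classes preserved, total conserved.
#'
#' @param counts A `class_counts` data frame.
#' @param merges Named list mapping new class id -> source class ids.
#' @return A `class_counts` data frame with merged classes appended.
#' @export
apply_merges <- function(counts, merges) {
  if (length(merges) == 0) return(counts)
  all_src <- unlist(merges, use.names = FALSE)
  if (anyDuplicated(all_src)) stop("merge map error: source id used twice")
  missing <- setdiff(all_src, counts$class_id)
  if (length(missing) > 0) {
    stop("merge map error: source id(s) not in counts: ", paste(missing, collapse = ", "))
  }
  if (any(names(merges) %in% all_src)) stop("merge map error: new id is also a source id")
  kept <- counts[!counts$class_id %in% all_src, , drop = FALSE]
  merged <- do.call(rbind, lapply(names(merges), function(new_id) {
    src <- counts[counts$class_id %in% merges[[new_id]], , drop = FALSE]
    data.frame(class_id = new_id,
               name = new_id,
               count = sum(src$count),
               routines = .MERGED_ROUTINES[new_id] %||% paste(
                 sort(unique(unlist(strsplit(src$routines, ";")))), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(kept, merged)
  rownames(out) <- NULL
  structure(out, class = c("class_counts", "data.frame"))
}

#' Remove under-represented classes
#'
#' Classes with fewer than `min_instances` instances (strictly less than) are
#' removed; a class exactly at the threshold is kept.
#'
#' @param counts A `class_counts` data frame.
#' @param min_instances Minimum instance count to keep a class (default 30).
#' @return List with `kept` and `removed` (`class_counts`) and
#'   `removed_fraction` (percentage of instances removed).
#' @export
filter_classes <- function(counts, min_instances = 30) {
  stopifnot(min_instances >= 0)
  low <- counts$count < min_instances
  kept <- counts[!low, , drop = FALSE]
  removed <- counts[low, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(
    kept = structure(kept, class = c("class_counts", "data.frame")),
    removed = structure(removed, class = c("class_counts", "data.frame")),
    removed_fraction = 100 * sum(removed$count) / max(sum(counts$count), 1)
  )
}

#' Run the full restructuring plan on a count table
#'
#' Merge first, then filter; this order is load-bearing (see package
#' vignette) and is asserted by a regression test.
#'
#' @param counts A `class_counts` data frame (defaults to the built-in
#'   original catalogue).
#' @param merges Merge map (defaults to [ucami_merge_map()]).
#' @param min_instances Removal threshold (default 30).
#' @return List with `catalog` (kept `class_counts`), `removed`,
#'   `removed_fraction`, `merged` (the intermediate merged table).
#' @export
restructure_counts <- function(counts = ucami_class_counts(),
                               merges = ucami_merge_map(),
                               min_instances = 30) {
  merged <- apply_merges(counts, merges)
  flt <- filter_classes(merged, min_instances)
  list(catalog = flt$kept, removed = flt$removed,
       removed_fraction = flt$removed_fraction, merged = merged)
}

#' The restructured 12-class catalogue
#'
#' Convenience accessor: merged and filtered class-count table (12 classes,
#' 1189 instances).
#'
#' @return A `class_counts` data frame.
#' @export
ucami_restructured_counts <- function() {
  restructure_counts()$catalog
}

#' Random train/test split
#'
#' Uniform random selection of `round_half_up(test_fraction * n)` instances
#' as the held-out test set; optionally stratified by class.
#'
#' @param data A `har_dataset`.
#' @param test_fraction Proportion held out (default 0.15).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified If `TRUE`, sample the fraction within each class.
#' @return List with `train` and `test` (`har_dataset`s) and `test_idx`.
#' @export
split_train_test <- function(data, test_fraction = 0.15, seed = 0,
                             stratified = FALSE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- data$n
  if (n < 2) stop("need at least 2 instances to split")
  test_idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), data$y), function(idx) {
        k <- round_half_up(test_fraction * length(idx))
        idx[sample.int(length(idx), k)]
      }), use.names = FALSE)
    } else {
      k <- round_half_up(test_fraction * n)
      sample.int(n, k)
    }
  })
  test_idx <- sort(test_idx)
  list(train = dataset_slice(data, setdiff(seq_len(n), test_idx)),
       test = dataset_slice(data, test_idx),
       test_idx = test_idx)
}

# Class counts of a dataset, as a named vector over `classes` (zeros kept).
dataset_counts <- function(data, classes = sort(unique(data$y))) {
  tab <- table(factor(data$y, levels = classes))
  stats::setNames(as.numeric(tab), classes)
}
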