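test_that("the four base models partition the restructured catalogue as published", {
  specs <- build_model_specs(ucami_restructured_counts())
  expect_equal(vapply(specs, `[[`, "", "name"),
               c("Morning", "Afternoon", "Evening", "Mixed"))
  expect_equal(vapply(specs, `[[`, 1L, "m"), c(3L, 2L, 3L, 8L))
  expect_setequal(specs[[1]]$main_classes, c("Act24", "ActN3"))
  expect_setequal(specs[[2]]$main_classes, "ActN4")
  expect_setequal(specs[[3]]$main_classes, c("Act23", "ActN5"))
  expect_length(specs[[2]]$complement_classes, 11)
  # partition properties: union is the catalogue, each class in exactly one
  all_main <- unlist(lapply(specs, `[[`, "main_classes"))
  expect_setequal(all_main, ucami_restructured_counts()$class_id)
  expect_false(anyDuplicated(all_main) > 0)
  for (s in specs) expect_length(intersect(s$main_classes, s$complement_classes), 0)
})

test_that("averages of main-class training counts behave", {
  specs <- toy_specs()
  expect_equal(average_main_instances(specs[[1]], c(m1 = 10, m2 = 30)), 20)
  expect_equal(average_main_instances(specs[[2]], c(a1 = 186)), 186)
  expect_error(average_main_instances(specs[[1]], c(m1 = 10)), "m2")
})

test_that("class-level allocation reproduces the published worked example", {
  a <- allocate_class_level(74, paste0("K", 1:10))
  expect_equal(a$per_class_raw, 14.8)
  expect_true(all(a$per_class == 15))
  expect_equal(a$total, 150)
  # single-main-class model at published scale: 186.15 over 11 donors -> 34
  a2 <- allocate_class_level(186.15, paste0("K", 1:11))
  expect_true(all(a2$per_class == 34))
  # degenerate allocation warns
  expect_warning(allocate_class_level(0.6, paste0("K", 1:3)), "degenerate")
})

test_that("model-level allocation apportions by largest remainder", {
  specs <- build_model_specs(ucami_restructured_counts())
  a <- allocate_model_level(73.525, specs[-1])
  expect_equal(unname(a$per_model), c(24L, 24L, 25L))
  expect_equal(a$total, 73)
  expect_equal(unname(a$per_class[c("Act23", "ActN5")]), c(12L, 12L))
  expect_equal(unname(a$per_class[["ActN4"]]), 24L)
  a2 <- allocate_model_level(186.15, specs[-2])
  expect_equal(unname(a2$per_model), c(62L, 62L, 62L))
  # apportionment conserves its total
  expect_equal(sum(a$per_class), a$total)
  expect_equal(sum(a2$per_class), a2$total)
})

test_that("published allocation tables are reproduced within rounding", {
  specs <- build_model_specs(ucami_restructured_counts())
  counts <- stats::setNames(0.85 * ucami_restructured_counts()$count,
                            ucami_restructured_counts()$class_id)
  # class level: uniform per donor class (15, 34, 16, 29)
  tab_cl <- allocation_table(specs, counts, "class_level")
  per_model_uniform <- vapply(c("Morning", "Afternoon", "Evening", "Mixed"),
                              function(nm) unique(tab_cl$count[tab_cl$model == nm]), 1L)
  expect_equal(unname(per_model_uniform), c(15L, 34L, 16L, 29L))
  # model level: published per-class figures within +-1 instance
  tab_ml <- allocation_table(specs, counts, "model_level")
  published <- list(
    Morning  = c(ActN4 = 24, Act23 = 12, ActN5 = 12, Act01 = 3, Act15 = 3,
                 Act17 = 3, Act18 = 4, Act22 = 4, ActN1 = 4, ActN2 = 4),
    Afternoon = c(Act24 = 31, ActN3 = 31, Act23 = 31, ActN5 = 31, Act18 = 8,
                  Act15 = 9, Act17 = 9, Act01 = 9, Act22 = 9, ActN1 = 9, ActN2 = 9),
    Evening  = c(Act24 = 13, ActN3 = 14, ActN4 = 27, Act18 = 3, Act01 = 4,
                 Act15 = 4, Act17 = 4, Act22 = 4, ActN1 = 4, ActN2 = 4),
    Mixed    = c(Act24 = 12, ActN3 = 12, ActN4 = 24, Act23 = 12, ActN5 = 12)
  )
  for (nm in names(published)) {
    got <- tab_ml[tab_ml$model == nm, ]
    got_counts <- stats::setNames(got$count, got$class_id)
    expect_setequal(names(got_counts), names(published[[nm]]))
    expect_true(all(abs(got_counts[names(published[[nm]])] - published[[nm]]) <= 1),
                info = nm)
  }
})

test_that("class-level is uniform across classes, model-level across models", {
  specs <- build_model_specs(ucami_restructured_counts())
  counts <- stats::setNames(0.85 * ucami_restructured_counts()$count,
                            ucami_restructured_counts()$class_id)
  for (j in seq_along(specs)) {
    donors <- specs[-j]
    cl <- harensemble:::complement_allocation_for(specs[[j]], specs, counts, "class_level")
    ml <- harensemble:::complement_allocation_for(specs[[j]], specs, counts, "model_level")
    # class level: one value across all donor classes
    expect_length(unique(cl$per_class), 1)
    # model level: shares uniform across models (within remainder 1) ...
    expect_lte(diff(range(ml$per_model)), 1)
    # ... but generally non-uniform across classes whenever donor sizes differ
    if (length(unique(vapply(donors, function(d) length(d$main_classes), 1L))) > 1) {
      expect_gt(length(unique(ml$per_class)), 1)
    }
  }
})

test_that("complement sampling honours counts, labels, seed and shortfall", {
  ds <- separable_dataset(30, c("A", "B", "C"))
  alloc <- structure(list(scheme = "class_level",
                          per_class = c(A = 2L, B = 3L), total = 5L),
                     class = "complement_allocation")
  s1 <- sample_complement(alloc, ds, seed = 5)
  expect_equal(s1$n, 5)
  expect_true(all(s1$y == complement_token()))
  expect_equal(as.vector(table(s1$source_class)[c("A", "B")]), c(2L, 3L))
  s2 <- sample_complement(alloc, ds, seed = 5)
  expect_identical(s1$X, s2$X)
  # shortfall: ask for more than the pool, warned, exact count delivered
  alloc_big <- structure(list(per_class = c(A = 40L), total = 40L),
                         class = "complement_allocation")
  expect_warning(s3 <- sample_complement(alloc_big, ds, seed = 1), "shortfall")
  expect_equal(s3$n, 40)
  expect_error(suppressWarnings(sample_complement(
    structure(list(per_class = c(ZZ = 3L)), class = "complement_allocation"),
    ds, seed = 1)), "ZZ")
})
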