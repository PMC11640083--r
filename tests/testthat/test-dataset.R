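test_that("8:1:1 split sizes follow the deterministic rounding rule", {
  expect_equal(SEIgait:::splitSizes(23580),
               c(train = 18864L, validation = 2358L, test = 2358L))
  expect_equal(SEIgait:::splitSizes(10),
               c(train = 8L, validation = 1L, test = 1L))
  # remainder absorbed validation first, then test
  expect_equal(unname(SEIgait:::splitSizes(11)), c(8L, 2L, 1L))
  expect_equal(unname(SEIgait:::splitSizes(12)), c(8L, 2L, 2L))
  expect_equal(unname(SEIgait:::splitSizes(19)), c(15L, 2L, 2L))
  # sizes always sum to N
  for (n in 10:60) expect_equal(sum(SEIgait:::splitSizes(n)), n)
})

test_that("splitDataset partitions deterministically under a seed", {
  ds <- fixtureDataset(c(normal = 12, mild = 9, moderate = 11, severe = 10))
  s1 <- splitDataset(ds, seed = 42)
  s2 <- splitDataset(ds, seed = 42)
  s3 <- splitDataset(ds, seed = 43)
  expect_identical(s1@train$id, s2@train$id)
  expect_identical(s1@test$id, s2@test$id)
  expect_false(identical(s1@train$id, s3@train$id))
  # partition: disjoint, union = all
  all_ids <- c(s1@train$id, s1@validation$id, s1@test$id)
  expect_equal(sort(all_ids), sort(records(ds)$id))
  expect_equal(anyDuplicated(all_ids), 0)
  # same sizes across seeds
  expect_equal(nrow(s3@train), nrow(s1@train))
  expect_error(splitDataset(fixtureDataset(c(normal = 3, mild = 2,
                                             moderate = 2, severe = 2))),
               "at least 10")
})

test_that("subject-level splitting keeps each subject in one partition", {
  ds <- fixtureDataset(c(normal = 20, mild = 10, moderate = 10, severe = 10))
  ds@records$subject_id <- rep(sprintf("p%d", 1:10), each = 5)
  sp <- splitDataset(ds, seed = 9, bySubject = TRUE)
  sides <- rbind(cbind(sp@train$subject_id, "train"),
                 cbind(sp@validation$subject_id, "validation"),
                 cbind(sp@test$subject_id, "test"))
  spread <- tapply(sides[, 2], sides[, 1], function(x) length(unique(x)))
  expect_true(all(spread == 1))
})

test_that("oversampleBalance equalizes classes at the pre-balancing maximum", {
  ds <- fixtureDataset(c(normal = 10, mild = 4, moderate = 6, severe = 8))
  bal <- oversampleBalance(ds, seed = 7)
  counts <- table(records(bal)$label)
  expect_true(all(counts == 10))
  expect_equal(nrow(records(bal)), 40)
  # originals retained, duplicates marked and pointing at originals
  expect_true(all(records(ds)$id %in% records(bal)$id))
  dups <- records(bal)[!is.na(records(bal)$duplicate_of), ]
  expect_equal(nrow(dups), 40 - 28)
  expect_true(all(dups$duplicate_of %in% records(ds)$id))
  expect_equal(dups$label,
               records(ds)$label[match(dups$duplicate_of, records(ds)$id)])
  # duplicate images are the original pixel matrices
  i <- match(dups$id[1], records(bal)$id)
  j <- match(dups$duplicate_of[1], records(bal)$id)
  expect_identical(images(bal)[[i]], images(bal)[[j]])
})

test_that("oversampleBalance edge cases: already balanced, singleton class, empty class", {
  ds <- fixtureDataset(c(normal = 5, mild = 5, moderate = 5, severe = 5))
  expect_identical(records(oversampleBalance(ds)), records(ds))
  ds1 <- fixtureDataset(c(normal = 10, mild = 1, moderate = 10, severe = 10))
  bal <- oversampleBalance(ds1, seed = 3)
  mild <- records(bal)[records(bal)$label == "mild", ]
  expect_equal(nrow(mild), 10)
  expect_equal(sum(is.na(mild$duplicate_of)), 1)
  expect_true(all(mild$duplicate_of[!is.na(mild$duplicate_of)] ==
                    mild$id[is.na(mild$duplicate_of)]))
  ds2 <- fixtureDataset(c(normal = 5, mild = 5, moderate = 5, severe = 5))
  ds2@records$label[ds2@records$label == "severe"] <- "normal"
  ds2@images <- ds2@images
  expect_error(oversampleBalance(ds2), "empty: severe")
})

test_that("per-class partitions carry normalized weights", {
  ds <- fixtureDataset(c(normal = 100, mild = 50, moderate = 50,
                         severe = 25))
  pc <- perClassPartitions(records(ds))
  expect_equal(unname(pc$weights),
               c(100, 50, 50, 25) / 225, tolerance = 1e-12)
  expect_equal(sum(pc$weights), 1)
  one <- perClassPartitions(records(ds)[records(ds)$label == "mild", ])
  expect_length(one$partitions, 1)
  expect_equal(unname(one$weights), 1)
})

test_that("weighted per-class accuracy equals pooled accuracy", {
  ds <- fixtureDataset(c(normal = 40, mild = 20, moderate = 30, severe = 10))
  recs <- records(ds)
  pred <- withr::with_seed(5,
    sample(severityClasses(), nrow(recs), replace = TRUE))
  rep_ <- SEIgait:::evalReportFromPredictions(recs$label, pred)
  pc <- perClassPartitions(recs)
  perAcc <- vapply(names(pc$partitions), function(cl) {
    sel <- recs$label == cl
    100 * mean(pred[sel] == cl)
  }, numeric(1))
  expect_equal(sum(pc$weights * perAcc), rep_@accuracy, tolerance = 1e-12)
  expect_equal(rep_@weightedAccuracy, rep_@accuracy, tolerance = 1e-12)
})
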