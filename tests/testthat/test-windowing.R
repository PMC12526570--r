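# Stratified splitting, class weights, stride rule, sliding windows, WASW.

test_that("stratified split respects 6:2:2 per class and is deterministic", {
  ds <- quick_dataset(10, duration_s = 4)
  sp <- stratified_split(ds, seed = 5)
  tab <- table(sp$label, sp$split)
  expect_true(all(tab[, "train"] == 6))
  expect_true(all(tab[, "val"] == 2))
  expect_true(all(tab[, "test"] == 2))
  expect_identical(sp, stratified_split(ds, seed = 5))
  expect_false(identical(sp$split, stratified_split(ds, seed = 6)$split))
  # every record assigned exactly once
  expect_setequal(sp$record_id, vapply(ds, `[[`, "", "record_id"))
})

test_that("5 records split 3/1/1 by largest-remainder rounding", {
  ds <- quick_dataset(5, duration_s = 4)
  sp <- stratified_split(ds, seed = 1)
  tab <- table(sp$label, sp$split)
  expect_true(all(tab[, "train"] == 3))
  expect_true(all(tab[, "val"] == 1))
  expect_true(all(tab[, "test"] == 1))
})

test_that("classes with fewer than 3 records trigger a warning and flag", {
  ds <- quick_dataset(2, duration_s = 4)
  expect_warning(sp <- stratified_split(ds, seed = 1), "fewer than 3")
  expect_false(attr(sp, "all_splits_guaranteed"))
})

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(compute_class_weights(c(10, 10, 10, 10))), rep(1, 4))
  expect_equal(unname(compute_class_weights(c(a = 10, b = 30))), c(1.5, 0.5))
  w <- compute_class_weights(c(5, 9, 40, 2))
  expect_equal(mean(w), 1)
  expect_true(all(diff(w[order(c(5, 9, 40, 2))]) <= 0))  # rarer => larger
  expect_error(compute_class_weights(c(3, 0)), class = "invalid_parameter")
})

test_that("stride rule matches the clipped inverse-weight formula", {
  expect_identical(stride_for_class(1), 250L)
  expect_identical(stride_for_class(4), 125L)    # 62.5 clipped up
  expect_identical(stride_for_class(0.25), 500L) # 1000 clipped down
  expect_identical(stride_for_class(1.25), 200L)
  expect_error(stride_for_class(0), class = "invalid_parameter")

  # oracle equivalence on 1000 random weights
  set.seed(42)
  w <- exp(runif(1000, log(0.05), log(20)))
  mine <- stride_for_class(w)
  ora <- vapply(w, literal_stride, 0)
  expect_identical(as.numeric(mine), ora)
  # monotone non-increasing in the weight
  ws <- sort(w)
  expect_true(all(diff(stride_for_class(ws)) <= 0))
})

test_that("sliding windows have the documented start grid and count", {
  r <- structure(list(samples = numeric(75000), fs = 250, label = "Bradycardia",
                      record_id = "r1", meta = list()), class = "ppg_record")
  expect_equal(nrow(slide_windows(r, 250)$windows), 291)
  expect_equal(nrow(slide_windows(r, 500)$windows), 146)
  r10 <- structure(list(samples = seq_len(2500), fs = 250, label = "Tachycardia",
                        record_id = "r2", meta = list()), class = "ppg_record")
  one <- slide_windows(r10, 250)
  expect_equal(nrow(one$windows), 1)
  expect_equal(one$windows[1, ], seq_len(2500))
  short <- structure(list(samples = numeric(100), fs = 250, label = "Tachycardia",
                          record_id = "r3", meta = list()), class = "ppg_record")
  expect_warning(empty <- slide_windows(short, 250), "shorter")
  expect_equal(nrow(empty$windows), 0)
})

test_that("window contents are contiguous slices of the source record", {
  r <- structure(list(samples = sin(seq_len(6000) / 7), fs = 250,
                      label = "Tachycardia", record_id = "r", meta = list()),
                 class = "ppg_record")
  ws <- slide_windows(r, stride = 400)
  for (i in seq_len(nrow(ws$windows))) {
    start <- 1 + (i - 1) * 400
    expect_identical(ws$windows[i, ], r$samples[start:(start + 2499)])
  }
})

test_that("WASW keeps splits leakage-free and equalizes class windows", {
  ds <- quick_dataset(6, duration_s = 20, seed = 13)
  # make it imbalanced: drop most records of two classes
  labs <- vapply(ds, `[[`, "", "label")
  keep <- c(which(labs == "Bradycardia"), which(labs == "Tachycardia"),
            which(labs == "VentricularTachycardia")[1:5],
            which(labs == "VentricularFlutterFib")[1:5])
  ds <- structure(ds[sort(keep)], class = "ppg_dataset")
  sp <- stratified_split(ds, seed = 3)
  sets <- build_window_sets(ds, sp)

  ids <- lapply(sets, function(s) unique(s$source_ids))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)

  # stride is smaller (denser windows) for the rarer classes
  strides <- attr(sets, "strides")
  expect_true(all(strides[c("VentricularTachycardia", "VentricularFlutterFib")] <=
                    strides[c("Bradycardia", "Tachycardia")]))

  # per-class window counts after WASW are no more imbalanced than the
  # record counts fed in
  rec_tab <- table(sp$label[sp$split == "train"])
  win_tab <- table(sets$train$labels)
  expect_lte(max(win_tab) / min(win_tab), max(rec_tab) / min(rec_tab))

  # val uses the reference stride; test windows are non-overlapping
  expect_equal(nrow(sets$val$windows),
               sum(sp$split == "val") * (floor((5000 - 2500) / 250) + 1))
  expect_equal(nrow(sets$test$windows), sum(sp$split == "test") * 2)
})
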