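# Record-level stratified splitting and weight-aware sliding-window (WASW)
# augmentation. Splitting happens BEFORE any windowing so that no source
# record ever contributes windows to two splits.

#' Augmentation configuration
#'
#' The class-specific stride is `clip(round(S_ref / w_c^beta), S_min, S_max)`
#' samples: rarer classes (larger weight) get denser windows.
#'
#' @param window_s Window length in seconds (10 s).
#' @param s_ref Reference stride in samples (250 = 1 s at 250 Hz).
#' @param s_min,s_max Stride bounds in samples (125 / 500 = 0.5 / 2 s).
#' @param beta Tuning exponent on the class weight.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(window_s = 10, s_ref = 250, s_min = 125,
                           s_max = 500, beta = 1.0) {
  check_number(window_s, "window_s", lower = 1e-9)
  check_number(beta, "beta", lower = 1e-12)
  if (!(s_min > 0 && s_min <= s_ref && s_ref <= s_max))
    abort("need 0 < s_min <= s_ref <= s_max", "invalid_parameter")
  structure(list(window_s = window_s, s_ref = s_ref, s_min = s_min,
                 s_max = s_max, beta = beta),
            class = "augment_config")
}

# Largest-remainder apportionment of n into parts proportional to ratios.
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified record-level split
#'
#' Shuffles each class independently (seeded) and partitions it into
#' train/validation/test by largest-remainder rounding of the ratios, so
#' per-class proportions are within one record of the target. Classes with
#' fewer than 3 records trigger a warning: they cannot appear in every split.
#'
#' @param records A `ppg_dataset` or list of `ppg_record`s.
#' @param ratios Length-3 numeric summing to 1 (default 6:2:2).
#' @param seed Integer seed for the per-class shuffles.
#' @return A data.frame with columns `record_id`, `label`, `split`
#'   (levels train/val/test), of class `split_assignment`.
#' @export
stratified_split <- function(records, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios)) - 1 > 1e-8 || length(ratios) != 3)
    abort("ratios must be three numbers summing to 1", "invalid_parameter")
  man <- dataset_manifest(records)
  if (any(!man$label %in% rhythm_classes()))
    abort("unknown class label in records", "invalid_parameter")
  out <- with_seed(seed, {
    pieces <- lapply(split(seq_len(nrow(man)), man$label), function(idx) {
      idx <- idx[sample.int(length(idx))]
      sizes <- largest_remainder(length(idx), ratios)
      data.frame(row = idx,
                 split = rep(c("train", "val", "test"), times = sizes),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  small <- table(man$label)[table(man$label) < 3]
  if (length(small))
    warning(sprintf("classes with fewer than 3 records cannot appear in every split: %s",
                    paste(names(small), collapse = ", ")),
            call. = FALSE)
  res <- data.frame(record_id = man$record_id[out$row],
                    label = man$label[out$row],
                    split = factor(out$split, levels = c("train", "val", "test")),
                    stringsAsFactors = FALSE)
  res <- res[order(match(res$record_id, man$record_id)), ]
  rownames(res) <- NULL
  class(res) <- c("split_assignment", "data.frame")
  attr(res, "seed") <- as.integer(seed)
  attr(res, "all_splits_guaranteed") <- length(small) == 0
  res
}

#' Inverse-frequency class weights
#'
#' Weights are proportional to 1/count and rescaled to mean 1, so a balanced
#' dataset has all weights equal to 1 and the reference stride is recovered.
#'
#' @param counts Named numeric vector of per-class record counts (all >= 1).
#' @return Named numeric weights, mean 1.
#' @export
#' @examples
#' compute_class_weights(c(Bradycardia = 10, Tachycardia = 30))
compute_class_weights <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 1))
    abort("all class counts must be at least 1", "invalid_parameter")
  w <- 1 / counts
  w / mean(w)
}

#' Class-weight-guided window stride
#'
#' `S_c = clip(round(S_ref / w_c^beta), S_min, S_max)` with rounding half
#' away from zero. Monotone non-increasing in the weight: rarer classes
#' (larger `w_c`) receive smaller strides, hence more windows.
#'
#' @param w_c Positive class weight.
#' @param cfg An [augment_config()].
#' @return Integer stride in samples.
#' @export
#' @examples
#' stride_for_class(1)    # 250, the reference stride
#' stride_for_class(4)    # 62.5 clipped up to 125
stride_for_class <- function(w_c, cfg = augment_config()) {
  if (!is.numeric(w_c) || any(!is.finite(w_c)) || any(w_c <= 0))
    abort("class weight must be positive", "invalid_parameter")
  as.integer(clip(round_half_away(cfg$s_ref / w_c^cfg$beta), cfg$s_min, cfg$s_max))
}

#' Slide fixed-length windows over one record
#'
#' Windows start at sample 1, 1+stride, 1+2*stride, ...; the count is
#' `floor((L - W) / stride) + 1`. A record shorter than one window yields an
#' empty window set with a warning.
#'
#' @param record A `ppg_record`.
#' @param stride Stride in samples.
#' @param window_s Window length in seconds.
#' @return A list with `windows` (matrix, one row per window), `labels`,
#'   `source_ids`.
#' @export
slide_windows <- function(record, stride, window_s = 10) {
  check_number(stride, "stride", lower = 1)
  n <- length(record$samples)
  wlen <- as.integer(round(window_s * record$fs))
  if (n < wlen) {
    warning(sprintf("record %s shorter than one window; no windows produced",
                    record$record_id), call. = FALSE)
    return(list(windows = matrix(numeric(0), 0, wlen),
                labels = character(0), source_ids = character(0)))
  }
  starts <- seq.int(1L, n - wlen + 1L, by = as.integer(stride))
  w <- matrix(0, length(starts), wlen)
  for (i in seq_along(starts))
    w[i, ] <- record$samples[starts[i]:(starts[i] + wlen - 1L)]
  list(windows = w,
       labels = rep(record$label, length(starts)),
       source_ids = rep(record$record_id, length(starts)))
}

#' Build per-split window sets with WASW augmentation
#'
#' Training-split records are windowed with the class-specific stride of
#' [stride_for_class()], where class weights come from TRAIN-split record
#' counts only. Validation records use the fixed reference stride and test
#' records use non-overlapping windows (stride = window length), keeping
#' evaluation windows free of augmentation choices.
#'
#' @param records A `ppg_dataset`.
#' @param assignment A [stratified_split()] result.
#' @param cfg An [augment_config()].
#' @return Named list of `window_set`s (`train`, `val`, `test`), each with
#'   `windows`, `labels`, `source_ids`, `split`, plus `class_weights` and
#'   `strides` attributes on the list.
#' @export
build_window_sets <- function(records, assignment, cfg = augment_config()) {
  ids <- vapply(records, `[[`, "", "record_id")
  stopifnot(setequal(ids, assignment$record_id))
  split_of <- stats::setNames(as.character(assignment$split), assignment$record_id)
  train_counts <- table(factor(assignment$label[assignment$split == "train"],
                               levels = rhythm_classes()))
  weights <- compute_class_weights(as.numeric(train_counts) |>
                                     stats::setNames(names(train_counts)))
  strides <- vapply(weights, stride_for_class, 0L, cfg = cfg)
  wlen_samples <- function(r) as.integer(round(cfg$window_s * r$fs))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    recs <- records[split_of[ids] == sp]
    parts <- lapply(recs, function(r) {
      stride <- switch(sp,
        train = strides[[r$label]],
        val = as.integer(cfg$s_ref),
        test = wlen_samples(r))
      slide_windows(r, stride, cfg$window_s)
    })
    ws <- list(windows = do.call(rbind, lapply(parts, `[[`, "windows")),
               labels = unlist(lapply(parts, `[[`, "labels"), use.names = FALSE),
               source_ids = unlist(lapply(parts, `[[`, "source_ids"), use.names = FALSE),
               split = sp)
    class(ws) <- "window_set"
    ws
  })
  attr(out, "class_weights") <- weights
  attr(out, "strides") <- strides
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set (%s): %d windows x %d samples from %d records\n",
              x$split, nrow(x$windows), ncol(x$windows),
              length(unique(x$source_ids))))
  print(table(factor(x$labels, levels = rhythm_classes())))
  invisible(x)
}
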