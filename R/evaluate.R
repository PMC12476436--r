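#' Match predictions to reference teeth by mask overlap
#'
#' Greedy one-to-one assignment: all prediction-reference pairs with
#' IoU at or above the threshold are considered in order of decreasing IoU
#' (ties broken by reference label, then prediction index) and a pair is
#' accepted when both members are still unassigned. Leftover predictions are
#' false positives, leftover reference teeth false negatives. The default
#' threshold of 1/3 corresponds to a Dice coefficient of 1/2; its exact value
#' is uncritical because candidate overlaps concentrate far below or far
#' above it.
#'
#' @param predictions list of [raw_detection()] objects from one image
#' @param references a [reference_annotation()] or a list of
#'   [reference_tooth()] entries; only status `"tooth"` entries take part —
#'   a prediction overlapping only an implant region is a false positive
#' @param iou_threshold matching threshold in `(0, 1]`
#' @return a `matching_result`: `pairs` (data.frame with `pred_index`,
#'   `pred_label`, `ref_label`, `iou`, `correct_label`), `fp_index`,
#'   `fp_label`, `fn_label`, `candidate_ious` (IoUs of all overlapping
#'   candidate pairs, for threshold-robustness checks), `n_pred`, `n_ref`.
#' @export
match_detections <- function(predictions, references, iou_threshold = 1 / 3) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (inherits(references, "reference_annotation")) {
    references <- reference_teeth(references)
  }
  references <- Filter(function(t) t$status == "tooth", references)
  n_pred <- length(predictions)
  n_ref <- length(references)
  pred_labels <- vapply(predictions, `[[`, integer(1), "label")
  ref_labels <- vapply(references, `[[`, integer(1), "label")

  cand <- list(p = integer(0), r = integer(0), iou = numeric(0))
  if (n_pred && n_ref) {
    pb <- t(vapply(predictions, function(d) d$bbox, numeric(4)))
    rb <- t(vapply(references, function(t) mask_bbox(t$mask), numeric(4)))
    for (i in seq_len(n_pred)) {
      hit <- which(rb[, 1] < pb[i, 3] & rb[, 3] > pb[i, 1] &
                     rb[, 2] < pb[i, 4] & rb[, 4] > pb[i, 2])
      for (j in hit) {
        iou <- mask_iou(predictions[[i]]$mask, references[[j]]$mask)
        if (iou > 0) {
          cand$p <- c(cand$p, i); cand$r <- c(cand$r, j)
          cand$iou <- c(cand$iou, iou)
        }
      }
    }
  }

  keep <- cand$iou >= iou_threshold
  ord <- order(-cand$iou[keep], ref_labels[cand$r[keep]], cand$p[keep])
  cp <- cand$p[keep][ord]; cr <- cand$r[keep][ord]; ci <- cand$iou[keep][ord]
  pred_used <- logical(n_pred); ref_used <- logical(n_ref)
  mp <- integer(0); mr <- integer(0); mi <- numeric(0)
  for (k in seq_along(cp)) {
    if (!pred_used[cp[k]] && !ref_used[cr[k]]) {
      pred_used[cp[k]] <- TRUE; ref_used[cr[k]] <- TRUE
      mp <- c(mp, cp[k]); mr <- c(mr, cr[k]); mi <- c(mi, ci[k])
    }
  }
  pairs <- data.frame(
    pred_index = mp,
    pred_label = pred_labels[mp],
    ref_label = ref_labels[mr],
    iou = mi
  )
  pairs$correct_label <- pairs$pred_label == pairs$ref_label
  structure(
    list(pairs = pairs,
         fp_index = which(!pred_used),
         fp_label = pred_labels[!pred_used],
         fn_label = ref_labels[!ref_used],
         candidate_ious = cand$iou,
         n_pred = n_pred, n_ref = n_ref),
    class = "matching_result"
  )
}

.as_matching_list <- function(matchings) {
  if (inherits(matchings, "matching_result")) list(matchings) else matchings
}

#' Tooth-level confusion matrix
#'
#' A 33 x 33 integer matrix: rows are the 32 reference FDI positions plus an
#' FP row for unmatched predictions, columns the 32 predicted positions plus
#' an FN column for missed reference teeth. A matched pair with reference
#' label r and predicted label p increments cell (r, p). The row-normalized
#' variant divides each non-empty row by its sum, revealing errors in less
#' frequent positions.
#'
#' @param matchings a `matching_result` or a list of them (one per image)
#' @return list with `counts` and `normalized` matrices
#' @export
tooth_confusion <- function(matchings) {
  matchings <- .as_matching_list(matchings)
  codes <- as.character(all_fdi_codes())
  m <- matrix(0L, 33L, 33L,
              dimnames = list(reference = c(codes, "FP"),
                              predicted = c(codes, "FN")))
  for (mt in matchings) {
    stopifnot(inherits(mt, "matching_result"))
    for (k in seq_len(nrow(mt$pairs))) {
      r <- as.character(mt$pairs$ref_label[k])
      p <- as.character(mt$pairs$pred_label[k])
      m[r, p] <- m[r, p] + 1L
    }
    for (l in mt$fn_label) m[as.character(l), "FN"] <- m[as.character(l), "FN"] + 1L
    for (l in mt$fp_label) m["FP", as.character(l)] <- m["FP", as.character(l)] + 1L
  }
  rs <- rowSums(m)
  norm <- m / ifelse(rs > 0, rs, 1)
  list(counts = m, normalized = norm)
}

#' Detection counts of a matching
#'
#' @param matchings a `matching_result` or a list of them
#' @return named integer vector: `tp` (matched predictions, regardless of
#'   label), `fp`, `fn`, `correct_label`, `mislabeled`
#' @export
detection_counts <- function(matchings) {
  matchings <- .as_matching_list(matchings)
  tp <- sum(vapply(matchings, function(m) nrow(m$pairs), integer(1)))
  correct <- sum(vapply(matchings, function(m) sum(m$pairs$correct_label), integer(1)))
  c(tp = tp,
    fp = sum(vapply(matchings, function(m) length(m$fp_label), integer(1))),
    fn = sum(vapply(matchings, function(m) length(m$fn_label), integer(1))),
    correct_label = correct,
    mislabeled = tp - correct)
}

.safe_ratio <- function(num, den) {
  if (is.na(den) || den <= 0) NA_real_ else num / den
}

#' Detection and labeling rates from integer counts
#'
#' The single source of truth for the metric definitions:
#' sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2 TP/(2 TP+FP+FN), label accuracy = correctly labeled matches / TP.
#' Specificity needs true negatives, which pure detection does not have; the
#' position-level definition used here counts every absent FDI position
#' (`total_positions` minus reference teeth) not consumed by a false positive
#' as a true negative: specificity = TN/(TN+FP) with
#' TN = absent positions - FP.
#'
#' Matched-but-mislabeled predictions count as TP for the detection rates and
#' as errors only for label accuracy. Zero denominators yield `NA`
#' (undefined), never 0.
#'
#' @param tp,fp,fn integer detection counts
#' @param correct_label matched predictions with the correct FDI label
#'   (`NA` if unknown)
#' @param total_positions total FDI position slots evaluated
#'   (32 per image; `NA` disables specificity)
#' @return list of counts and rates (rates as fractions in `[0, 1]`)
#' @export
rates_from_counts <- function(tp, fp, fn, correct_label = NA,
                              total_positions = NA) {
  absent <- if (is.na(total_positions)) NA_real_ else total_positions - (tp + fn)
  tn <- if (is.na(absent)) NA_real_ else absent - fp
  list(
    tp = tp, fp = fp, fn = fn,
    correct_label = correct_label,
    mislabeled = if (is.na(correct_label)) NA_integer_ else tp - correct_label,
    tn = tn,
    sensitivity = .safe_ratio(tp, tp + fn),
    precision = .safe_ratio(tp, tp + fp),
    f1 = .safe_ratio(2 * tp, 2 * tp + fp + fn),
    label_accuracy = if (is.na(correct_label)) NA_real_ else .safe_ratio(correct_label, tp),
    specificity = if (is.na(tn)) NA_real_ else .safe_ratio(tn, tn + fp)
  )
}

#' Metric summary of one or more matchings
#'
#' @param matchings a `matching_result` or a list of them
#' @param total_positions total FDI position slots in the evaluated images
#'   (32 per image), needed for the position-level specificity
#' @return as [rates_from_counts()]
#' @export
metric_summary <- function(matchings, total_positions = NA) {
  ct <- detection_counts(matchings)
  rates_from_counts(ct[["tp"]], ct[["fp"]], ct[["fn"]],
                    correct_label = ct[["correct_label"]],
                    total_positions = total_positions)
}

#' Kennedy-level confusion matrix
#'
#' @param predicted,reference character vectors of per-jaw classes
#'   (values from [kennedy_levels()]), aligned
#' @param jaw optional character vector (`"upper"`/`"lower"`) for a per-jaw
#'   accuracy split
#' @return list with the 5 x 5 `counts` matrix (rows reference, columns
#'   predicted), overall `accuracy` (fraction), `n`, and `by_jaw` accuracies
#'   when `jaw` is given
#' @export
kennedy_confusion <- function(predicted, reference, jaw = NULL) {
  lev <- kennedy_levels()
  if (length(predicted) != length(reference)) {
    stop("predicted and reference class vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(predicted, reference)), lev)
  if (length(bad)) stop("unknown Kennedy class: ", bad[1L], call. = FALSE)
  counts <- table(reference = factor(reference, lev),
                  predicted = factor(predicted, lev))
  counts <- unclass(counts)
  out <- list(counts = counts,
              accuracy = .safe_ratio(sum(diag(counts)), sum(counts)),
              n = length(reference))
  if (!is.null(jaw)) {
    stopifnot(length(jaw) == length(reference))
    out$by_jaw <- vapply(split(predicted == reference, jaw), mean, numeric(1))
  }
  out
}

#' Evaluate a corpus of (post-processed) detections against references
#'
#' Runs per-image matching, accumulates the tooth and Kennedy confusion
#' matrices, and computes the scalar metric summary. Kennedy classes of the
#' predictions are derived via [presence_from_detections()] and
#' [classify_jaw()]; reference classes are taken from the annotations.
#'
#' @param detections_by_image list of detection lists, aligned with `references`
#' @param references list of [reference_annotation()] objects
#' @param iou_threshold matching threshold, default 1/3
#' @return an `evaluation_report`: `matchings`, `tooth` (confusion matrices),
#'   `metrics`, `kennedy` (confusion, accuracy, per-jaw split), `jaws`
#'   (per-jaw class data.frame), `candidate_ious`, `n_images`
#' @export
evaluate_corpus <- function(detections_by_image, references, iou_threshold = 1 / 3) {
  stopifnot(length(detections_by_image) == length(references))
  matchings <- vector("list", length(references))
  jaws <- vector("list", length(references))
  for (i in seq_along(references)) {
    ann <- references[[i]]
    matchings[[i]] <- match_detections(detections_by_image[[i]], ann,
                                       iou_threshold = iou_threshold)
    maps <- presence_from_detections(detections_by_image[[i]])
    jaws[[i]] <- data.frame(
      image_id = rep(ann$image_id, 2L),
      jaw = c("upper", "lower"),
      reference = unname(ann$kennedy[c("upper", "lower")]),
      predicted = c(classify_jaw(maps$upper), classify_jaw(maps$lower)),
      stringsAsFactors = FALSE
    )
  }
  jaws <- do.call(rbind, jaws)
  structure(
    list(matchings = matchings,
         tooth = tooth_confusion(matchings),
         metrics = metric_summary(matchings,
                                  total_positions = 32L * length(references)),
         kennedy = kennedy_confusion(jaws$predicted, jaws$reference, jaws$jaw),
         jaws = jaws,
         candidate_ious = unlist(lapply(matchings, `[[`, "candidate_ious")),
         n_images = length(references)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Evaluation of %d images (%d jaws)\n", x$n_images, x$kennedy$n))
  cat(sprintf("  detections: TP %d, FP %d, FN %d (mislabeled %d)\n",
              m$tp, m$fp, m$fn, m$mislabeled))
  cat(sprintf("  sensitivity %.1f%%  precision %.1f%%  F1 %.1f%%  specificity %.1f%%\n",
              100 * m$sensitivity, 100 * m$precision, 100 * m$f1,
              100 * m$specificity))
  cat(sprintf("  label accuracy %.1f%%\n", 100 * m$label_accuracy))
  cat(sprintf("  Kennedy accuracy %.1f%% (upper %.1f%%, lower %.1f%%)\n",
              100 * x$kennedy$accuracy,
              100 * x$kennedy$by_jaw[["upper"]],
              100 * x$kennedy$by_jaw[["lower"]]))
  invisible(x)
}

#' Ablation harness over post-processing configurations
#'
#' Re-runs post-processing and evaluation of one corpus under several filter
#' configurations and tabulates the counts the filter stages trade off:
#' surviving detections, TP, FP, FN, mislabeled teeth, label accuracy, and
#' Kennedy accuracy.
#'
#' @param detections_by_image list of *raw* detection lists
#' @param references list of [reference_annotation()] objects
#' @param configs named list of [postprocess_config()] objects
#' @param iou_threshold matching threshold
#' @return a data.frame, one row per configuration
#' @export
ablation_run <- function(detections_by_image, references, configs,
                         iou_threshold = 1 / 3) {
  stopifnot(length(configs) >= 1L)
  if (is.null(names(configs))) names(configs) <- paste0("config", seq_along(configs))
  rows <- lapply(names(configs), function(nm) {
    filtered <- postprocess_corpus(detections_by_image, configs[[nm]])
    rep <- evaluate_corpus(filtered, references, iou_threshold = iou_threshold)
    m <- rep$metrics
    data.frame(
      config = nm,
      n_selected = sum(lengths(filtered)),
      tp = m$tp, fp = m$fp, fn = m$fn, mislabeled = m$mislabeled,
      label_accuracy = m$label_accuracy,
      sensitivity = m$sensitivity,
      precision = m$precision,
      kennedy_accuracy = rep$kennedy$accuracy,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
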