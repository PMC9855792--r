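#' Infer treatment recommendations for a cohort
#'
#' For every (case, target) pair, the evidence is the case's non-missing
#' observable values (missing values are simply omitted and therefore
#' marginalized by exact inference); the posterior P(true), the argmax
#' prediction and the recorded truth label are returned. Target nodes are
#' never used as evidence for each other. Cases carrying an invalid state
#' label are flagged, not silently dropped: their records are emitted with
#' `flagged = TRUE` and `NA` posteriors, and are excluded from metric
#' denominators downstream.
#'
#' @param object a `"bn"` or `"bn_fit"` network.
#' @param newdata cohort data frame (columns = observable/target variables;
#'   `NA` = missing).
#' @param targets target nodes to infer (default all target-role nodes).
#' @param ... unused.
#' @return Data frame of class `"bn_predictions"`: `case_id`, `target`,
#'   `p_true`, `predicted`, `truth`, `evidence_complete`, `flagged`.
#' @export
predict.bn <- function(object, newdata, targets = bn_targets(object), ...) {
  stopifnot(all(targets %in% names(object$variables)))
  obs <- setdiff(bn_observables(object), targets)
  obs <- intersect(obs, names(newdata))
  n <- nrow(newdata)
  case_id <- if ("case_id" %in% names(newdata)) {
    as.character(newdata$case_id)
  } else sprintf("case_%04d", seq_len(n))

  flagged <- rep(FALSE, n)
  for (v in obs) {
    flagged <- flagged |
      (!is.na(newdata[[v]]) & !(newdata[[v]] %in% object$variables[[v]]))
  }
  ev_key <- do.call(paste, c(lapply(obs, function(v) {
    ifelse(is.na(newdata[[v]]), "", newdata[[v]])
  }), sep = "\r"))
  if (n == 0L) ev_key <- character()

  cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (flagged[i]) {
      p <- rep(NA_real_, length(targets))
    } else if (!is.null(cache[[ev_key[i]]])) {
      p <- cache[[ev_key[i]]]
    } else {
      ev <- lapply(obs, function(v) newdata[[v]][i])
      names(ev) <- obs
      ev <- ev[!vapply(ev, is.na, TRUE)]
      p <- vapply(targets, function(trt) {
        bn_posterior(object, ev, trt)[["true"]]
      }, 1.0)
      cache[[ev_key[i]]] <- p
    }
    rows[[i]] <- p
  }
  p_true <- unlist(rows, use.names = FALSE)
  if (n == 0L) p_true <- numeric()
  ev_complete <- if (length(obs) == 0L) rep(TRUE, n) else
    !Reduce(`|`, lapply(obs, function(v) is.na(newdata[[v]])))

  # rows[[i]] holds all targets for case i (case-major order)
  out <- data.frame(
    case_id = rep(case_id, each = length(targets)),
    target = rep(targets, times = n),
    p_true = p_true,
    stringsAsFactors = FALSE
  )
  out$predicted <- ifelse(is.na(out$p_true), NA_character_,
                          ifelse(out$p_true > 0.5, "true", "false"))
  truth_by_case <- as.data.frame(lapply(targets, function(trt) {
    if (trt %in% names(newdata)) as.character(newdata[[trt]]) else rep(NA_character_, n)
  }), col.names = targets, stringsAsFactors = FALSE)
  out$truth <- if (n == 0L) character() else
    as.vector(t(as.matrix(truth_by_case)))
  out$evidence_complete <- rep(ev_complete, each = length(targets))
  out$flagged <- rep(flagged, each = length(targets))
  class(out) <- c("bn_predictions", "data.frame")
  out
}

# usable (case, target) records for metric computation
metric_rows <- function(preds) {
  preds[!preds$flagged & !is.na(preds$predicted) & !is.na(preds$truth), ,
        drop = FALSE]
}

#' Per-target and overall prediction accuracy
#'
#' Fraction of (case, target) records whose argmax prediction equals the
#' recorded therapy, per target and pooled over all targets; the overall
#' correct count is by construction the sum of the per-target correct
#' counts.
#'
#' @param preds a `"bn_predictions"` data frame.
#' @return List of class `"bn_accuracy"` with `per_target` (data frame
#'   `target`, `correct`, `total`, `accuracy`) and `overall`.
#' @export
accuracy <- function(preds) {
  use <- metric_rows(preds)
  tg <- unique(preds$target)
  per <- do.call(rbind, lapply(tg, function(trt) {
    sub <- use[use$target == trt, , drop = FALSE]
    data.frame(target = trt, correct = sum(sub$predicted == sub$truth),
               total = nrow(sub),
               accuracy = if (nrow(sub) == 0L) NA_real_ else
                 sum(sub$predicted == sub$truth) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  res <- list(per_target = per,
              overall = data.frame(correct = sum(per$correct),
                                   total = sum(per$total),
                                   accuracy = sum(per$correct) / sum(per$total)))
  class(res) <- "bn_accuracy"
  res
}

#' @export
print.bn_accuracy <- function(x, ...) {
  cat("Accuracy (absolute and relative numbers)\n")
  all_row <- data.frame(target = "all nodes", correct = x$overall$correct,
                        total = x$overall$total, accuracy = x$overall$accuracy)
  tab <- rbind(all_row, x$per_target)
  tab$fraction <- sprintf("%d/%d", tab$correct, tab$total)
  tab$accuracy <- sprintf("%.4f (%.0f%%)", tab$accuracy, 100 * tab$accuracy)
  print(tab[, c("target", "fraction", "accuracy")], row.names = FALSE)
  invisible(x)
}

#' F1 scores for a binary target
#'
#' Harmonic mean of precision and recall, computed twice — once with each
#' class (`"true"`, `"false"`) taken as the positive class — plus the
#' average weighted by the true-class frequencies. A class with no true and
#' no predicted members has an undefined F1, reported as 0 by convention
#' (the weighted average then effectively ignores it, since its weight is
#' 0).
#'
#' @param preds a `"bn_predictions"` data frame.
#' @param target target node name.
#' @return Named numeric vector `f1_positive`, `f1_negative`, `weighted`.
#' @export
f1_scores <- function(preds, target) {
  sub <- metric_rows(preds)
  sub <- sub[sub$target == target, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no usable records for target ", target, call. = FALSE)
  f1_of <- function(cls) {
    tp <- sum(sub$truth == cls & sub$predicted == cls)
    fp <- sum(sub$truth != cls & sub$predicted == cls)
    fn <- sum(sub$truth == cls & sub$predicted != cls)
    if (2 * tp + fp + fn == 0) return(0) # undefined -> 0 by convention
    2 * tp / (2 * tp + fp + fn)
  }
  f1p <- f1_of("true")
  f1n <- f1_of("false")
  wp <- mean(sub$truth == "true")
  c(f1_positive = f1p, f1_negative = f1n,
    weighted = wp * f1p + (1 - wp) * f1n)
}

#' ROC curve and AUC for one target
#'
#' Sweeps a decision threshold over the distinct posterior values of
#' P(true) and reports (false positive rate, true positive rate) points and
#' the trapezoidal area under the curve. With a single-class truth vector
#' the curve is undefined; an explicit marker is returned instead of a
#' number, mirroring the convention of omitting such curves.
#'
#' @param preds a `"bn_predictions"` data frame.
#' @param target target node name.
#' @return List of class `"bn_roc"`: either `undefined = TRUE` with a
#'   `reason`, or `points` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(preds, target) {
  sub <- metric_rows(preds)
  sub <- sub[sub$target == target, , drop = FALSE]
  y <- sub$truth == "true"
  s <- sub$p_true
  res <- if (length(unique(y)) < 2L) {
    list(target = target, undefined = TRUE,
         reason = "single-class truth: no positives or no negatives")
  } else {
    o <- order(s, decreasing = TRUE)
    y <- y[o]; s <- s[o]
    last <- !duplicated(s, fromLast = TRUE) # last index of each distinct score
    tp <- cumsum(y)[last]
    fp <- cumsum(!y)[last]
    pts <- data.frame(threshold = s[last], fpr = fp / sum(!y),
                      tpr = tp / sum(y))
    pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
    auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
    list(target = target, undefined = FALSE, points = pts, auc = auc)
  }
  class(res) <- "bn_roc"
  res
}

#' @export
print.bn_roc <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("ROC for %s: undefined (%s)\n", x$target, x$reason))
  } else {
    cat(sprintf("ROC for %s: AUC = %.4f (%d points)\n", x$target, x$auc,
                nrow(x$points)))
  }
  invisible(x)
}

# Average precision by step interpolation: sum over recall increments of the
# precision at that threshold.
step_ap <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  pred_pos <- seq_along(y)[last]
  prec <- tp / pred_pos
  rec <- tp / sum(y)
  data.frame(threshold = s[last], precision = prec, recall = rec,
             ap = sum(diff(c(0, rec)) * prec))
}

#' Precision-recall curves and average precision for one target
#'
#' Computes the precision-recall step curve and its area (average
#' precision, AP) for each class orientation of a binary target: the
#' `"true"` class scored by P(true) and the `"false"` class scored by
#' 1 - P(true). A class with no true members is omitted with an explicit
#' marker rather than a curve. The micro-averaged AP pools the
#' (score, label) pairs of both orientations before computing a single
#' curve.
#'
#' @param preds a `"bn_predictions"` data frame.
#' @param target target node name.
#' @return List of class `"bn_pr"` with per-class entries (each either
#'   `points` + `ap` or an omission marker) and `micro_ap`.
#' @export
pr_curve <- function(preds, target) {
  sub <- metric_rows(preds)
  sub <- sub[sub$target == target, , drop = FALSE]
  orient <- list(true = list(scores = sub$p_true, labels = sub$truth == "true"),
                 false = list(scores = 1 - sub$p_true, labels = sub$truth == "false"))
  classes <- lapply(orient, function(cl) {
    if (sum(cl$labels) == 0L) {
      list(omitted = TRUE, reason = "no positive cases for this class")
    } else {
      tab <- step_ap(cl$scores, cl$labels)
      list(omitted = FALSE,
           points = tab[, c("threshold", "precision", "recall")],
           ap = tab$ap[1L])
    }
  })
  pooled_scores <- c(orient$true$scores, orient$false$scores)
  pooled_labels <- c(orient$true$labels, orient$false$labels)
  micro_ap <- if (sum(pooled_labels) == 0L) NA_real_ else
    step_ap(pooled_scores, pooled_labels)$ap[1L]
  res <- list(target = target, classes = classes, micro_ap = micro_ap)
  class(res) <- "bn_pr"
  res
}

#' @export
print.bn_pr <- function(x, ...) {
  cat(sprintf("Precision-recall for %s:\n", x$target))
  for (cls in names(x$classes)) {
    cl <- x$classes[[cls]]
    if (isTRUE(cl$omitted)) {
      cat(sprintf("  class %-5s: omitted (%s)\n", cls, cl$reason))
    } else {
      cat(sprintf("  class %-5s: AP = %.4f\n", cls, cl$ap))
    }
  }
  cat(sprintf("  micro-averaged AP over both classes: %.4f\n", x$micro_ap))
  invisible(x)
}

#' Full validation report
#'
#' Bundles accuracy, per-target F1, ROC and precision-recall summaries (and
#' optionally a cross-validation result) into one object whose print method
#' mirrors the accuracy and F1 report tables of clinical decision-support
#' validations.
#'
#' @param preds a `"bn_predictions"` data frame.
#' @param cv optional `"bn_cv"` object.
#' @param provenance optional named list (seed, hashes, versions) embedded
#'   verbatim in the report.
#' @return List of class `"bn_metrics_report"`.
#' @export
metrics_report <- function(preds, cv = NULL, provenance = NULL) {
  tg <- unique(preds$target)
  res <- list(
    accuracy = accuracy(preds),
    f1 = stats::setNames(lapply(tg, function(t) f1_scores(preds, t)), tg),
    roc = stats::setNames(lapply(tg, function(t) roc_curve(preds, t)), tg),
    pr = stats::setNames(lapply(tg, function(t) pr_curve(preds, t)), tg),
    class_counts = stats::setNames(lapply(tg, function(t) {
      sub <- metric_rows(preds); sub <- sub[sub$target == t, ]
      c(positive = sum(sub$truth == "true"), negative = sum(sub$truth == "false"))
    }), tg),
    cv = cv,
    provenance = provenance
  )
  class(res) <- "bn_metrics_report"
  res
}

#' @export
print.bn_metrics_report <- function(x, ...) {
  print(x$accuracy)
  cat("\nF1 measure\n")
  tab <- do.call(rbind, lapply(names(x$f1), function(t) {
    data.frame(target = t,
               positive_cases = x$class_counts[[t]][["positive"]],
               negative_cases = x$class_counts[[t]][["negative"]],
               f1_positive = round(x$f1[[t]][["f1_positive"]], 3),
               f1_negative = round(x$f1[[t]][["f1_negative"]], 3),
               weighted_f1 = round(x$f1[[t]][["weighted"]], 3),
               stringsAsFactors = FALSE)
  }))
  print(tab, row.names = FALSE)
  cat("\n")
  for (t in names(x$roc)) print(x$roc[[t]])
  cat("\n")
  for (t in names(x$pr)) print(x$pr[[t]])
  if (!is.null(x$cv)) { cat("\n"); print(x$cv) }
  invisible(x)
}

#' Export a validation report
#'
#' Writes the report as structured JSON; ROC and precision-recall points
#' can additionally be exported as CSV files for external plotting.
#'
#' @param report a `"bn_metrics_report"`.
#' @param path output JSON path.
#' @param points_dir optional directory for per-target `roc_<target>.csv` /
#'   `pr_<target>_<class>.csv` point files.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, points_dir = NULL) {
  doc <- list(
    provenance = report$provenance,
    accuracy = list(per_target = report$accuracy$per_target,
                    overall = as.list(report$accuracy$overall)),
    f1 = lapply(report$f1, as.list),
    class_counts = lapply(report$class_counts, as.list),
    roc = lapply(report$roc, function(r) {
      if (isTRUE(r$undefined)) list(undefined = TRUE, reason = r$reason)
      else list(undefined = FALSE, auc = r$auc)
    }),
    pr = lapply(report$pr, function(p) {
      list(classes = lapply(p$classes, function(cl) {
        if (isTRUE(cl$omitted)) list(omitted = TRUE, reason = cl$reason)
        else list(omitted = FALSE, ap = cl$ap)
      }), micro_ap = p$micro_ap)
    }),
    cv = if (!is.null(report$cv)) {
      list(k = report$cv$k, fold_accuracy = report$cv$fold_accuracy,
           mean_accuracy = report$cv$mean_accuracy, seed = report$cv$seed)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(points_dir)) {
    dir.create(points_dir, showWarnings = FALSE, recursive = TRUE)
    for (t in names(report$roc)) {
      r <- report$roc[[t]]
      if (!isTRUE(r$undefined)) {
        utils::write.csv(r$points, file.path(points_dir, paste0("roc_", t, ".csv")),
                         row.names = FALSE)
      }
      p <- report$pr[[t]]
      for (cls in names(p$classes)) {
        cl <- p$classes[[cls]]
        if (!isTRUE(cl$omitted)) {
          utils::write.csv(cl$points,
                           file.path(points_dir, sprintf("pr_%s_%s.csv", t, cls)),
                           row.names = FALSE)
        }
      }
    }
  }
  invisible(path)
}
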