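#' Pipeline configuration for a leave-one-patient-out run
#'
#' Bundles every stage default: temporal resampling length, spatial size,
#' flow backend settings, kinematic channels, network and forest training
#' configs, classification mode and the patient-level aggregation rule.
#'
#' @param target_len Cardiac-cycle length after resampling (frames).
#' @param size Spatial side length of preprocessed frames (px).
#' @param channels Kinematic channels used as network input.
#' @param eps Speed floor for acceleration channels (px/frame).
#' @param flow A [flow_config].
#' @param net A [conv3d_config].
#' @param forest A [forest_config].
#' @param mode `"rf"` (per-kinematic embeddings fused into a random forest)
#'   or `"e2e"` (one softmax network over all channels).
#' @param embedding_layer Dense layer the embeddings are read from.
#' @param aggregate `"majority"` (slice-vote) or `"mean_prob"` patient-level
#'   aggregation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_len = 13L, size = 128L,
                            channels = c("a_N", "div", "vor"), eps = 1e-3,
                            flow = flow_config(), net = conv3d_config(),
                            forest = forest_config(), mode = c("rf", "e2e"),
                            embedding_layer = "dense_1",
                            aggregate = c("majority", "mean_prob")) {
  structure(list(target_len = as.integer(target_len), size = as.integer(size),
                 channels = channels, eps = eps, flow = flow, net = net,
                 forest = forest, mode = match.arg(mode),
                 embedding_layer = embedding_layer,
                 aggregate = match.arg(aggregate)),
            class = "pipeline_config")
}

#' Leave-one-patient-out folds
#'
#' One fold per patient; each fold trains on every other patient's samples.
#'
#' @param cohort List of [cine_sequence]s (several slices per patient
#'   allowed).
#' @return A list of folds, each `list(train_ids, test_id)`; the `test_id`s
#'   enumerate every patient exactly once.
#' @export
lopo_split <- function(cohort) {
  ids <- unique(vapply(cohort, function(s) s$patient_id, character(1)))
  if (length(ids) < 2L)
    stopf("leave-one-patient-out needs >= 2 patients, got %d", length(ids))
  lapply(ids, function(id) list(train_ids = setdiff(ids, id), test_id = id))
}

#' Aggregate slice-level predictions to one patient-level label
#'
#' Majority vote over slice predictions; ties are broken toward the
#' lexicographically first label.
#'
#' @param per_slice Non-empty character vector of predicted labels.
#' @return A single label.
#' @export
aggregate_patient <- function(per_slice) {
  if (length(per_slice) == 0L) stopf("no slice predictions to aggregate")
  tab <- table(per_slice)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Classification metrics from prediction/truth pairs
#'
#' Accuracy plus macro-averaged precision and recall over the classes
#' present in the truth; F1 is the harmonic mean of macro precision and
#' macro recall. The confusion matrix (rows = truth, columns = predicted)
#' is stored so every metric is recomputable from it.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param classes Known label set; defaults to the classes present in
#'   `truth`. A predicted label outside this set is an error.
#' @param task Optional task name carried into the report.
#' @return A `metrics_report` with fields `accuracy`, `precision`, `recall`,
#'   `f1` (fractions in `[0, 1]`), `confusion`, `n`.
#' @export
compute_metrics <- function(predicted, truth, classes = NULL, task = "") {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stopf("predicted/truth must be non-empty and of equal length")
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(truth))
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad))
    stopf("unknown label(s): %s (known: %s)", paste(bad, collapse = ", "),
          paste(classes, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  prec <- rec <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
  }
  present <- rowSums(cm) > 0
  mp <- mean(prec[present]); mr <- mean(rec[present])
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  structure(list(task = task, accuracy = mean(predicted == truth),
                 precision = mp, recall = mr, f1 = f1,
                 confusion = cm, n = length(truth), classes = classes),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report>%s n = %d\n",
              if (nzchar(x$task)) paste0(" ", x$task, ":") else "", x$n))
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

prepare_sample <- function(seq, config) {
  s <- resample_cycle(seq, config$target_len)
  s <- preprocess_frames(s, config$size)
  fs <- estimate_flow_sequence(s, config$flow)
  list(seq = s, flow = fs)
}

task_spec <- function(task) {
  if (is.character(task) && length(task) == 2L)
    return(list(type = "pairwise", pair = task))
  if (identical(task, "triage")) return(list(type = "triage"))
  if (identical(task, "multi")) return(list(type = "multi"))
  stopf("task must be 'triage', 'multi', or a pair of class labels")
}

#' Run the full leave-one-patient-out evaluation
#'
#' For each fold: trains the flow -> kinematics -> 3D network stage (and, in
#' `"rf"` mode, one network per kinematic channel whose embeddings are fused
#' into a random forest) on the training patients only, predicts the
#' held-out patient's slices, and aggregates them to a patient-level label.
#' Flow fields and kinematic stacks are computed once per sample (they are
#' unsupervised and patient-local, so no information crosses folds). Fully
#' seeded and deterministic.
#'
#' @param cohort List of [cine_sequence]s.
#' @param task `"triage"` (pathology vs N), `"multi"`, or a length-2
#'   character vector naming a class pair, e.g. `c("DCM", "N")`.
#' @param config A [pipeline_config].
#' @param seed Master seed; per-fold substream seeds are derived from it.
#' @return A `lopo_result`: list with `folds` (per-fold predictions and
#'   training-patient ids), `metrics` (patient-level `metrics_report`),
#'   `task`, `seed`.
#' @export
run_lopo <- function(cohort, task, config = pipeline_config(), seed = 0L) {
  ts <- task_spec(task)
  labels <- vapply(cohort, function(s) s$label, character(1))
  if (ts$type == "pairwise") {
    keep <- labels %in% ts$pair
    cohort <- cohort[keep]; labels <- labels[keep]
    if (length(unique(labels)) < 2L)
      stopf("pairwise task %s vs %s needs samples of both classes",
            ts$pair[1], ts$pair[2])
  }
  eff_labels <- if (ts$type == "triage") triage_labels(labels) else labels

  prepared <- lapply(cohort, prepare_sample, config = config)
  pids <- vapply(cohort, function(s) s$patient_id, character(1))
  slices <- vapply(cohort, function(s) s$slice_index, integer(1))

  if (config$mode == "rf") {
    stacks_by_ch <- lapply(config$channels, function(ch)
      lapply(prepared, function(p)
        build_kinematic_stack(p$flow, ch, eps = config$eps,
                              frames = p$seq$frames)))
    names(stacks_by_ch) <- config$channels
  } else {
    stacks_all <- lapply(prepared, function(p)
      build_kinematic_stack(p$flow, config$channels, eps = config$eps,
                            frames = p$seq$frames))
  }

  folds <- lopo_split(cohort)
  # fold substream seeds are derived from the held-out patient id (not the
  # fold position) so the run is invariant to cohort ordering
  hash_id <- function(s) {
    v <- utf8ToInt(s)
    sum(v * seq_along(v) * 131) %% 1000003L
  }
  fold_seeds <- vapply(folds, function(f)
    (abs(seed) %% 1000003L) * 2011L + hash_id(f$test_id), numeric(1))
  fold_results <- vector("list", length(folds))
  patient_pred <- character(length(folds))
  patient_true <- character(length(folds))

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr <- which(pids %in% fold$train_ids)
    te <- which(pids == fold$test_id)
    # canonical sample order inside the fold, for cohort-order invariance
    tr <- tr[order(pids[tr], slices[tr])]
    te <- te[order(slices[te])]
    if (length(unique(eff_labels[tr])) < 2L)
      stopf("fold %s: training labels collapse to one class", fold$test_id)
    res <- tryCatch({
      if (config$mode == "rf") {
        ch_seeds <- derive_seeds(fold_seeds[fi], length(config$channels) + 1L)
        emb_tr <- vector("list", length(config$channels))
        emb_te <- vector("list", length(config$channels))
        for (ci in seq_along(config$channels)) {
          st <- stacks_by_ch[[ci]]
          net <- train_binary(st[tr], eff_labels[tr], config = config$net,
                              seed = ch_seeds[ci])
          emb_tr[[ci]] <- lapply(st[tr], extract_embedding, model = net,
                                 layer = config$embedding_layer)
          emb_te[[ci]] <- lapply(st[te], extract_embedding, model = net,
                                 layer = config$embedding_layer)
        }
        fuse_all <- function(embs, idx) fuse_embeddings(
          lapply(embs, `[[`, idx))
        desc_tr <- lapply(seq_along(tr), function(i) fuse_all(emb_tr, i))
        desc_te <- lapply(seq_along(te), function(i) fuse_all(emb_te, i))
        fc <- config$forest; fc$seed <- ch_seeds[length(ch_seeds)]
        forest <- fit_forest(desc_tr, eff_labels[tr], fc)
        forest_predict(forest, desc_te)$labels
      } else {
        net <- train_binary(stacks_all[tr], eff_labels[tr],
                            config = config$net, seed = fold_seeds[fi])
        probs <- predict(net, stacks_all[te])
        colnames(probs)[apply(probs, 1, which.max)]
      }
    }, error = function(e)
      stopf("fold %s failed: %s", fold$test_id, conditionMessage(e)))

    patient_true[fi] <- unique(eff_labels[te])
    patient_pred[fi] <- if (config$aggregate == "majority")
      aggregate_patient(res) else res[1]
    fold_results[[fi]] <- list(
      held_out_patient = fold$test_id,
      train_patients = fold$train_ids,
      per_slice_predictions = data.frame(slice_index = slices[te],
                                         predicted = res,
                                         true = eff_labels[te],
                                         stringsAsFactors = FALSE),
      patient_prediction = patient_pred[fi])
  }

  metrics <- compute_metrics(patient_pred, patient_true,
                             classes = sort(unique(eff_labels)),
                             task = paste0(ts$type,
                               if (ts$type == "pairwise")
                                 paste0(":", paste(ts$pair, collapse = "-"))
                               else ""))
  structure(list(folds = fold_results, metrics = metrics, task = task,
                 config = config, seed = seed),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("<lopo_result> %d folds, seed %d\n", length(x$folds), x$seed))
  print(x$metrics)
  invisible(x)
}

#' Audit a LOPO run for patient leakage
#'
#' Verifies, for every fold, that the held-out patient id is absent from the
#' fold's training-patient set and that the fold test ids partition the
#' cohort's patients.
#'
#' @param result A `lopo_result`.
#' @return `TRUE` invisibly; errors on any leakage.
#' @export
audit_no_leakage <- function(result) {
  stopifnot(inherits(result, "lopo_result"))
  test_ids <- vapply(result$folds, `[[`, character(1), "held_out_patient")
  if (anyDuplicated(test_ids)) stopf("duplicated held-out patients")
  for (f in result$folds)
    if (f$held_out_patient %in% f$train_patients)
      stopf("leakage: patient %s appears in its own training fold",
            f$held_out_patient)
  invisible(TRUE)
}

#' Write a tabular LOPO report
#'
#' Emits the metric summary of one or several LOPO results as a CSV and a
#' Markdown table (rows = tasks, columns = accuracy / F1 / precision /
#' recall in percent, rounded to 2 decimals).
#'
#' @param results A `lopo_result` or named list of them.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the report data frame.
#' @export
write_report <- function(results, dir) {
  if (inherits(results, "lopo_result")) results <- list(results)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(results, function(r) {
    m <- r$metrics
    data.frame(task = m$task, n_patients = m$n,
               accuracy = round(100 * m$accuracy, 2),
               f1 = round(100 * m$f1, 2),
               precision = round(100 * m$precision, 2),
               recall = round(100 * m$recall, 2),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(dir, "report.csv"), row.names = FALSE)
  md <- c("| Task | n | ACC | F1 | Precision | Recall |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %d | %.2f | %.2f | %.2f | %.2f |",
                  df$task, df$n_patients, df$accuracy, df$f1, df$precision,
                  df$recall))
  writeLines(md, file.path(dir, "report.md"))
  invisible(df)
}
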