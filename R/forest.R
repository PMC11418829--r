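#' Random-forest configuration
#'
#' The forest consumes fused embedding descriptors. Only the tree count and
#' maximum depth are tuned (100 trees, depth 60); split criterion (gini),
#' features per split (sqrt of descriptor length) and bootstrap sampling are
#' the forest implementation's documented defaults, frozen here for
#' reproducibility.
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param seed Integer seed.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, max_depth = 60L, seed = 1L) {
  if (n_trees < 1L || max_depth < 1L)
    stopf("n_trees and max_depth must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "forest_config")
}

#' Late-fuse per-kinematic embeddings into a cardiac descriptor
#'
#' Concatenates embedding vectors extracted from independently trained
#' per-kinematic networks of the same sample, in the canonical order
#' `a_N`, `div`, `vor`, then any remaining kinematics alphabetically.
#'
#' @param per_kinematic List of `embedding_vector`s from the same
#'   `(patient_id, slice_index)` sample, one per distinct kinematic channel.
#' @return A `fused_descriptor`: list with `values` (length = sum of
#'   embedding widths, `1024 * K` at default width), `kinematic_order`,
#'   `patient_id`, `slice_index`, `label`.
#' @export
fuse_embeddings <- function(per_kinematic) {
  stopifnot(length(per_kinematic) >= 1L)
  for (e in per_kinematic) stopifnot(inherits(e, "embedding_vector"))
  pids <- vapply(per_kinematic, function(e) e$patient_id, character(1))
  slcs <- vapply(per_kinematic, function(e) e$slice_index, integer(1))
  if (length(unique(pids)) > 1L || length(unique(slcs)) > 1L)
    stopf("embeddings come from different samples: patients %s, slices %s",
          paste(unique(pids), collapse = "/"),
          paste(unique(slcs), collapse = "/"))
  keys <- vapply(per_kinematic, function(e)
    paste(e$kinematic_channels, collapse = "+"), character(1))
  if (anyDuplicated(keys))
    stopf("duplicate kinematic channel(s): %s",
          paste(keys[duplicated(keys)], collapse = ", "))
  canon <- c("a_N", "div", "vor")
  rank <- match(keys, canon)
  ord <- order(ifelse(is.na(rank), length(canon) + 1L, rank),
               keys)
  per_kinematic <- per_kinematic[ord]
  structure(list(values = unname(unlist(lapply(unname(per_kinematic),
                                               `[[`, "values"))),
                 kinematic_order = keys[ord],
                 patient_id = pids[1], slice_index = slcs[1],
                 label = per_kinematic[[1]]$label),
            class = "fused_descriptor")
}

#' @export
length.fused_descriptor <- function(x) length(x$values)

descriptor_matrix <- function(descriptors) {
  if (inherits(descriptors, "fused_descriptor") ||
      inherits(descriptors, "embedding_vector"))
    descriptors <- list(descriptors)
  X <- if (is.matrix(descriptors)) descriptors
  else do.call(rbind, lapply(descriptors, function(d) {
    if (inherits(d, "fused_descriptor") || inherits(d, "embedding_vector"))
      d$values
    else as.numeric(d)
  }))
  dimnames(X) <- list(NULL, paste0("V", seq_len(ncol(X))))
  X
}

#' Map pathology labels for the triage task
#'
#' Collapses the four disease classes (`MINF`, `DCM`, `HCM`, `RV`) to
#' `"pathology"`, leaving `"N"` untouched.
#'
#' @param labels Character vector of cardiac class labels.
#' @return Character vector over `{"pathology", "N"}`.
#' @export
triage_labels <- function(labels) {
  ifelse(labels %in% c("MINF", "DCM", "HCM", "RV"), "pathology", labels)
}

#' Fit the random forest on fused descriptors
#'
#' @param descriptors List of `fused_descriptor`s (or a numeric matrix,
#'   samples x features).
#' @param labels Class label per descriptor (>= 2 classes present). For the
#'   triage task map labels with [triage_labels] first.
#' @param config A [forest_config].
#' @return A `kinematic_forest` wrapping the fitted forest with its config
#'   and training feature count.
#' @export
fit_forest <- function(descriptors, labels, config = forest_config()) {
  X <- descriptor_matrix(descriptors)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stopf("need at least 2 classes to fit the forest, got %d", length(classes))
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df$.label <- factor(labels, levels = classes)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = config$n_trees, max.depth = config$max_depth,
    seed = config$seed, num.threads = 1L, probability = FALSE,
    respect.unordered.factors = TRUE)
  structure(list(forest = fit, config = config, classes = classes,
                 n_features = ncol(X)),
            class = "kinematic_forest")
}

#' Predict with the embedding random forest
#'
#' Each tree votes; the hard label is the majority vote with ties broken
#' toward the lexicographically first class label, and the score is the vote
#' fraction per class.
#'
#' @param model A `kinematic_forest`.
#' @param descriptors List of `fused_descriptor`s or a numeric matrix with
#'   the training feature count.
#' @return A list with `labels` (character) and `scores` (samples x classes
#'   vote-fraction matrix).
#' @export
forest_predict <- function(model, descriptors) {
  stopifnot(inherits(model, "kinematic_forest"))
  X <- descriptor_matrix(descriptors)
  if (ncol(X) != model$n_features)
    stopf("descriptor length %d does not match training length %d",
          ncol(X), model$n_features)
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  pr <- predict(model$forest, data = df, predict.all = TRUE,
                num.threads = 1L)
  votes <- pr$predictions                       # samples x trees (class idx)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(X))
  classes <- model$classes
  scores <- t(apply(votes, 1, function(v)
    tabulate(v, nbins = length(classes)) / length(v)))
  colnames(scores) <- classes
  # majority vote, ties toward the lexicographically first label
  labels <- classes[apply(scores, 1, which.max)]
  list(labels = labels, scores = scores)
}

#' @export
print.kinematic_forest <- function(x, ...) {
  cat(sprintf("<kinematic_forest> %d trees, depth <= %d, %d features, classes [%s]\n",
              x$config$n_trees, x$config$max_depth, x$n_features,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
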