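# Feature sets for the classification proof-of-concept. Core outputs of the
# package are classifier-agnostic trait tables; this module only demonstrates
# that they carry enough signal for species identification.

morphology_feature_cols <- function(summaries) {
  pats <- paste0("^(mean|median|sd)_(",
                 paste(morph_descriptor_cols, collapse = "|"), ")$")
  grep(pats, names(summaries), value = TRUE)
}

movement_feature_cols <- function(summaries) {
  intersect(c("median_step", "mean_step", "sd_step", "iqr_step", "mean_speed",
              "mean_turning", "sd_turning", "net_displacement",
              "gross_displacement", "duration"),
            names(summaries))
}

#' Train a species classifier on labelled trajectory summaries
#'
#' Proof-of-concept trait-based identification: a random forest is trained
#' on per-trajectory summaries from monocultures (where species identity is
#' known) and later applied to mixed cultures. `feature_set = "morphology"`
#' uses the morphology summary columns only; `"morphology+movement"` adds
#' the movement summaries (speed, step, turning, displacement, duration).
#' Performance is reported as classification success = 1 - out-of-bag error
#' (percent), a built-in cross-validation, together with the out-of-bag
#' confusion matrix as row proportions. Class imbalance is surfaced
#' (per-class support is stored and printed) but not corrected.
#'
#' @param summaries a [summarize_trajectories()] table with a `species`
#'   column; rows with missing feature values are dropped with a message.
#' @param feature_set `"morphology"` or `"morphology+movement"`.
#' @param seed integer seed (the forest is stochastic); the caller's RNG
#'   state is preserved.
#' @param ntree number of trees.
#' @return an object of class `species_classifier`: the fitted forest, the
#'   feature columns used, the out-of-bag `confusion` (row proportions sum
#'   to 1), `success` (percent) and per-class `support`.
#' @export
train_classifier <- function(summaries,
                             feature_set = c("morphology",
                                             "morphology+movement"),
                             seed = 1, ntree = 500) {
  feature_set <- match.arg(feature_set)
  require_columns(summaries, "species", "training table")
  feats <- morphology_feature_cols(summaries)
  if (feature_set == "morphology+movement") {
    feats <- c(feats, movement_feature_cols(summaries))
  }
  if (!length(feats)) stop("no feature columns found in `summaries`")
  y <- factor(as.character(summaries$species))
  if (nlevels(y) < 2) {
    stop("training data must contain at least two species", call. = FALSE)
  }
  X <- summaries[, feats, drop = FALSE]
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    message(sum(!ok), " row(s) with missing feature values dropped")
    X <- X[ok, , drop = FALSE]
    y <- droplevels(y[ok])
    if (nlevels(y) < 2) stop("fewer than two species left after dropping NAs")
  }
  if (min(table(y)) < 2) {
    stop("need at least two trajectories per species", call. = FALSE)
  }
  fit <- with_seed(seed, randomForest::randomForest(x = X, y = y,
                                                    ntree = ntree))
  conf <- fit$confusion[, levels(y), drop = FALSE]
  prop <- conf / rowSums(conf)
  success <- 100 * sum(diag(conf)) / sum(conf)
  structure(list(model = fit, feature_cols = feats, feature_set = feature_set,
                 confusion = prop, success = success,
                 support = table(species = y), seed = seed),
            class = "species_classifier")
}

#' @export
print.species_classifier <- function(x, ...) {
  cat(sprintf("<species_classifier: %s, %d features, OOB success %.1f%%>\n",
              x$feature_set, length(x$feature_cols), x$success))
  cat("per-class support:\n")
  print(x$support)
  cat("out-of-bag confusion (row proportions):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Predict species identity for unlabelled trajectories
#'
#' Applies a trained classifier to new trajectory summaries (e.g. from mixed
#' cultures) and returns the majority-vote label together with the vote
#' fraction, so downstream analyses can flag low-confidence assignments as
#' uncertain.
#'
#' @param classifier a [train_classifier()] result.
#' @param summaries trajectory summaries containing the classifier's feature
#'   columns (missing ones raise an error naming them).
#' @return data.frame with `id` (if present), `predicted_species`,
#'   `vote_fraction`, and one vote-fraction column per species.
#' @export
predict_species <- function(classifier, summaries) {
  stopifnot(inherits(classifier, "species_classifier"))
  missing <- setdiff(classifier$feature_cols, names(summaries))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- summaries[, classifier$feature_cols, drop = FALSE]
  votes <- stats::predict(classifier$model, X, type = "prob")
  top <- max.col(votes, ties.method = "first")
  out <- data.frame(
    predicted_species = colnames(votes)[top],
    vote_fraction = votes[cbind(seq_len(nrow(votes)), top)]
  )
  if ("id" %in% names(summaries)) out <- cbind(id = summaries$id, out)
  cbind(out, as.data.frame(votes))
}
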