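# Layer-wise relevance propagation (LRP) for the trained linear SVMs.
# For a linear model the LRP decomposition of the decision score of class k
# is simply R_i = x_i * w_{k,i}; the intercept is not distributed to the
# inputs.  Analyses use the ground-truth class's one-vs-rest weight vector,
# keep only positive scores and normalise each explanation to its maximum.

#' Decompose a prediction into per-input relevance scores
#'
#' Computes the raw linear-LRP relevance `R_i = x_i * w_i` of every input,
#' where `w` is the one-vs-rest weight vector of `class` (normally the
#' recording's ground-truth class).  The intercept is excluded, so
#' `sum(R) = score(class) - b_class` exactly.
#'
#' @param model a [train_svm()] model.
#' @param x a scaled feature vector (same scaler as the training data).
#' @param class the class whose weight vector is used.
#' @return numeric vector of raw relevance scores, one per input.
#' @export
decompose <- function(model, x, class) {
  stopifnot(inherits(model, "linsvm"))
  k <- match(as.character(class), model$classes)
  if (is.na(k))
    stop("unknown class: ", class, call. = FALSE)
  x <- as.numeric(x)
  if (length(x) != ncol(model$W))
    stop("feature vector length does not match the model", call. = FALSE)
  x * model$W[k, ]
}

#' Positive filtering and maximum normalisation of relevance scores
#'
#' Negative scores are set to zero; the remaining scores are divided by the
#' maximum positive score, so each explanation lies in \[0, 1\] with
#' maximum 1.  An all-non-positive input yields an all-zero output.
#'
#' @param r raw relevance scores.
#' @return normalised non-negative relevance scores.
#' @export
positive_normalize <- function(r) {
  r <- pmax(r, 0)
  m <- max(r)
  if (m > 0) r / m else r
}

#' Relevance scores for every recording of a cross-validation run
#'
#' For each outer fold, scales the fold's test recordings with that fold's
#' training scaler and decomposes them with that fold's model using the
#' ground-truth class weight vector, so every recording is explained by the
#' model that saw it as test data.
#'
#' @param cv a [run_task()] result.
#' @param features the unscaled feature matrix the run was made from.
#' @param metadata the matching metadata.
#' @param normalize apply [positive_normalize()] per recording (default
#'   TRUE; FALSE keeps raw signed scores).
#' @return an object of class `relevance_map`: `scores` (matrix, rows
#'   aligned with `metadata`), `metadata` (with fold and class columns) and
#'   the `normalized` flag.
#' @export
relevance_scores <- function(cv, features, metadata, normalize = TRUE) {
  stopifnot(inherits(cv, "grf_cv"))
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(cv$folds))
  scores <- matrix(NA_real_, nrow(features), ncol(features))
  for (f in seq_len(cv$k)) {
    te <- which(cv$folds == f)
    xte <- apply_minmax(cv$scalers[[f]], features[te, , drop = FALSE])
    for (j in seq_along(te)) {
      r <- decompose(cv$models[[f]], xte[j, ],
                     as.character(cv$labels[te[j]]))
      scores[te[j], ] <- if (normalize) positive_normalize(r) else r
    }
  }
  meta <- metadata
  meta$fold <- cv$folds
  meta$class <- as.character(cv$labels)
  structure(list(scores = scores, metadata = meta, task = cv$task,
                 normalized = normalize), class = "relevance_map")
}

#' Aggregate relevance maps over the task, classes or subjects
#'
#' Sums the (normalised, non-negative) relevance scores across all
#' recordings of each group, per input position.  With the default
#' 101-point curves the 303 positions fold into a 101 x 3 per-timepoint
#' matrix (columns ML, AP, V); channel totals are its column sums.  Mean
#' input curves of each group are included when `features` is supplied,
#' for colour-coded curve plots.
#'
#' @param rel a [relevance_scores()] result (or any list with `scores` and
#'   `metadata`).
#' @param group_by `"task"` (one aggregate over everything), `"class"` or
#'   `"subject"`.
#' @param features optional unscaled feature matrix for mean input curves.
#' @return an object of class `relevance_aggregate`: a named list of
#'   groups, each with `per_timepoint` (n_points x 3), `channel_totals`
#'   (named ML/AP/V), `n` and optionally `mean_curves`.
#' @export
aggregate_relevance <- function(rel, group_by = c("task", "class", "subject"),
                                features = NULL) {
  group_by <- match.arg(group_by)
  scores <- rel$scores
  meta <- rel$metadata
  key <- switch(group_by,
    task = rep("all", nrow(scores)),
    class = meta$class,
    subject = as.character(meta$subject_id)
  )
  if (length(unique(key)) == 0 || nrow(scores) == 0)
    stop("empty group: no relevance maps to aggregate", call. = FALSE)
  n_points <- ncol(scores) / 3
  groups <- lapply(split(seq_len(nrow(scores)), key), function(idx) {
    tot <- colSums(scores[idx, , drop = FALSE])
    per_tp <- matrix(tot, n_points, 3,
                     dimnames = list(NULL, c("ML", "AP", "V")))
    out <- list(per_timepoint = per_tp,
                channel_totals = colSums(per_tp),
                n = length(idx))
    if (!is.null(features))
      out$mean_curves <- matrix(colMeans(features[idx, , drop = FALSE]),
                                n_points, 3,
                                dimnames = list(NULL, c("ML", "AP", "V")))
    out
  })
  structure(list(groups = groups, group_by = group_by,
                 normalized = isTRUE(rel$normalized)),
            class = "relevance_aggregate")
}

#' @export
print.relevance_aggregate <- function(x, ...) {
  cat(sprintf("Relevance aggregate by %s (%d group%s)\n", x$group_by,
              length(x$groups), if (length(x$groups) == 1) "" else "s"))
  for (g in names(x$groups)) {
    ct <- x$groups[[g]]$channel_totals
    cat(sprintf("  %s (n = %d): ML %.1f | AP %.1f | V %.1f\n", g,
                x$groups[[g]]$n, ct["ML"], ct["AP"], ct["V"]))
  }
  invisible(x)
}
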