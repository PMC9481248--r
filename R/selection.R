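#' Pearson correlation matrix of trial features
#'
#' @param table Feature table (see [build_feature_table()]).
#' @param features Character vector of numeric feature columns; defaults
#'   to every numeric engineered feature in the table.
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   columns have undefined correlations, reported as 0 with a warning.
#' @export
correlation_matrix <- function(table, features = NULL) {
  if (nrow(table) < 2L) stop("need at least 2 rows for correlations")
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        c("trial_index"))
  }
  x <- as.matrix(table[features])
  const <- apply(x, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  if (any(const)) {
    warning("constant feature(s) with undefined correlation reported as 0: ",
            paste(features[const], collapse = ", "))
    r[const, ] <- 0; r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Greedy collinearity pruning
#'
#' While any off-diagonal pair exceeds `threshold` in absolute
#' correlation, drops the non-pinned member of the worst pair with the
#' larger mean absolute correlation to all remaining features (ties broken
#' lexicographically by feature name). Mirrors the practice of removing
#' highly inter-correlated covariates before model fitting, but as a
#' deterministic rule instead of visual heatmap inspection.
#'
#' @param mat A [correlation_matrix()].
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @param pinned Features never dropped (e.g. the model's chosen
#'   covariates). Two pinned features above threshold raise a warning and
#'   both are kept.
#' @return List of class `selection_result`: `kept`, `dropped` (data.frame
#'   `feature`, `partner`, `abs_r`), `threshold`.
#' @export
prune_collinear <- function(mat, threshold = 0.7, pinned = character(0)) {
  stopifnot(is.matrix(mat), isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)))
  feats <- sort(colnames(mat))
  mat <- mat[feats, feats, drop = FALSE]
  dropped <- data.frame(feature = character(0), partner = character(0),
                        abs_r = numeric(0))
  repeat {
    m <- abs(mat[feats, feats, drop = FALSE])
    diag(m) <- 0
    droppable <- outer(!(feats %in% pinned), !(feats %in% pinned), `|`)
    over <- m > threshold & droppable
    if (!any(over)) break
    worst <- which(over & m == max(m[over]), arr.ind = TRUE)[1L, ]
    a <- feats[worst[1L]]; b <- feats[worst[2L]]
    cand <- setdiff(c(a, b), pinned)
    if (length(cand) == 2L) {
      mean_r <- vapply(cand, function(f) {
        mean(abs(mat[f, setdiff(feats, f)]))
      }, numeric(1))
      # drop the larger mean |r|; lexicographic tie-break (feats sorted)
      cand <- cand[order(-mean_r, cand)][1L]
    }
    dropped <- rbind(dropped, data.frame(
      feature = cand, partner = setdiff(c(a, b), cand)[1L],
      abs_r = abs(mat[a, b])))
    feats <- setdiff(feats, cand)
  }
  pinned_pairs <- abs(mat[intersect(feats, pinned), intersect(feats, pinned),
                          drop = FALSE])
  diag(pinned_pairs) <- 0
  if (any(pinned_pairs > threshold)) {
    warning("pinned features exceed the correlation threshold; both kept")
  }
  structure(list(kept = feats, dropped = dropped, threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d kept, %d dropped at |r| > %g>\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  - %s (|r| = %.3f with %s)\n", x$dropped$feature[i],
                  x$dropped$abs_r[i], x$dropped$partner[i]))
    }
  }
  invisible(x)
}

#' The model's five pinned covariates
#'
#' The covariates retained for the placement GLM after collinearity
#' pruning: average bite duration, average bite strength, interaction
#' time, peak bite frequency, and condition.
#' @return Character vector of feature-table column names.
#' @export
model_covariates <- function() {
  c("avg_duration_s", "avg_strength_kpa", "interaction_time_s",
    "peak_freq_hz", "condition")
}

#' Condition-by-outcome feature summaries
#'
#' Mean, min and max of each feature per condition for all analyzable
#' trials and split by outcome (pass = placed, fail = released), computed
#' only over trials where the dog interacted with the ball
#' (zero-interaction rows are excluded). Strata with no rows are absent,
#' not zero.
#'
#' @param table Feature table with `placed` and `zero_interaction`.
#' @param features Feature columns to summarize; defaults to the model
#'   covariates minus `condition`.
#' @return Long-format data.frame: `condition, outcome, feature, stat,
#'   value, n` with `outcome` in `all`, `pass`, `fail`.
#' @export
summarize_by_outcome <- function(table, features = setdiff(model_covariates(),
                                                           "condition")) {
  stopifnot("placed" %in% names(table), "zero_interaction" %in% names(table))
  act <- table[!table$zero_interaction, , drop = FALSE]
  out <- list()
  for (cond in unique(table$condition)) {
    for (oc in c("all", "pass", "fail")) {
      sub <- act[act$condition == cond, , drop = FALSE]
      if (oc == "pass") sub <- sub[sub$placed %in% TRUE, , drop = FALSE]
      if (oc == "fail") sub <- sub[sub$placed %in% FALSE, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (f in features) {
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, outcome = oc, feature = f,
          stat = c("mean", "min", "max"),
          value = c(mean(sub[[f]]), min(sub[[f]]), max(sub[[f]])),
          n = nrow(sub))
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(condition = character(0), outcome = character(0),
                      feature = character(0), stat = character(0),
                      value = numeric(0), n = integer(0))
  }
  rownames(res) <- NULL
  res
}
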