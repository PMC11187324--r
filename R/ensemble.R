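# Ensemble consensus with abstention, and the standard evaluation metrics.
# Each model votes by thresholding its bag probability; the ensemble decides
# by majority, and an exact 50/50 split abstains ("indecision") rather than
# classifies.

as_vote <- function(votes) {
  if (is.logical(votes)) return(votes)
  if (is.numeric(votes)) return(votes > 0)
  votes <- as.character(votes)
  if (!all(votes %in% c("positive", "negative")))
    stop("votes must be 'positive'/'negative' (or logical/0-1)", call. = FALSE)
  votes == "positive"
}

#' Majority consensus with an indecision outcome
#'
#' Confidence is the majority-vote fraction over hard votes (never averaged
#' probabilities): `confidence = max class count / N`. The decision is the
#' majority class when confidence exceeds 0.5 and `"indecision"` when the
#' votes split exactly evenly — for six models, "at least 4 converged"
#' decides, and 3-3 abstains. Permutation-invariant; odd vote counts can
#' never abstain.
#'
#' @param votes Vector of binary votes (`"positive"`/`"negative"`, logical,
#'   or 0/1); at least one vote.
#' @return List with `decision` (`"positive"`, `"negative"` or
#'   `"indecision"`) and `confidence` (in `[0.5, 1]` for 2 or more votes).
#' @examples
#' consensus(c("positive", "positive", "positive", "positive",
#'             "negative", "negative")) # positive, 4/6
#' @export
consensus <- function(votes) {
  if (length(votes) == 0) stop("at least one vote required", call. = FALSE)
  v <- as_vote(votes)
  pos <- sum(v)
  neg <- length(v) - pos
  confidence <- max(pos, neg) / length(v)
  decision <- if (pos > neg) "positive" else if (neg > pos) "negative"
  else "indecision"
  list(decision = decision, confidence = confidence)
}

#' Ensemble prediction for one bag
#'
#' Runs every model on the bag, converts each bag probability into a hard
#' vote at threshold 0.5 (probabilities of exactly 0.5 vote positive), and
#' applies [consensus()]. Per-model probabilities are retained for audit.
#'
#' @param models Named list of `"trained_model"` objects sharing the same
#'   label space.
#' @param bag A `"mil_bag"`.
#' @return An object of class `"ensemble_prediction"`: `slide_id`, `votes`,
#'   `probabilities`, `confidence`, `decision`.
#' @export
predict_slide <- function(models, bag) {
  stopifnot(length(models) >= 1, inherits(bag, "mil_bag"))
  if (is.null(names(models)))
    names(models) <- paste0("m", seq_along(models))
  probs <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (m$config$input_size_px != models[[1]]$config$input_size_px)
      stop("model ", names(models)[i],
           " uses a different input size than the rest of the ensemble",
           call. = FALSE)
    forward_bag(m, bag)$bag_probability
  }, numeric(1))
  names(probs) <- names(models)
  votes <- ifelse(probs >= 0.5, "positive", "negative")
  cons <- consensus(votes)
  structure(
    list(slide_id = bag$slide_id, votes = votes, probabilities = probs,
         confidence = cons$confidence, decision = cons$decision),
    class = "ensemble_prediction"
  )
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble> %s: %s (confidence %.2f; %d/%d positive votes)\n",
              x$slide_id, x$decision, x$confidence,
              sum(x$votes == "positive"), length(x$votes)))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F1 score; `NA` when both inputs are zero.
#' @examples
#' f1_score(0.75, 0.68) # ~0.71
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Confusion-matrix metrics for binary predictions
#'
#' Positive class is `"positive"`. Ratios with zero denominators are
#' reported as `NA` (absent), never as 0.
#'
#' @param predictions,truths Equal-length vectors of class labels
#'   (`"positive"`/`"negative"`, logical, or 0/1).
#' @return An object of class `"metrics_report"`: confusion counts `tp`,
#'   `fp`, `tn`, `fn` and `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0)
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  p <- as_vote(predictions)
  t <- as_vote(truths)
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    f1_score(precision, recall) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(t),
         precision = precision, recall = recall, f1 = f1),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> acc %.3f  precision %.3f  recall %.3f  f1 %.3f  (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counting one half.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param truths Class labels aligned with `scores`; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truths) {
  t <- as_vote(truths)
  stopifnot(length(scores) == length(t))
  np <- sum(t); nn <- sum(!t)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[t]) - np * (np + 1) / 2) / (np * nn)
}

#' Score ensemble decisions against the truth
#'
#' @param predictions List of `"ensemble_prediction"` objects (or a
#'   character vector of decisions).
#' @param truths Named (by slide id) or aligned vector of true labels.
#' @return Character vector over `"correct"`, `"incorrect"`,
#'   `"indecision"`.
#' @export
score_decisions <- function(predictions, truths) {
  if (is.list(predictions)) {
    ids <- vapply(predictions, function(p) p$slide_id, character(1))
    decisions <- vapply(predictions, function(p) p$decision, character(1))
    if (!is.null(names(truths))) truths <- truths[ids]
  } else decisions <- as.character(predictions)
  truths <- as_class_label(truths)
  stopifnot(length(decisions) == length(truths))
  out <- ifelse(decisions == "indecision", "indecision",
                ifelse(decisions == truths, "correct", "incorrect"))
  unname(out)
}

#' Three-way ensemble report
#'
#' Percentages of correct / indecision / incorrect outcomes, rounded to
#' integers with largest-remainder correction so they always sum to 100
#' (remainder ties resolve toward the later category).
#'
#' @param decisions Character vector over `"correct"`, `"incorrect"`,
#'   `"indecision"` (see [score_decisions()]).
#' @return An object of class `"ensemble_report"`: counts `n_correct`,
#'   `n_indecision`, `n_incorrect`, total `n`, and integer
#'   `percent_correct`, `percent_indecision`, `percent_incorrect`.
#' @examples
#' ensemble_report(rep(c("correct", "indecision"), c(29, 6))) # 83 / 17 / 0
#' @export
ensemble_report <- function(decisions) {
  decisions <- as.character(decisions)
  if (length(decisions) == 0) stop("no decisions supplied", call. = FALSE)
  if (!all(decisions %in% c("correct", "incorrect", "indecision")))
    stop("decisions must be 'correct', 'incorrect' or 'indecision'",
         call. = FALSE)
  counts <- c(correct = sum(decisions == "correct"),
              indecision = sum(decisions == "indecision"),
              incorrect = sum(decisions == "incorrect"))
  pct <- largest_remainder_percent(counts)
  structure(
    list(n = length(decisions),
         n_correct = counts[["correct"]],
         n_indecision = counts[["indecision"]],
         n_incorrect = counts[["incorrect"]],
         percent_correct = pct[["correct"]],
         percent_indecision = pct[["indecision"]],
         percent_incorrect = pct[["incorrect"]]),
    class = "ensemble_report"
  )
}

# Integer percentages summing to exactly 100 (largest-remainder method,
# remainder ties to the later category).
largest_remainder_percent <- function(counts) {
  raw <- 100 * counts / sum(counts)
  pct <- floor(raw)
  rem <- raw - pct
  left <- 100 - sum(pct)
  if (left > 0) {
    ord <- order(-rem, -seq_along(rem))
    pct[ord[seq_len(left)]] <- pct[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(pct), names(counts))
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble report> n=%d: %d%% correct, %d%% indecision, %d%% incorrect\n",
              x$n, x$percent_correct, x$percent_indecision,
              x$percent_incorrect))
  invisible(x)
}
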