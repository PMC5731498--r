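#' Surface-residue mask
#'
#' Evaluation is restricted to surface residues; the published benchmark
#' rules are `"ge_0.05"` (RASA >= 0.05) and `"gt_0"` (RASA > 0). `"none"`
#' evaluates every residue; `custom` accepts any predicate on RASA.
#'
#' @param rasa numeric RASA vector.
#' @param rule `"ge_0.05"`, `"gt_0"`, `"none"` or `"custom"`.
#' @param custom predicate function used when `rule = "custom"`.
#' @return Logical mask, `FALSE` for `NA` RASA.
#' @export
surface_mask <- function(rasa, rule = c("ge_0.05", "gt_0", "none", "custom"),
                         custom = NULL) {
  rule <- match.arg(rule)
  m <- switch(rule,
    ge_0.05 = rasa >= 0.05,
    gt_0 = rasa > 0,
    none = rep(TRUE, length(rasa)),
    custom = {
      stopifnot(is.function(custom))
      custom(rasa)
    }
  )
  m & !is.na(rasa)
}

#' Confusion counts for interface calls
#'
#' @param call logical predicted calls.
#' @param truth logical ground-truth interface labels, aligned with `call`.
#' @param mask optional logical mask (e.g. [surface_mask()]); only masked
#'   residues are counted.
#' @return Named integer vector `c(tp, fn, fp, tn)` of class
#'   `ppi_confusion`: tp/tn are correctly labeled interface/non-interface
#'   residues, fn/fp the respective errors.
#' @export
confusion_counts <- function(call, truth, mask = NULL) {
  if (length(call) != length(truth)) {
    stop("call/truth length mismatch", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(call))
  call <- call[mask]; truth <- truth[mask]
  out <- c(
    tp = sum(call & truth), fn = sum(!call & truth),
    fp = sum(call & !truth), tn = sum(!call & !truth)
  )
  structure(as.integer(out), names = names(out), class = "ppi_confusion")
}

#' Matthews correlation coefficient
#'
#' `(tp * tn - fp * fn) / sqrt((tp + fp)(tp + fn)(tn + fp)(tn + fn))`,
#' ranging from -1 (inverted prediction) through 0 (random) to 1 (perfect).
#' Any zero factor under the radical yields 0 by convention.
#'
#' @param counts a [confusion_counts()] result or named vector with
#'   `tp`, `fn`, `fp`, `tn`.
#' @return Numeric in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fn <- as.numeric(counts[["fn"]])
  fp <- as.numeric(counts[["fp"]]); tn <- as.numeric(counts[["tn"]])
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Prediction quality metrics from confusion counts
#'
#' MCC plus precision, recall, accuracy and F1. Undefined ratios (0/0, e.g.
#' precision with no positive calls) are reported as 0; the affected metric
#' names are listed in the `"undefined"` attribute.
#'
#' @inheritParams mcc
#' @return One-row tibble: `mcc`, `precision`, `recall`, `accuracy`, `f1`.
#' @export
ppi_metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fn <- as.numeric(counts[["fn"]])
  fp <- as.numeric(counts[["fp"]]); tn <- as.numeric(counts[["tn"]])
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      return(0)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  accuracy <- ratio(tp + tn, tp + fn + fp + tn, "accuracy")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  out <- tibble(mcc = mcc(counts), precision = precision, recall = recall,
                accuracy = accuracy, f1 = f1)
  attr(out, "undefined") <- unique(undef)
  out
}

#' Score predictions against ground truth
#'
#' Joins a prediction table with ground-truth labels by structure and
#' residue id, applies a surface-residue rule on the predictions' RASA
#' values, and computes pooled confusion counts and metrics; optionally also
#' per-protein rows. Residues present in only one of the two tables raise
#' an alignment error naming the offenders.
#'
#' @param predictions `ppi_prediction` tibble from [predict_structure()]
#'   (possibly several, row-bound), with `structure_id`, `res_id`, `rasa`,
#'   `prob`, `call`.
#' @param truth tibble with `structure_id`, `res_id`, `interface` — e.g.
#'   from [annotate_residues()] or a fixture generator's truth table.
#' @param surface_rule passed to [surface_mask()].
#' @param per_protein also compute metrics per structure id.
#' @return A `ppi_eval` list: `counts` (`ppi_confusion`), `metrics` (one-row
#'   tibble), `n_evaluated`, and `per_protein` tibble when requested.
#' @export
evaluate_predictions <- function(predictions, truth,
                                 surface_rule = "none",
                                 per_protein = FALSE) {
  p <- as_tibble(predictions)
  t <- as_tibble(truth)
  p$.key <- paste(p$structure_id, p$res_id)
  t$.key <- paste(t$structure_id, t$res_id)
  only_p <- setdiff(p$.key, t$.key)
  only_t <- setdiff(t$.key, p$.key)
  if (length(only_p) || length(only_t)) {
    stop("prediction/truth residue sets differ; offenders: ",
         paste(head(c(only_p, only_t), 10), collapse = ", "), call. = FALSE)
  }
  t <- t[match(p$.key, t$.key), ]
  mask <- surface_mask(p$rasa, rule = surface_rule)
  counts <- confusion_counts(p$call, t$interface, mask)
  out <- list(
    counts = counts,
    metrics = ppi_metrics(counts),
    n_evaluated = sum(mask),
    surface_rule = surface_rule
  )
  if (per_protein) {
    out$per_protein <- p |>
      mutate(truth = t$interface, mask = mask) |>
      group_by(.data$structure_id) |>
      summarise(
        {
          cc <- confusion_counts(.data$call, .data$truth, .data$mask)
          mutate(ppi_metrics(cc), tp = cc[["tp"]], fn = cc[["fn"]],
                 fp = cc[["fp"]], tn = cc[["tn"]])
        },
        .groups = "drop"
      )
  }
  class(out) <- "ppi_eval"
  out
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat("# ppi_eval over", x$n_evaluated, "surface residues (rule",
      x$surface_rule, ")\n")
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_predictions
#' @param x a `ppi_eval`.
#' @param ... unused.
#' @method tidy ppi_eval
#' @export
tidy.ppi_eval <- function(x, ...) {
  tibble(
    quantity = c("tp", "fn", "fp", "tn"),
    count = as.integer(x$counts)
  )
}

#' @rdname evaluate_predictions
#' @method glance ppi_eval
#' @export
glance.ppi_eval <- function(x, ...) {
  mutate(x$metrics,
         tp = x$counts[["tp"]], fn = x$counts[["fn"]],
         fp = x$counts[["fp"]], tn = x$counts[["tn"]],
         n_evaluated = x$n_evaluated)
}

#' Threshold sweep over retained probabilities
#'
#' Recomputes confusion counts and metrics for a grid of decision
#' thresholds from the per-residue probabilities, without re-querying the
#' knowledge base. Undefined probabilities (`NA`, nothing retrieved) are
#' never called interface.
#'
#' @inheritParams evaluate_predictions
#' @param thresholds numeric vector of thresholds (strict `prob > tau`).
#' @return A `ppi_sweep` tibble: one row per threshold with counts,
#'   `n_calls` and all metrics.
#' @export
sweep_thresholds <- function(predictions, truth,
                             thresholds = seq(0, 1, by = 0.05),
                             surface_rule = "none") {
  p <- as_tibble(predictions)
  rows <- purrr::map(thresholds, function(tau) {
    p2 <- mutate(p, call = !is.na(.data$prob) & .data$prob > tau)
    ev <- evaluate_predictions(p2, truth, surface_rule = surface_rule)
    mutate(glance(ev), threshold = tau, n_calls = sum(p2$call), .before = 1)
  })
  out <- bind_rows(rows)
  class(out) <- c("ppi_sweep", class(out))
  out
}
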