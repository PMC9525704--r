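# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_tile
#'   geom_abline geom_text coord_flip labs theme_minimal scale_fill_gradient
NULL

#' Bar plot of the top AMGM dispersion scores
#'
#' @param scores Tibble from [amgm_scores()] (or [select_top_k()]).
#' @param top_n Number of features shown.
#' @return A ggplot object.
#' @export
plot_amgm_scores <- function(scores, top_n = 30) {
  top <- select_top_k(scores, min(top_n, nrow(scores)))
  ggplot(top, aes(x = stats::reorder(.data$feature_id, .data$r), y = .data$r)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "modified AMGM dispersion",
         title = "Top features by AMGM score") +
    theme_minimal()
}

#' Panel composition by community
#'
#' @param object A `candidate_panel` from [select_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_panel
#' @export
autoplot.candidate_panel <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$community), y = .data$amgm)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    labs(x = "community", y = "AMGM score",
         title = sprintf("Candidate panel: %d features from %d communities",
                         nrow(object), length(unique(object$community)))) +
    theme_minimal()
}

#' Confusion matrix and one-vs-rest ROC curves of an evaluation report
#'
#' @param object An `eval_report` from [evaluate()].
#' @param what `"roc"` or `"confusion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, what = c("roc", "confusion"), ...) {
  what <- match.arg(what)
  if (what == "roc") {
    ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
      geom_line() +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
      labs(x = "false positive rate", y = "true positive rate",
           title = sprintf("One-vs-rest ROC (%s, accuracy %.1f%%)",
                           object$partition, object$accuracy_multiclass)) +
      theme_minimal()
  } else {
    df <- as.data.frame(object$confusion)
    names(df) <- c("truth", "predicted", "n")
    ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
      geom_tile() +
      geom_text(aes(label = .data$n)) +
      scale_fill_gradient(low = "white", high = "steelblue") +
      labs(title = sprintf("Confusion matrix (%s)", object$partition)) +
      theme_minimal()
  }
}

#' Bar plot of a subtype's repeat-count table
#'
#' @param table Tibble from [repeat_counts()].
#' @param top_n Number of molecules shown.
#' @return A ggplot object.
#' @export
plot_repeat_counts <- function(table, top_n = 15) {
  top <- utils::head(table, top_n)
  ggplot(top, aes(x = stats::reorder(.data$feature_id, .data$repeat_count),
                  y = .data$repeat_count)) +
    geom_col(fill = "darkorange") +
    coord_flip() +
    labs(x = NULL, y = "repeat count in class rules",
         title = "Molecules dominating the subtype's association rules") +
    theme_minimal()
}
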