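# Evaluation of predicted complex sets against a reference catalogue:
# match-based precision/recall/F using the neighborhood-affinity criterion,
# and the clustering-wise Sn/PPV/Accuracy triple computed from the
# reference-by-prediction overlap matrix.

#' Neighborhood affinity between two complexes
#'
#' `|P intersect B|^2 / (|P| * |B|)`: the product of the two containment
#' fractions. Symmetric, in `[0, 1]`, and 1 exactly for identical sets.
#'
#' @param p,b non-empty character vectors (member sets).
#' @return Numeric scalar.
#' @export
neighborhood_affinity <- function(p, b) {
  p <- unique(p)
  b <- unique(b)
  if (length(p) == 0L || length(b) == 0L) {
    stop("neighborhood_affinity requires non-empty sets", call. = FALSE)
  }
  sum(p %in% b)^2 / (length(p) * length(b))
}

affinity_matrix <- function(predicted, reference) {
  outer(seq_along(predicted), seq_along(reference),
        Vectorize(function(i, j)
          neighborhood_affinity(predicted[[i]], reference[[j]])))
}

#' Matched complex counts at an affinity threshold
#'
#' `n_cp` is the number of predicted complexes whose best neighborhood
#' affinity against the reference reaches `omega`; `n_cb` the number of
#' reference complexes matched by at least one prediction.
#'
#' @param predicted,reference catalogues or lists of member vectors.
#' @param omega affinity threshold in `(0, 1]`.
#' @return List with `n_cp`, `n_cb`.
#' @export
match_counts <- function(predicted, reference, omega = 0.2) {
  stopifnot(omega > 0, omega <= 1)
  predicted <- member_sets(predicted)
  reference <- member_sets(reference)
  if (length(predicted) == 0L || length(reference) == 0L) {
    return(list(n_cp = 0L, n_cb = 0L))
  }
  aff <- affinity_matrix(predicted, reference)
  list(n_cp = sum(apply(aff, 1L, max) >= omega),
       n_cb = sum(apply(aff, 2L, max) >= omega))
}

#' Match-based precision, recall and F-measure
#'
#' `precision = n_cp / #predicted`, `recall = n_cb / #reference`, and their
#' harmonic mean (0 when both are 0).
#'
#' @inheritParams match_counts
#' @return List with `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(predicted, reference, omega = 0.2) {
  predicted <- member_sets(predicted)
  reference <- member_sets(reference)
  if (length(predicted) == 0L || length(reference) == 0L) {
    stop("predicted and reference sets must be non-empty", call. = FALSE)
  }
  mc <- match_counts(predicted, reference, omega)
  precision <- mc$n_cp / length(predicted)
  recall <- mc$n_cb / length(reference)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f)
}

#' Clustering-wise sensitivity, PPV and accuracy
#'
#' With `T[i, j] = |reference_i intersect predicted_j|`:
#' `Sn = sum_i max_j T[i, j] / sum_i |reference_i|`,
#' `PPV = sum_j max_i T[i, j] / sum_{i,j} T[i, j]`, and
#' `Accuracy = sqrt(Sn * PPV)`. When no prediction overlaps any reference
#' complex the PPV denominator is zero; all three metrics are then reported
#' as 0 with a warning.
#'
#' @inheritParams match_counts
#' @return List with `sensitivity`, `ppv`, `accuracy`.
#' @export
sn_ppv_acc <- function(predicted, reference) {
  predicted <- member_sets(predicted)
  reference <- member_sets(reference)
  if (length(predicted) == 0L || length(reference) == 0L) {
    stop("predicted and reference sets must be non-empty", call. = FALSE)
  }
  Tm <- outer(seq_along(reference), seq_along(predicted),
              Vectorize(function(i, j)
                sum(reference[[i]] %in% predicted[[j]])))
  sn <- sum(apply(Tm, 1L, max)) / sum(lengths(reference))
  denom <- sum(Tm)
  if (denom == 0) {
    warning("no prediction overlaps any reference complex; Sn/PPV/Acc = 0")
    return(list(sensitivity = 0, ppv = 0, accuracy = 0))
  }
  ppv <- sum(apply(Tm, 2L, max)) / denom
  list(sensitivity = sn, ppv = ppv, accuracy = sqrt(sn * ppv))
}

#' Evaluate a predicted complex set against a reference catalogue
#'
#' Bundles [precision_recall_f()] and [sn_ppv_acc()] together with the
#' matched-complex counts and coverage statistics. Predicted singletons are
#' excluded by default: their affinity against any reference complex is
#' degenerate.
#'
#' @inheritParams match_counts
#' @param min_size smallest predicted complex size retained (default 2).
#' @return A list of class `eval_metrics`: `n_predicted`,
#'   `n_covered_proteins`, `n_cp`, `n_cb`, `precision`, `recall`,
#'   `f_measure`, `sensitivity`, `ppv`, `accuracy`, `omega`.
#' @export
evaluate_complexes <- function(predicted, reference, omega = 0.2,
                               min_size = 2L) {
  predicted <- member_sets(predicted)
  reference <- member_sets(reference)
  predicted <- predicted[lengths(predicted) >= min_size]
  if (length(predicted) == 0L) {
    stop("no predicted complex of size >= ", min_size, call. = FALSE)
  }
  mc <- match_counts(predicted, reference, omega)
  prf <- precision_recall_f(predicted, reference, omega)
  spa <- sn_ppv_acc(predicted, reference)
  structure(c(list(n_predicted = length(predicted),
                   n_covered_proteins =
                     length(unique(unlist(predicted, use.names = FALSE))),
                   n_cp = mc$n_cp, n_cb = mc$n_cb),
              prf, spa, list(omega = omega)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("eval_metrics (omega = %g): %d predicted (%d proteins), ",
           "matched %d/%d\n  P = %.3f  R = %.3f  F = %.3f  ",
           "Sn = %.3f  PPV = %.3f  Acc = %.3f\n"),
    x$omega, x$n_predicted, x$n_covered_proteins, x$n_cp, x$n_cb,
    x$precision, x$recall, x$f_measure, x$sensitivity, x$ppv, x$accuracy))
  invisible(x)
}
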