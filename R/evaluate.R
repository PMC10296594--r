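# Evaluation: the accuracy metric is hits over total residues; the
# confusion matrix is laid out observed-in-rows, predicted-in-columns,
# classes ordered H, E, L.  Residues the classifier could not label
# (still "U") count as misses and are reported separately.

#' Score predictions against truth
#'
#' @param truth Character truth labels over `c("H","E","L")`.
#' @param pred Predicted labels over `c("H","E","L","U")`, or an
#'   `sse_prediction` tibble with truth in `sse` and predictions in
#'   `label`.
#' @return An `sse_eval` object: 3x3 confusion matrix, accuracy
#'   (hits over all residues, unresolved included in the denominator),
#'   per-class precision/recall/F1, and counts.
#' @export
sse_evaluate <- function(truth, pred = NULL) {
  if (is.data.frame(truth) && is.null(pred)) {
    pred <- truth$label
    truth <- truth$sse
  }
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop("truth and predictions have different lengths", call. = FALSE)
  }
  stopifnot(all(truth %in% SSE_CLASSES), all(pred %in% c(SSE_CLASSES, "U")))
  resolved <- pred != "U"
  cm <- table(factor(truth[resolved], SSE_CLASSES),
              factor(pred[resolved], SSE_CLASSES))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(observed = SSE_CLASSES,
                               predicted = SSE_CLASSES))
  n <- length(truth)
  hits <- sum(diag(cm))
  per_class <- lapply(SSE_CLASSES, function(cl) {
    tp <- cm[cl, cl]
    p <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    r <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else NA_real_
    f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
    c(precision = p, recall = r, f1 = f1)
  })
  names(per_class) <- SSE_CLASSES
  structure(list(confusion = cm, accuracy = hits / n, n = n,
                 n_unresolved = sum(!resolved),
                 per_class = per_class), class = "sse_eval")
}

#' @export
print.sse_eval <- function(x, ...) {
  cat(sprintf("# SSE evaluation: accuracy %.3f over %d residues%s\n",
              x$accuracy, x$n,
              if (x$n_unresolved > 0)
                sprintf(" (%d unresolved, scored as misses)", x$n_unresolved)
              else ""))
  cm <- x$confusion
  tot <- rbind(cbind(cm, Total = rowSums(cm)),
               Total = c(colSums(cm), sum(cm)))
  print(tot)
  for (cl in SSE_CLASSES) {
    pc <- x$per_class[[cl]]
    cat(sprintf("  %s: precision %.3f recall %.3f F1 %.3f\n",
                cl, pc["precision"], pc["recall"], pc["f1"]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class metrics of an evaluation, one row per class
#' @param x An `sse_eval` object.
#' @param ... Unused.
#' @return A tibble with class, precision, recall, f1, support.
#' @method tidy sse_eval
#' @export
tidy.sse_eval <- function(x, ...) {
  tibble::tibble(
    class = SSE_CLASSES,
    precision = unname(vapply(x$per_class, `[[`, numeric(1), "precision")),
    recall = unname(vapply(x$per_class, `[[`, numeric(1), "recall")),
    f1 = unname(vapply(x$per_class, `[[`, numeric(1), "f1")),
    support = unname(rowSums(x$confusion)))
}

#' One-row summary of an evaluation
#' @inheritParams tidy.sse_eval
#' @return A tibble with accuracy, n, n_unresolved.
#' @method glance sse_eval
#' @export
glance.sse_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n,
                 n_unresolved = x$n_unresolved)
}

#' Ranks and window counts of a fitted subspace model, one row per class
#' @param x An `sse_subspace_model`.
#' @param ... Unused.
#' @method tidy sse_subspace_model
#' @export
tidy.sse_subspace_model <- function(x, ...) {
  tibble::tibble(class = SSE_CLASSES, rank = as.integer(x$rank[SSE_CLASSES]),
                 n_windows = as.integer(x$n_windows[SSE_CLASSES]))
}

#' One-row summary of a fitted subspace model
#' @inheritParams tidy.sse_subspace_model
#' @method glance sse_subspace_model
#' @export
glance.sse_subspace_model <- function(x, ...) {
  tibble::tibble(q = x$q, z = x$z, d = x$d,
                 ambient_dim = x$q * x$d,
                 n_windows = sum(x$n_windows))
}

#' Classify one trace end to end
#'
#' Featurize, classify with the chosen method, and (by default)
#' post-process.
#'
#' @param trace A [ca_trace].
#' @param model An `sse_subspace_model` or `eml_model`.
#' @param method `"model1"`, `"model2"` or `"eml"`.
#' @param postprocess Apply [postprocess_labels()].
#' @param model2_cfg,post_cfg Optional configs.
#' @return An `sse_prediction` tibble.
#' @export
sse_classify <- function(trace, model, method = c("model1", "model2", "eml"),
                         postprocess = TRUE,
                         model2_cfg = model2_config(),
                         post_cfg = postprocess_config()) {
  method <- match.arg(method)
  pred <- switch(method,
                 model1 = classify_model1(trace, model),
                 model2 = classify_model2(trace, model, model2_cfg),
                 eml = classify_eml(trace, model))
  if (postprocess) {
    pred <- postprocess_labels(pred, ca_features(trace), post_cfg)
  }
  pred
}

#' Run the full pipeline over PDB files
#'
#' Reads each chain, classifies it, optionally evaluates against the
#' file's HELIX/SHEET truth, and writes one prediction TSV.  Chains the
#' reader rejects are skipped and reported.
#'
#' @param pdb_files Character vector of PDB paths.
#' @param model A trained model (subspace or EML).
#' @param method Classifier to use.
#' @param chain Chain identifier, recycled over files.
#' @param out_tsv Optional path for the combined prediction TSV.
#' @param postprocess Apply the correction rules.
#' @param evaluate Score against the PDB truth records.
#' @param lenient Passed to [read_ca_trace()].
#' @return A list with `predictions` (tibble), `report` (an `sse_eval` or
#'   `NULL`) and `skipped` (tibble of rejected chains with reasons).
#' @export
run_sse_pipeline <- function(pdb_files, model,
                             method = c("model1", "model2", "eml"),
                             chain = "A", out_tsv = NULL, postprocess = TRUE,
                             evaluate = TRUE, lenient = FALSE) {
  method <- match.arg(method)
  chain <- rep_len(chain, length(pdb_files))
  preds <- list()
  skipped <- list()
  for (k in seq_along(pdb_files)) {
    f <- pdb_files[k]
    trace <- tryCatch(
      if (evaluate) read_pdb_chain(f, chain[k], lenient = lenient)
      else read_ca_trace(f, chain[k], lenient = lenient),
      catrace_rejection = function(e) e)
    if (inherits(trace, "condition")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(file = f, chain = chain[k],
                       reason = trace$reason %||% "rejected")
      next
    }
    attr(trace, "source_id") <- paste0(basename(f), ":", chain[k])
    preds[[length(preds) + 1L]] <-
      sse_classify(trace, model, method, postprocess = postprocess)
  }
  if (!length(preds)) {
    stop("all chains were rejected", call. = FALSE)
  }
  predictions <- dplyr::bind_rows(preds)
  report <- NULL
  if (evaluate && !is.null(predictions$sse)) {
    report <- sse_evaluate(predictions$sse, predictions$label)
  }
  if (!is.null(out_tsv)) {
    readr::write_tsv(predictions, out_tsv)
  }
  list(predictions = predictions,
       report = report,
       skipped = dplyr::bind_rows(skipped))
}
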