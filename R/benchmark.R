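# Reproducible end-to-end evaluation on the synthetic corpus.

#' End-to-end benchmark on synthetic proteins
#'
#' Generates a corpus of synthetic proteins (helix / coil / hairpin /
#' coil / helix chains, Gaussian coordinate jitter), trains the subspace
#' model on the training split, optionally trains the stacked ensemble
#' on the training residues (capped at `eml_max_samples` rows before
#' class balancing), classifies the held-out proteins with each
#' requested method (with post-processing), and scores per-residue
#' accuracy against the generator's truth labels.
#'
#' @param seed Master seed for corpus generation and model training.
#' @param n_train,n_test Corpus split sizes.
#' @param jitter_sd Coordinate noise of the corpus, Angstroms.
#' @param methods Subset of `c("model1", "model2", "eml")`.
#' @param window_cfg,model2_cfg,eml_cfg Model configurations.
#' @param eml_max_samples Training-row cap for the ensemble.
#' @return A list with `results` (tibble: method, accuracy, n), `evals`
#'   (named list of `sse_eval` objects) and the fitted models.
#' @export
synthetic_benchmark <- function(seed = 1, n_train = 60, n_test = 20,
                                jitter_sd = 0.1,
                                methods = c("model1", "model2", "eml"),
                                window_cfg = window_config(),
                                model2_cfg = model2_config(),
                                eml_cfg = eml_config(),
                                eml_max_samples = 5000) {
  methods <- match.arg(methods, several.ok = TRUE)
  corpus <- make_protein_corpus(n_train + n_test, seed = seed,
                                jitter_sd = jitter_sd)
  train <- corpus[seq_len(n_train)]
  test <- corpus[n_train + seq_len(n_test)]
  subspace <- NULL
  if (any(c("model1", "model2") %in% methods)) {
    subspace <- train_subspace(train, window_cfg)
  }
  eml <- NULL
  if ("eml" %in% methods) {
    feats <- dplyr::bind_rows(lapply(train, ca_features))
    feats <- feats[stats::complete.cases(feats[, feature_names()]), ]
    if (nrow(feats) > eml_max_samples) {
      feats <- feats[with_seed(seed, sample(nrow(feats), eml_max_samples)), ]
    }
    eml <- train_eml(feats, cfg = eml_cfg, seed = seed)
  }
  evals <- list()
  for (m in methods) {
    model <- if (m == "eml") eml else subspace
    preds <- dplyr::bind_rows(lapply(test, function(tr) {
      sse_classify(tr, model, m, model2_cfg = model2_cfg)
    }))
    evals[[m]] <- sse_evaluate(preds$sse, preds$label)
  }
  results <- tibble::tibble(
    method = methods,
    accuracy = vapply(evals, function(e) e$accuracy, numeric(1)),
    n = vapply(evals, function(e) e$n, numeric(1)))
  list(results = results, evals = evals,
       subspace_model = subspace, eml_model = eml)
}
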