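# End-to-end convenience layer: family blocks from a corpus, and a full
# detection run (features -> leaderboards -> fusion -> baselines -> report).

#' Build the three family feature blocks for a corpus
#'
#' @param corpus an [si_corpus()]
#' @param lexicons named lexicon list (as from [make_fixture_lexicons()])
#' @param wec_k,wec_m,wec_dim,wec_window,wec_epochs,wec_min_count
#'   word-embedding-cluster parameters (see [wec_pipeline()])
#' @param seed integer seed for embedding training and clustering
#' @return named list with `blocks` (list of `BSC`, `RFS`, `WEC`
#'   `feature_block`s) and `wec` (keywords, clustering, embeddings)
#' @export
build_family_blocks <- function(corpus, lexicons, wec_k = 10L, wec_m = 20L,
                                wec_dim = 100L, wec_window = 5L,
                                wec_epochs = 5L, wec_min_count = 2L,
                                seed = 1L) {
  wec <- wec_pipeline(corpus, k = wec_k, m_per_cluster = wec_m,
                      dim = wec_dim, window = wec_window, epochs = wec_epochs,
                      min_count = wec_min_count, seed = seed)
  list(blocks = list(BSC = bsc_block(corpus, lexicons),
                     RFS = rfs_block(corpus, lexicons$risk),
                     WEC = wec$block),
       wec = wec[c("keywords", "clustering", "embeddings")])
}

#' Run the full detection pipeline on a labeled corpus
#'
#' Builds the three family blocks, cross-validates the zoo on each single
#' family (with and without feature selection), evaluates the fusion
#' ensemble on the given feature-set configuration under nested CV, runs the
#' ensemble baselines on the joint selected matrix, and writes the report.
#'
#' @param corpus a labeled [si_corpus()]
#' @param lexicons named lexicon list
#' @param out_dir report directory
#' @param seed integer master seed
#' @param zoo model ids evaluated per feature set (default full zoo)
#' @param fusion_sets recipe strings for the fusion configuration
#' @param selection a [selection_config()] for every `-fs` step
#' @param wec_k,wec_m word-embedding-cluster parameters
#' @param folds CV folds
#' @return invisible list with `blocks`, `results`, `fusion`, `out_dir`
#' @export
run_pipeline <- function(corpus, lexicons, out_dir, seed = 1L,
                         zoo = model_zoo(),
                         fusion_sets = c("(BSC+RFS)-fs", "WEC-fs"),
                         selection = selection_config(seed = seed),
                         wec_k = 10L, wec_m = 20L, folds = 5L) {
  labels <- corpus_labels(corpus)
  fam <- build_family_blocks(corpus, lexicons, wec_k = wec_k, wec_m = wec_m,
                             seed = seed)
  blocks <- fam$blocks

  single <- list(); optimum <- character(0)
  for (bl in c("BSC", "RFS", "WEC")) {
    for (mode in c("direct", "select-then-combine")) {
      recipe <- combination_recipe(bl, mode, selection)
      pick <- select_best(recipe, labels, zoo = zoo, folds = folds,
                          seed = seed, blocks = blocks)
      single[[recipe$label]] <- pick$result
      optimum[recipe$label] <- pick$best
    }
  }

  multi <- list()
  pairs <- list(c("BSC", "RFS"), c("BSC", "WEC"), c("RFS", "WEC"),
                c("BSC", "RFS", "WEC"))
  for (bls in pairs) {
    for (mode in c("direct", "select-then-combine", "combine-then-select")) {
      recipe <- combination_recipe(bls, mode, selection)
      pick <- select_best(recipe, labels, zoo = zoo, folds = folds,
                          seed = seed, blocks = blocks)
      multi[[recipe$label]] <- pick$result
      optimum[recipe$label] <- pick$best
    }
  }

  spec <- ensemble_spec(lapply(fusion_sets, parse_recipe, selection = selection),
                        folds = folds, seed = seed)
  spec <- choose_base_models(spec, blocks, labels, zoo = zoo)
  fusion_res <- evaluate_fusion_cv(spec, blocks, labels, outer_folds = folds,
                                   seed = seed, zoo = spec$base_models)
  fusion <- stats::setNames(list(fusion_res), spec$label)

  joint <- apply_recipe(combination_recipe(c("BSC", "RFS", "WEC"),
                                           "combine-then-select", selection),
                        blocks, labels)
  baselines <- run_baselines(joint, labels, seed = seed, folds = folds)

  results <- list(single = single, multi = multi, fusion = fusion,
                  baselines = baselines, optimum = optimum)
  config <- list(seed = seed, zoo = zoo, fusion_sets = fusion_sets,
                 folds = folds, wec_k = wec_k, wec_m = wec_m,
                 n_posts = n_posts(corpus),
                 provenance = attr(corpus, "provenance"))
  report(results, out_dir, config)
  invisible(list(blocks = blocks, results = results, fusion = spec,
                 out_dir = out_dir))
}
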