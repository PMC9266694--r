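# Reporting: leaderboard tables in the style of the method's comparison
# tables (single features, multi-feature combinations, fusion feature sets,
# ensemble baselines) plus reproducibility metadata.

fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)

results_to_table <- function(results, label_col = "Feature") {
  rows <- lapply(names(results), function(nm) {
    p <- results[[nm]]$pooled
    data.frame(label = nm,
               Accuracy = fmt_pct(p["accuracy"]),
               `F1-Score` = fmt_pct(p["f1"]),
               Precision = fmt_pct(p["precision"]),
               Recall = fmt_pct(p["recall"]),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- label_col
  out
}

config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run report
#'
#' Emits four CSV tables (single-feature leaderboard, multi-feature
#' combination leaderboard, fusion feature-set comparison, ensemble-baseline
#' comparison; metrics formatted as percentages with two decimals), a
#' markdown summary, and a JSON metadata file carrying seeds, the run
#' configuration and its hash.
#'
#' @param results named list with elements `single`, `multi`, `fusion`,
#'   `baselines` — each a named list of `cv_result`s (named by feature /
#'   recipe / model label) — plus optional `optimum` (named character vector
#'   of winning classifier per feature row)
#' @param out_dir output directory (created if needed)
#' @param config run configuration recorded (and hashed) in the metadata
#' @return `out_dir`, invisibly
#' @export
report <- function(results, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    single_features = results_to_table(results$single, "Feature"),
    multi_features = results_to_table(results$multi, "Feature Combination"),
    fusion_feature_sets = results_to_table(results$fusion, "Feature Set"),
    ensemble_baselines = results_to_table(results$baselines, "Model")
  )
  if (!is.null(results$optimum)) {
    opt <- results$optimum
    for (nm in c("single_features", "multi_features")) {
      tab <- tables[[nm]]
      hit <- opt[tab[[1]]]
      if (!all(is.na(hit))) tab$`Optimum Classifier` <- unname(hit)
      tables[[nm]] <- tab
    }
  }
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  meta <- list(seed = config$seed, config = config,
               config_hash = config_hash(config),
               n_tables = length(tables))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE),
             file.path(out_dir, "run_metadata.json"))
  md <- c("# Run report", "",
          sprintf("Config hash: %s", meta$config_hash), "")
  for (nm in names(tables)) {
    md <- c(md, paste0("## ", gsub("_", " ", nm)), "")
    tab <- tables[[nm]]
    md <- c(md, paste(names(tab), collapse = " | "),
            paste(rep("---", ncol(tab)), collapse = " | "),
            apply(tab, 1, paste, collapse = " | "), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
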