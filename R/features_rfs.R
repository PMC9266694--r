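# Suicide-risk-factor features from the 13-category risk dictionary.

#' Risk-factor feature block
#'
#' One relative-frequency column per risk-dictionary category (13 columns)
#' plus one overall risk-word rate, all tagged `RFS`. The overall column is
#' the rate of tokens matching any category; when categories are disjoint it
#' equals the sum of the per-category rates.
#'
#' @param corpus an [si_corpus()]
#' @param risk_dict a `risk-dictionary` [si_lexicon()] (13 categories)
#' @return a 14-column `feature_block` tagged `RFS`
#' @export
rfs_block <- function(corpus, risk_dict) {
  if (nrow(corpus) == 0) stop("empty corpus")
  if (risk_dict$kind != "risk-dictionary") {
    stop("rfs_block requires a risk-dictionary lexicon (13 categories)")
  }
  counts <- category_counts(corpus, risk_dict$categories)
  lens <- lengths(corpus$tokens)
  rates <- counts / lens
  all_words <- unique(unlist(risk_dict$categories))
  overall <- vapply(corpus$tokens, function(tk) sum(tk %in% all_words), 0) / lens
  m <- cbind(rates, overall)
  colnames(m) <- c(paste0("rfs.", names(risk_dict$categories)), "rfs.overall")
  feature_block(m, "RFS", corpus$id)
}
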