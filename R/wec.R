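# Word-embedding clustering: candidate keyword extraction, Lloyd K-means on
# word vectors, distance-ranked keyword selection, per-post featurization.

#' Extract candidate keywords by part of speech
#'
#' Unique tokens whose POS tag is in `pos_keep` (content-word tags) and which
#' survive the embedding vocabulary lookup.
#'
#' @param corpus an [si_corpus()]
#' @param pos_keep character vector of POS codes to keep
#' @param embeddings optional `embedding_table`; candidates missing from its
#'   vocabulary are dropped
#' @return character vector of candidate keywords (first-occurrence order)
#' @export
extract_candidates <- function(corpus, pos_keep = c("n", "v", "a"),
                               embeddings = NULL) {
  toks <- unlist(corpus$tokens)
  tags <- unlist(corpus$pos)
  if (length(tags) != length(toks)) stop("corpus must carry POS tags aligned to tokens")
  cand <- unique(toks[tags %in% pos_keep])
  if (!is.null(embeddings)) cand <- cand[cand %in% embeddings$vocabulary]
  cand
}

#' Cluster candidate keywords with Lloyd K-means
#'
#' The clustering procedure is deliberately the plain Lloyd loop: initial
#' centers are chosen uniformly at random among the candidate vectors,
#' candidates are assigned to the nearest center (Euclidean distance, ties
#' broken toward the lowest cluster id), centers are recomputed as cluster
#' means, and the loop stops when assignments no longer change (or at
#' `max_iter`). A cluster that empties is re-seeded with the point farthest
#' from its current center.
#'
#' Because single-start Lloyd regularly lands in local optima on small
#' instances, the loop is restarted `n_init` times from fresh random centers
#' (the standard default in mainstream K-means implementations) and the run
#' with the lowest final within-cluster sum of squares is kept. Restarts are
#' deterministic functions of `seed`.
#'
#' @param candidates character vector of candidate words
#' @param embeddings an `embedding_table` containing all candidates
#' @param k number of clusters (must not exceed the number of candidates)
#' @param seed integer seed for center initialization
#' @param max_iter iteration cap per restart
#' @param n_init number of random restarts (best run kept)
#' @return an object of class `keyword_clustering` with `candidates`,
#'   `assignments` (named integer 1..k), `centroids` (k x d), `distances`
#'   (named, Euclidean distance to own centroid), `wss` (final within-cluster
#'   sum of squares), `wss_trace` (objective after each assignment step) and
#'   `iterations`
#' @export
kmeans_cluster <- function(candidates, embeddings, k, seed = 1L,
                           max_iter = 100L, n_init = 10L) {
  n <- length(candidates)
  if (k > n) stop("k (", k, ") exceeds number of candidates (", n, ")")
  if (k < 1) stop("k must be at least 1")
  if (n_init < 1) stop("n_init must be at least 1")
  miss <- setdiff(candidates, embeddings$vocabulary)
  if (length(miss) > 0) {
    stop("candidate(s) missing from embedding vocabulary: ",
         paste(head(miss, 5), collapse = ", "))
  }
  x <- embeddings$vectors[candidates, , drop = FALSE]

  dist2_to <- function(centers) {
    # n x k matrix of squared Euclidean distances
    xc <- rowSums(x^2)
    cc <- rowSums(centers^2)
    outer(xc, cc, "+") - 2 * x %*% t(centers)
  }

  lloyd_once <- function(run_seed) withr::with_seed(run_seed, {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    iter <- 0L
    wss_trace <- numeric(0)
    repeat {
      iter <- iter + 1L
      d2 <- dist2_to(centers)
      assignment <- max.col(-d2, ties.method = "first") # lowest cluster id on ties
      # re-seed empty clusters with the farthest point from its center
      repeat {
        sizes <- tabulate(assignment, nbins = k)
        empty <- which(sizes == 0)
        if (length(empty) == 0) break
        own <- d2[cbind(seq_len(n), assignment)]
        far <- which.max(own)
        centers[empty[1], ] <- x[far, ]
        d2 <- dist2_to(centers)
        assignment <- max.col(-d2, ties.method = "first")
      }
      wss_trace <- c(wss_trace, sum(pmax(d2[cbind(seq_len(n), assignment)], 0)))
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
      }
      if (identical(assignment, assign_old) || iter >= max_iter) break
      assign_old <- assignment
    }
    d2 <- dist2_to(centers)
    own <- pmax(d2[cbind(seq_len(n), assignment)], 0)
    structure(list(candidates = candidates,
                   assignments = stats::setNames(assignment, candidates),
                   centroids = centers,
                   distances = stats::setNames(sqrt(own), candidates),
                   wss = sum(own), wss_trace = wss_trace,
                   k = k, iterations = iter),
              class = "keyword_clustering")
  })

  best <- NULL
  for (i in seq_len(n_init)) {
    run <- lloyd_once(seed + i - 1L)
    if (is.null(best) || run$wss < best$wss) best <- run
  }
  best
}

#' @exportS3Method print keyword_clustering
print.keyword_clustering <- function(x, ...) {
  cat(sprintf("<keyword_clustering> %d candidates in %d clusters (wss %.4g, %d iterations)\n",
              length(x$candidates), x$k, x$wss, x$iterations))
  invisible(x)
}

#' Select keywords nearest to their cluster centers
#'
#' Within each cluster, candidates are ranked by ascending distance to the
#' centroid (ties broken lexicographically) and the top `m_per_cluster` are
#' kept.
#'
#' @param clustering a `keyword_clustering`
#' @param m_per_cluster keywords to keep per cluster
#' @return character vector of selected keywords, ordered by cluster then rank
#' @export
select_keywords <- function(clustering, m_per_cluster = 20L) {
  out <- character(0)
  for (j in seq_len(clustering$k)) {
    members <- clustering$candidates[clustering$assignments == j]
    if (length(members) == 0) next
    d <- clustering$distances[members]
    ord <- order(d, members)
    out <- c(out, members[ord][seq_len(min(m_per_cluster, length(members)))])
  }
  out
}

#' Silhouette sweep to suggest a cluster count
#'
#' Mean silhouette width of [kmeans_cluster()] solutions over a range of k.
#'
#' @param candidates,embeddings,seed as in [kmeans_cluster()]
#' @param k_range integer vector of cluster counts to try
#' @return data.frame with columns `k` and `mean_silhouette`
#' @export
silhouette_sweep <- function(candidates, embeddings, k_range = 2:15, seed = 1L) {
  x <- embeddings$vectors[candidates, , drop = FALSE]
  dmat <- as.matrix(stats::dist(x))
  res <- lapply(k_range, function(k) {
    cl <- kmeans_cluster(candidates, embeddings, k, seed = seed)
    a <- cl$assignments
    sil <- vapply(seq_along(candidates), function(i) {
      own <- which(a == a[i]); own <- setdiff(own, i)
      if (length(own) == 0) return(0)
      ai <- mean(dmat[i, own])
      bi <- min(vapply(setdiff(seq_len(k), a[i]), function(j) {
        mem <- which(a == j)
        if (length(mem) == 0) Inf else mean(dmat[i, mem])
      }, 0))
      if (!is.finite(bi)) return(0)
      (bi - ai) / max(ai, bi)
    }, 0)
    data.frame(k = k, mean_silhouette = mean(sil))
  })
  do.call(rbind, res)
}

#' Word-embedding-cluster feature block
#'
#' Per post: the relative frequency of each selected keyword plus, per
#' cluster, the aggregate rate of that cluster's selected keywords
#' (`|keywords| + k` columns, all tagged `WEC`). Alternatively
#' (`representation = "mean-embedding"`), the mean embedding vector of the
#' selected keywords present in the post.
#'
#' @param corpus an [si_corpus()]
#' @param keywords selected keywords from [select_keywords()]
#' @param clustering the `keyword_clustering` the keywords came from
#' @param embeddings required for `"mean-embedding"` representation
#' @param representation `"frequency"` (default) or `"mean-embedding"`
#' @return a `feature_block` tagged `WEC`
#' @export
wec_block <- function(corpus, keywords, clustering, embeddings = NULL,
                      representation = c("frequency", "mean-embedding")) {
  representation <- match.arg(representation)
  if (nrow(corpus) == 0) stop("empty corpus")
  if (length(keywords) == 0) stop("no keywords selected")
  lens <- lengths(corpus$tokens)
  if (representation == "mean-embedding") {
    if (is.null(embeddings)) stop("mean-embedding representation needs the embedding table")
    v <- embeddings$vectors[keywords, , drop = FALSE]
    m <- t(vapply(corpus$tokens, function(tk) {
      present <- keywords[keywords %in% tk]
      if (length(present) == 0) rep(0, ncol(v))
      else colMeans(v[present, , drop = FALSE])
    }, numeric(ncol(v))))
    colnames(m) <- sprintf("wec.dim%03d", seq_len(ncol(m)))
    return(feature_block(m, "WEC", corpus$id))
  }
  kw_counts <- matrix(0, nrow(corpus), length(keywords),
                      dimnames = list(NULL, paste0("wec.kw.", keywords)))
  for (j in seq_along(keywords)) {
    kw_counts[, j] <- vapply(corpus$tokens, function(tk) sum(tk == keywords[j]), 0)
  }
  kw_rates <- kw_counts / lens
  k <- clustering$k
  cl_of <- clustering$assignments[keywords]
  agg <- matrix(0, nrow(corpus), k,
                dimnames = list(NULL, sprintf("wec.cluster%02d", seq_len(k))))
  for (j in seq_len(k)) {
    sel <- which(cl_of == j)
    if (length(sel) > 0) agg[, j] <- rowSums(kw_rates[, sel, drop = FALSE])
  }
  feature_block(cbind(kw_rates, agg), "WEC", corpus$id)
}

#' End-to-end word-embedding-cluster featurization
#'
#' Convenience wrapper running skip-gram training, candidate extraction,
#' K-means clustering and keyword selection, then building the WEC block.
#'
#' @param corpus an [si_corpus()]
#' @param k number of keyword clusters
#' @param m_per_cluster keywords kept per cluster
#' @param pos_keep POS codes treated as content words
#' @param dim,window,epochs,min_count skip-gram parameters
#' @param seed integer seed driving embedding training and clustering
#' @return list with `block` (`feature_block`), `keywords`, `clustering`,
#'   `embeddings`
#' @export
wec_pipeline <- function(corpus, k = 10L, m_per_cluster = 20L,
                         pos_keep = c("n", "v", "a"),
                         dim = 100L, window = 5L, epochs = 5L, min_count = 2L,
                         seed = 1L) {
  emb <- train_skipgram(corpus, dim = dim, window = window, epochs = epochs,
                        min_count = min_count, seed = seed)
  cand <- extract_candidates(corpus, pos_keep, emb)
  if (length(cand) < k) stop("fewer candidates (", length(cand), ") than clusters (", k, ")")
  cl <- kmeans_cluster(cand, emb, k, seed = seed)
  kw <- select_keywords(cl, m_per_cluster)
  list(block = wec_block(corpus, kw, cl),
       keywords = kw, clustering = cl, embeddings = emb)
}
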