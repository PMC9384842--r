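# Cluster/switch scoring of verbal-fluency word streams: a stream is
# segmented left to right, a new cluster opening whenever the semantic
# relatedness of an adjacent word pair falls below a threshold. Cluster size
# follows the switching/clustering convention of (run length - 1).

#' Similarity providers for word streams
#'
#' A similarity provider maps a word pair to a relatedness value in
#' `[0, 1]`. `similarity_from_matrix()` wraps a labelled square matrix;
#' `similarity_from_embeddings()` wraps a words-by-dimensions embedding
#' matrix with cosine similarity rescaled from `[-1, 1]` to `[0, 1]`. Any
#' function `f(word_a, word_b)` with symmetric values and unit
#' self-similarity also works wherever a provider is accepted.
#'
#' @param mat Square numeric matrix with identical row/column word labels.
#' @param embeddings Numeric matrix, one row per word (rownames are the
#'   words), columns are embedding dimensions.
#' @return A function `(word_a, word_b) -> similarity`.
#' @export
similarity_from_matrix <- function(mat) {
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat))) {
    stop("similarity matrix needs identical row and column word labels")
  }
  function(a, b) {
    if (!(a %in% rownames(mat)) || !(b %in% rownames(mat))) {
      stop("similarity unknown for pair (", a, ", ", b, ")")
    }
    mat[a, b]
  }
}

#' @rdname similarity_from_matrix
#' @export
similarity_from_embeddings <- function(embeddings) {
  if (is.null(rownames(embeddings))) stop("embeddings need word rownames")
  norms <- sqrt(rowSums(embeddings^2))
  function(a, b) {
    if (!(a %in% rownames(embeddings)) || !(b %in% rownames(embeddings))) {
      stop("similarity unknown for pair (", a, ", ", b, ")")
    }
    cosine <- sum(embeddings[a, ] * embeddings[b, ]) / (norms[[a]] * norms[[b]])
    (cosine + 1) / 2
  }
}

.provider_of <- function(stream) {
  sim <- if (inherits(stream, "semantic_stream")) stream$similarity else
    stop("expected a semantic_stream")
  if (is.function(sim)) sim else similarity_from_matrix(sim)
}

#' Segment a word stream into semantic clusters
#'
#' Greedy left-to-right chaining: the stream is scanned once and a new
#' cluster starts whenever the similarity of the adjacent word pair falls
#' below `theta`. Switches are transitions between clusters
#' (`clusters - 1`); cluster size is, by convention, run length minus one
#' (a singleton has size 0), averaged over clusters.
#'
#' @param stream A `semantic_stream` (see [generate_word_stream()]), or any
#'   list with `words` plus a `similarity` matrix or provider function.
#' @param theta Similarity threshold in `(0, 1)` (default 0.5) on the
#'   `[0, 1]`-normalized relatedness scale.
#' @param size_convention `"run_minus_one"` (default) or `"run_length"`.
#' @return A `cluster_report`: list with `clusters` (list of word runs),
#'   `n_clusters`, `switches`, `mean_cluster_size`, `theta`.
#' @export
segment_clusters <- function(stream, theta = 0.5,
                             size_convention = c("run_minus_one", "run_length")) {
  size_convention <- match.arg(size_convention)
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  words <- stream$words
  if (length(words) < 1) stop("need at least one word")
  sim <- .provider_of(stream)
  breaks <- integer(0)
  if (length(words) > 1) {
    for (i in seq_len(length(words) - 1)) {
      if (sim(words[i], words[i + 1]) < theta) breaks <- c(breaks, i)
    }
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(words))
  clusters <- mapply(function(s, e) words[s:e], starts, ends,
                     SIMPLIFY = FALSE)
  sizes <- ends - starts + 1L
  mean_size <- if (size_convention == "run_minus_one") {
    mean(sizes - 1)
  } else {
    mean(sizes)
  }
  structure(list(clusters = clusters, n_clusters = length(clusters),
                 switches = length(clusters) - 1L,
                 cluster_sizes = sizes,
                 mean_cluster_size = mean_size,
                 theta = theta, size_convention = size_convention),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Cluster report: %d cluster(s), %d switch(es), mean size %.2f (theta = %g)\n",
              x$n_clusters, x$switches, x$mean_cluster_size, x$theta))
  invisible(x)
}

#' Battery-level cluster/switch metrics
#'
#' Segments one stream per administered trial, sums switches across trials
#' and pools all cluster sizes before averaging.
#'
#' @param streams List of `semantic_stream` objects, one per trial.
#' @inheritParams segment_clusters
#' @return List with `total_switches`, `mean_cluster_size`, and the per-trial
#'   `reports`.
#' @export
battery_cluster_metrics <- function(streams, theta = 0.5,
                                    size_convention = c("run_minus_one", "run_length")) {
  size_convention <- match.arg(size_convention)
  reports <- lapply(streams, segment_clusters, theta = theta,
                    size_convention = size_convention)
  sizes <- unlist(lapply(reports, `[[`, "cluster_sizes"))
  pooled <- if (size_convention == "run_minus_one") sizes - 1 else sizes
  list(total_switches = sum(vapply(reports, `[[`, 0L, "switches")),
       mean_cluster_size = mean(pooled),
       reports = reports)
}
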