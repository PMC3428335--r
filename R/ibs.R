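#' Configuration for IBS network inference
#'
#' @param word_length symbolic word length `m >= 1` (default 2). The
#'   series must satisfy `2^m <= length - m`.
#' @param n_permutations permutations of the sample order used for the
#'   null distribution (default 1000).
#' @param alpha significance level applied to BH-adjusted permutation
#'   p-values when building the network (default 0.05).
#' @param seed integer seed making the permutation null reproducible.
#' @return A list of class `ibs_config`. The `variant` field records the
#'   exact IBS weighting in force (average-rank ties, probability-weighted
#'   rank differences normalized to `[0, 1]`, zero increments binarized as
#'   "not increasing") so results are reproducible.
#' @export
ibs_config <- function(word_length = 2L, n_permutations = 1000L,
                       alpha = 0.05, seed = 1L) {
  if (word_length < 1 || word_length != floor(word_length)) {
    stop("word_length must be a positive integer")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(
    list(
      word_length = as.integer(word_length),
      n_permutations = as.integer(n_permutations),
      alpha = alpha, seed = as.integer(seed),
      variant = "rank-difference, average-rank ties, mean-probability weight, /(2^m - 1)"
    ),
    class = "ibs_config"
  )
}

# word-frequency profile of a series: binarize increments (x[i+1] > x[i]),
# slide an m-bit window, count the 2^m word types, rank by frequency
# (average ranks for ties). Returns rank and probability vectors.
.ibs_profile <- function(x, m) {
  z <- as.integer(diff(x) > 0)
  idx <- if (m == 1L) {
    z + 1L
  } else {
    drop(stats::embed(z, m) %*% 2^(seq_len(m) - 1)) + 1L
  }
  counts <- tabulate(idx, nbins = 2^m)
  list(rank = rank(-counts, ties.method = "average"), prob = counts / length(idx))
}

.check_ibs_series <- function(x, y, m) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < m + 2^m) {
    stop("series too short: need length >= m + 2^m = ", m + 2^m)
  }
}

#' Information Based Similarity distance between two series
#'
#' Maps each series to the binary sequence of its increments (1 where the
#' series increases, 0 otherwise), forms overlapping `m`-bit words, ranks
#' the `2^m` word types by frequency (average ranks for ties), and returns
#' the rank-difference distance weighted by the mean word probability,
#' normalized to `[0, 1]`:
#' \deqn{D = \frac{1}{2^m - 1} \sum_k |R_1(k) - R_2(k)|\,
#'       \frac{p_1(k) + p_2(k)}{2}.}
#' The distance is symmetric, zero for identical series, and depends only
#' on increment signs and word ranks, hence is invariant under strictly
#' monotone transforms of either series.
#'
#' @param x,y numeric series of equal length `>= m + 2^m`.
#' @param m word length (default 2).
#' @return Distance in `[0, 1]`.
#' @examples
#' ibs_distance(sin(1:30), cos(1:30), m = 2)
#' @export
ibs_distance <- function(x, y, m = 2L) {
  if (m < 1 || m != floor(m)) stop("m must be a positive integer")
  .check_ibs_series(x, y, m)
  px <- .ibs_profile(x, m)
  py <- .ibs_profile(y, m)
  sum(abs(px$rank - py$rank) * (px$prob + py$prob) / 2) / (2^m - 1)
}

# profiles for every row of a matrix: list of rank / prob matrices (genes x 2^m)
.profile_matrix <- function(vals, m) {
  nw <- 2^m
  rk <- pr <- matrix(NA_real_, nrow(vals), nw, dimnames = list(rownames(vals), NULL))
  for (i in seq_len(nrow(vals))) {
    p <- .ibs_profile(vals[i, ], m)
    rk[i, ] <- p$rank
    pr[i, ] <- p$prob
  }
  list(rank = rk, prob = pr)
}

# distances from one profile to every row of a profile matrix
.dist_to_all <- function(prof, pm, m) {
  rowSums(abs(sweep(pm$rank, 2, prof$rank)) * sweep(pm$prob, 2, prof$prob, "+") / 2) / (2^m - 1)
}

#' Permutation significance of IBS distances around a core gene set
#'
#' For every (core gene, other gene) pair, the IBS distance observed under
#' the current sample ordering is compared with the distances obtained by
#' permuting the sample order of the core gene's series. Smaller distance
#' means stronger similarity, so
#' `p = (1 + #\{D_perm <= D_obs\}) / (n_permutations + 1)`. Pairs between
#' two core genes are evaluated once (from the lexicographically smaller
#' member). Deterministic given `config$seed`.
#'
#' @param em an [expression_matrix()], typically with columns already in
#'   progression order (see [order_samples_by_marker()]).
#' @param core character vector of core gene ids (non-empty, all present
#'   in `em`).
#' @param config an [ibs_config()].
#' @return Data frame with columns `gene_a`, `gene_b` (canonical
#'   `gene_a < gene_b` order), `ibs_distance`, `p_value`.
#' @export
permutation_threshold <- function(em, core, config = ibs_config()) {
  stopifnot(inherits(em, "expression_matrix"), inherits(config, "ibs_config"))
  if (length(core) == 0L) stop("empty core gene set")
  if (!all(core %in% em$gene_ids)) {
    stop("core genes missing from the matrix: ", paste(setdiff(core, em$gene_ids), collapse = ", "))
  }
  m <- config$word_length
  n_samp <- ncol(em$values)
  if (n_samp < m + 2^m) {
    stop("too few samples for word_length ", m, ": need >= ", m + 2^m)
  }
  vals <- em$values
  pm <- .profile_matrix(vals, m)
  # partner sets: every gene except the core gene itself; core-core pairs
  # only from the lexicographically smaller member
  partners <- lapply(core, function(cg) {
    setdiff(em$gene_ids[!(em$gene_ids %in% core[core < cg])], cg)
  })
  names(partners) <- core
  obs <- lapply(core, function(cg) {
    prof <- list(rank = pm$rank[cg, ], prob = pm$prob[cg, ])
    .dist_to_all(prof, pm, m)[partners[[match(cg, core)]]]
  })
  names(obs) <- core
  hits <- lapply(obs, function(o) integer(length(o)))
  names(hits) <- core
  set.seed(config$seed)
  for (b in seq_len(config$n_permutations)) {
    perm <- sample.int(n_samp)
    for (cg in core) {
      prof <- .ibs_profile(vals[cg, perm], m)
      d <- .dist_to_all(prof, pm, m)[partners[[cg]]]
      hits[[cg]] <- hits[[cg]] + (d <= obs[[cg]])
    }
  }
  out <- do.call(rbind, lapply(core, function(cg) {
    data.frame(
      gene_a = pmin(cg, partners[[cg]]),
      gene_b = pmax(cg, partners[[cg]]),
      ibs_distance = unname(obs[[cg]]),
      p_value = unname((1 + hits[[cg]]) / (config$n_permutations + 1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# annotation precedence: breast_cancer > other_cancer > metabolic > other
.annotation_class <- function(genes, annotations) {
  i <- match(genes, annotations$gene_id)
  cls <- rep("other", length(genes))
  met <- !is.na(i) & annotations$is_metabolic[i]
  cls[met] <- "metabolic"
  oc <- !is.na(i) & annotations$cancer_score[i] == 1
  cls[oc] <- "other_cancer"
  bc <- !is.na(i) & annotations$cancer_score[i] == 2
  cls[bc] <- "breast_cancer"
  cls
}

#' Build the core-set-centered nonlinear-correlation network
#'
#' Computes permutation p-values for all core-to-genome IBS pairs
#' ([permutation_threshold()]), adjusts them by Benjamini-Hochberg across
#' all pairs, and keeps pairs with adjusted p at or below `config$alpha`.
#' Indirect correlations among the core genes themselves are retained, not
#' pruned. Each edge is annotated by the highest-precedence literature
#' class of its two members (breast cancer > other cancer > metabolic >
#' other).
#'
#' @inheritParams permutation_threshold
#' @param annotations an [annotation_table()] (genes absent from it are
#'   classed `"other"`).
#' @return Data frame of class `edge_table` with columns `gene_a`,
#'   `gene_b`, `ibs_distance`, `p_value`, `q_value`, `annotation_class`.
#'   The `ibs_config` used (including the IBS variant string) is attached
#'   as attribute `config`.
#' @export
build_network <- function(em, core, annotations, config = ibs_config()) {
  tab <- permutation_threshold(em, core, config)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  keep <- tab$q_value <= config$alpha
  edges <- tab[keep, , drop = FALSE]
  cls_a <- .annotation_class(edges$gene_a, annotations)
  cls_b <- .annotation_class(edges$gene_b, annotations)
  prec <- c(breast_cancer = 1, other_cancer = 2, metabolic = 3, other = 4)
  edges$annotation_class <- ifelse(prec[cls_a] <= prec[cls_b], cls_a, cls_b)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("edge_table", "data.frame")
  attr(edges, "config") <- config
  edges
}

#' @export
`[.edge_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.edge_table <- function(x, ...) {
  cat("edge_table:", nrow(x), "edges\n")
  if (nrow(x)) print(table(class = x$annotation_class))
  NextMethod()
}

#' Degree and co-regulation summary of an edge table
#'
#' @param edges an `edge_table` from [build_network()].
#' @param core character vector of core gene ids.
#' @return List with `degree` (named vector, edges incident to each core
#'   gene) and `co_regulation` (data frame of core-gene pairs with the
#'   number of shared partners).
#' @export
degree_summary <- function(edges, core) {
  partners <- lapply(core, function(cg) {
    unique(c(
      edges$gene_b[edges$gene_a == cg],
      edges$gene_a[edges$gene_b == cg]
    ))
  })
  names(partners) <- core
  degree <- vapply(partners, length, integer(1))
  pairs <- if (length(core) >= 2) t(utils::combn(sort(core), 2)) else matrix(character(0), 0, 2)
  co <- data.frame(
    core_a = pairs[, 1], core_b = pairs[, 2],
    shared = apply(pairs, 1, function(p) {
      length(intersect(
        setdiff(partners[[p[1]]], core),
        setdiff(partners[[p[2]]], core)
      ))
    }),
    stringsAsFactors = FALSE
  )
  list(degree = degree, co_regulation = co)
}

#' Export an edge table for network-visualization tools
#'
#' `write_sif` writes the simple-interaction format (`gene_a ibs gene_b`);
#' `write_edge_attributes` writes a tab-delimited attribute table;
#' `write_graphml` writes GraphML through igraph.
#'
#' @param edges an `edge_table`.
#' @param path output file.
#' @export
write_sif <- function(edges, path) {
  writeLines(paste(edges$gene_a, "ibs", edges$gene_b), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_edge_attributes <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges)[, c("gene_a", "gene_b", "ibs_distance", "p_value", "annotation_class")],
    directed = FALSE
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
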