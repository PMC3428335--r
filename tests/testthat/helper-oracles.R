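# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# IBS by brute force: words as substrings of a pasted character sequence,
# ranks by explicit pairwise comparison counting (average-rank identity).
oracle_ibs <- function(x, y, m) {
  word_profile <- function(s) {
    z <- ifelse(diff(s) > 0, "1", "0")
    str <- paste(z, collapse = "")
    words <- vapply(
      seq_len(nchar(str) - m + 1),
      function(i) substr(str, i, i + m - 1), character(1)
    )
    all_words <- apply(
      expand.grid(rep(list(c("0", "1")), m))[, rev(seq_len(m)), drop = FALSE],
      1, paste, collapse = ""
    )
    counts <- vapply(all_words, function(w) sum(words == w), numeric(1))
    rk <- vapply(seq_along(counts), function(k) {
      1 + sum(counts > counts[k]) + 0.5 * sum(counts[-k] == counts[k])
    }, numeric(1))
    list(rank = rk, prob = counts / length(words), words = all_words)
  }
  px <- word_profile(x)
  py <- word_profile(y)
  total <- 0
  for (k in seq_along(px$words)) {
    total <- total + abs(px$rank[k] - py$rank[k]) * (px$prob[k] + py$prob[k]) / 2
  }
  unname(total / (2^m - 1))
}

# GSEA running sum by an explicit step-by-step loop
oracle_es <- function(ranked, gene_set, weight = 1) {
  metric <- ranked$metric
  genes <- ranked$gene_id
  n <- length(genes)
  hit <- genes %in% gene_set
  nr <- sum(abs(metric[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) abs(metric[i])^weight / nr else 1 / sum(hit)
    } else {
      cur <- cur - 1 / (n - sum(hit))
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# hypergeometric upper tail by full enumeration of all draws (small N only)
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# hypergeometric upper tail from the combinatorial mass function
oracle_hyper_formula <- function(N, K, n, k) {
  js <- k:min(K, n)
  if (length(js) == 0 || k > min(K, n)) {
    return(if (k <= 0) 1 else 0)
  }
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small labeled expression matrix from a numeric matrix of log2 values
make_em <- function(lx, phenotype = NULL) {
  if (is.null(rownames(lx))) rownames(lx) <- sprintf("g%03d", seq_len(nrow(lx)))
  if (is.null(colnames(lx))) colnames(lx) <- sprintf("s%03d", seq_len(ncol(lx)))
  expression_matrix(2^lx, phenotype = phenotype)
}

# random admissible series for IBS property tests
random_series <- function(n, alphabet = NULL) {
  if (is.null(alphabet)) stats::runif(n) else sample(alphabet, n, replace = TRUE)
}

# canonical "a b" keys of an edge data frame for set comparison
edge_keys <- function(df, a = "regulator", b = "target") {
  paste(pmin(df[[a]], df[[b]]), pmax(df[[a]], df[[b]]))
}
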