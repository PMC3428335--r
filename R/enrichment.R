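#' Read or write gene-set collections in GMT format
#'
#' GMT is tab-delimited: set name, description, then member genes. Set
#' names must be unique and sets non-empty.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors with the
#'   descriptions attached as attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' @param sets named list of character vectors.
#' @param description optional per-set description vector.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  writeLines(
    vapply(seq_along(sets), function(i) {
      paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

#' Urn-model hypergeometric over-representation p-value
#'
#' Exact upper-tail probability `P(X >= k)` of observing at least the
#' actual overlap `k` between a hit list and a pathway when drawing
#' `|hits|` genes without replacement from the universe.
#'
#' @param hits character vector of significant genes (subset of `universe`).
#' @param pathway character vector of pathway members (subset of `universe`).
#' @param universe character vector of all assayed genes.
#' @return The exact upper-tail p-value.
#' @examples
#' hypergeometric_ora(letters[1:5], letters[1:5], letters[1:10]) # 1/choose(10, 5)
#' @export
hypergeometric_ora <- function(hits, pathway, universe) {
  hits <- unique(hits)
  pathway <- unique(pathway)
  universe <- unique(universe)
  if (!all(pathway %in% universe)) stop("pathway is not a subset of the universe")
  if (!all(hits %in% universe)) stop("hits are not a subset of the universe")
  k <- length(intersect(hits, pathway))
  stats::phyper(k - 1, length(pathway), length(universe) - length(pathway),
    length(hits),
    lower.tail = FALSE
  )
}

#' Over-representation analysis of a gene-set collection
#'
#' Applies [hypergeometric_ora()] to every set of a collection. Both the
#' unadjusted probability and the BH-adjusted q-value are reported. Sets
#' are intersected with the universe first.
#'
#' @inheritParams hypergeometric_ora
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @return Data frame with columns `set_name`, `set_size`,
#'   `overlap_count`, `overlap_genes`, `p_value`, `q_value`, ordered by
#'   `p_value`.
#' @export
ora_table <- function(hits, collection, universe) {
  universe <- unique(universe)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    ov <- intersect(intersect(hits, universe), pw)
    data.frame(
      set_name = nm, set_size = length(pw), overlap_count = length(ov),
      overlap_genes = paste(sort(ov), collapse = ";"),
      p_value = if (length(pw)) {
        hypergeometric_ora(intersect(hits, universe), pw, universe)
      } else {
        1
      },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Signal-to-noise ranking of genes between two phenotypes
#'
#' Per-gene `(mean1 - mean2) / (sd1 + sd2)` on log2 intensities, with each
#' group standard deviation floored at `max(0.2 * |group mean|, 0.2)` (the
#' convention of the reference GSEA implementation). Genes are returned in
#' descending metric order (phenotype-1-high genes at the top).
#'
#' @param em an [expression_matrix()] with two phenotype groups of at
#'   least two samples each.
#' @return Data frame with columns `gene_id`, `metric`, descending.
#' @export
signal2noise_ranking <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$phenotype)) stop("matrix carries no phenotype labels")
  lev <- unique(em$phenotype)
  if (length(lev) != 2L) stop("signal-to-noise needs exactly two phenotype groups")
  .s2n_ranking(log2(em$values), em$phenotype == lev[1], em$phenotype == lev[2])
}

# core signal-to-noise on a log2 matrix and two logical group masks
.s2n_ranking <- function(lx, g1, g2) {
  if (sum(g1) < 2 || sum(g2) < 2) stop("need at least two samples per phenotype group")
  m1 <- rowMeans(lx[, g1, drop = FALSE])
  m2 <- rowMeans(lx[, g2, drop = FALSE])
  n1 <- sum(g1)
  n2 <- sum(g2)
  s1 <- sqrt((rowSums(lx[, g1, drop = FALSE]^2) - n1 * m1^2) / (n1 - 1))
  s2 <- sqrt((rowSums(lx[, g2, drop = FALSE]^2) - n2 * m2^2) / (n2 - 1))
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s2 <- pmax(s2, 0.2 * abs(m2), 0.2)
  metric <- (m1 - m2) / (s1 + s2)
  out <- data.frame(
    gene_id = rownames(lx), metric = unname(metric),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$metric, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Weighted GSEA enrichment score
#'
#' Kolmogorov-Smirnov-style running sum over a ranked gene list: at each
#' gene-set member ("hit") the sum increases proportionally to
#' `|metric|^weight_exponent` (normalized over hits), at each non-member it
#' decreases by `1/(N - Nh)`. The enrichment score is the running-sum value
#' of largest magnitude.
#'
#' @param ranked data frame with columns `gene_id`, `metric` in descending
#'   metric order (see [signal2noise_ranking()]), or a named numeric
#'   vector sorted descending.
#' @param gene_set character vector of member genes; must intersect the
#'   ranked list and must not cover it entirely.
#' @param weight_exponent hit-weight exponent (default 1; 0 gives the
#'   classic unweighted statistic).
#' @return List with `es` (in `[-1, 1]`), `running` (the running-sum
#'   profile), `hit_index` (positions of the set members) and
#'   `leading_edge` (member genes up to and including the extremum).
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  if (is.data.frame(ranked)) {
    metric <- stats::setNames(ranked$metric, ranked$gene_id)
  } else {
    metric <- ranked
  }
  if (is.null(names(metric))) stop("ranked list must carry gene names")
  n <- length(metric)
  hit <- names(metric) %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set is disjoint from the ranked list")
  if (nh == n) stop("gene set covers the entire ranked list; miss decrement undefined")
  w <- abs(metric)^weight_exponent
  wsum <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (wsum > 0) w[hit] / wsum else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) {
    names(metric)[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    names(metric)[seq.int(i_ext, n)][hit[seq.int(i_ext, n)]]
  }
  list(es = es, running = running, hit_index = which(hit), leading_edge = leading)
}

#' GSEA with phenotype permutations: NES, nominal p and FDR q
#'
#' Computes the weighted enrichment score of every gene set against the
#' signal-to-noise ranking, then permutes the phenotype labels
#' `n_permutations` times, recomputing the ranking and scores each time.
#' `NES = ES / mean(same-sign permutation ES)`; the nominal p-value is the
#' same-sign permutation tail fraction (it can be exactly 0); FDR q
#' follows the standard multi-set normalized-ES procedure. A
#' `"geneset"` permutation mode (random member sets of the same size,
#' ranking held fixed) is available for very small cohorts.
#'
#' @param em an [expression_matrix()] with two phenotype groups.
#' @param collection named list of gene sets.
#' @param n_permutations number of permutations (>= 1; default 1000).
#' @param seed integer seed.
#' @param weight_exponent passed to [gsea_es()].
#' @param permutation `"phenotype"` (default) or `"geneset"`.
#' @return Data frame of class `gsea_result` with columns `set_name`,
#'   `size`, `es`, `nes`, `nominal_p`, `fdr_q`, `leading_edge`
#'   (semicolon-collapsed), ordered by `nominal_p`.
#' @export
gsea_significance <- function(em, collection, n_permutations = 1000L, seed = 1L,
                              weight_exponent = 1,
                              permutation = c("phenotype", "geneset")) {
  stopifnot(inherits(em, "expression_matrix"))
  permutation <- match.arg(permutation)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (length(collection) == 0L) stop("empty gene-set collection")
  if (is.null(em$phenotype)) stop("matrix carries no phenotype labels")
  lev <- unique(em$phenotype)
  if (length(lev) != 2L) stop("GSEA needs exactly two phenotype groups")
  if (sum(em$phenotype == lev[1]) < 2 || sum(em$phenotype == lev[2]) < 2) {
    stop("too few samples per phenotype to permute")
  }
  lx <- log2(em$values)
  obs_rank <- .s2n_ranking(lx, em$phenotype == lev[1], em$phenotype == lev[2])
  obs <- lapply(collection, function(gs) gsea_es(obs_rank, gs, weight_exponent))
  es <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(collection, function(gs) length(intersect(gs, em$gene_ids)), integer(1))

  set.seed(seed)
  nset <- length(collection)
  perm_es <- matrix(NA_real_, nset, n_permutations,
    dimnames = list(names(collection), NULL)
  )
  if (permutation == "phenotype") {
    for (b in seq_len(n_permutations)) {
      ph <- sample(em$phenotype)
      rk <- .s2n_ranking(lx, ph == lev[1], ph == lev[2])
      for (i in seq_len(nset)) {
        perm_es[i, b] <- gsea_es(rk, collection[[i]], weight_exponent)$es
      }
    }
  } else {
    for (b in seq_len(n_permutations)) {
      for (i in seq_len(nset)) {
        gs <- sample(em$gene_ids, sizes[i])
        perm_es[i, b] <- gsea_es(obs_rank, gs, weight_exponent)$es
      }
    }
  }

  norm_pos <- pmax(rowMeans(perm_es * (perm_es > 0)) /
    pmax(rowMeans(perm_es > 0), .Machine$double.eps), .Machine$double.eps)
  norm_neg <- pmax(-rowMeans(perm_es * (perm_es < 0)) /
    pmax(rowMeans(perm_es < 0), .Machine$double.eps), .Machine$double.eps)
  nes <- ifelse(es >= 0, es / norm_pos, es / norm_neg)
  nes_perm <- perm_es / ifelse(perm_es >= 0, norm_pos[row(perm_es)], norm_neg[row(perm_es)])

  nominal_p <- vapply(seq_len(nset), function(i) {
    pe <- perm_es[i, ]
    if (es[i] >= 0) {
      same <- pe[pe >= 0]
      if (!length(same)) return(1)
      mean(same >= es[i])
    } else {
      same <- pe[pe < 0]
      if (!length(same)) return(1)
      mean(same <= es[i])
    }
  }, numeric(1))

  all_perm <- as.vector(nes_perm)
  fdr_q <- vapply(seq_len(nset), function(i) {
    if (nes[i] >= 0) {
      num <- mean(all_perm[all_perm >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(all_perm[all_perm < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num)) num <- 1
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  # q is reported monotone non-decreasing in nominal p within sign groups
  for (sgn in c(TRUE, FALSE)) {
    grp <- which((nes >= 0) == sgn)
    if (length(grp) > 1) {
      ord <- grp[order(nominal_p[grp])]
      fdr_q[ord] <- cummax(fdr_q[ord])
    }
  }

  out <- data.frame(
    set_name = names(collection),
    size = sizes,
    es = unname(es),
    nes = unname(nes),
    nominal_p = nominal_p,
    fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$nominal_p, -abs(out$nes)), ]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' @export
`[.gsea_result` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("GSEA results for", nrow(x), "gene sets\n")
  print(as.data.frame(x[, c("set_name", "size", "es", "nes", "nominal_p", "fdr_q")]),
    digits = 3
  )
  invisible(x)
}
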