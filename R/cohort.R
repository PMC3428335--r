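#' Gene annotation table for master-regulator mining
#'
#' One row per gene with the four data-mining constraint columns:
#' `is_tf` (experimentally supported transcription-factor activity),
#' `cancer_score` (2 = breast-cancer association, 1 = other solid tumor,
#' 0 = none; liquid neoplasms are excluded when the table is built),
#' `is_metabolic` (protein product participates in cellular metabolic
#' pathways) and `has_thermo_params` (the transcript has a complete
#' physicochemical characterization, i.e. calibrated hybridization
#' parameters).
#'
#' @param df data frame with columns `gene_id`, `is_tf`, `cancer_score`,
#'   `is_metabolic`, `has_thermo_params`.
#' @return The validated data frame with class `annotation_table`.
#' @export
annotation_table <- function(df) {
  need <- c("gene_id", "is_tf", "cancer_score", "is_metabolic", "has_thermo_params")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation table")
  if (!all(df$cancer_score %in% 0:2)) stop("cancer_score must be in {0, 1, 2}")
  df <- df[, need]
  df$is_tf <- as.logical(df$is_tf)
  df$is_metabolic <- as.logical(df$is_metabolic)
  df$has_thermo_params <- as.logical(df$has_thermo_params)
  df$cancer_score <- as.integer(df$cancer_score)
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read or write an annotation table as tab-delimited text
#'
#' @param path file path.
#' @return `read_annotations` returns an [annotation_table()].
#' @export
read_annotations <- function(path) {
  annotation_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param annotations an [annotation_table()].
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Order samples by a progression-marker gene
#'
#' Orders the independent steady-state samples ascending by the marker
#' gene's intensity, the surrogate time course used in place of an actual
#' longitudinal design (marker default elsewhere: BNIP3, probe
#' 201848_s_at, a marker of progression and malignancy in primary breast
#' cancer). Sorting is stable: tied samples keep their original column
#' order.
#'
#' @param em an [expression_matrix()].
#' @param marker gene id of the marker; must be present in `em`.
#' @return Character vector of sample ids in progression order.
#' @export
order_samples_by_marker <- function(em, marker = "201848_s_at") {
  stopifnot(inherits(em, "expression_matrix"))
  if (!marker %in% em$gene_ids) {
    stop("marker gene '", marker, "' not present in the matrix")
  }
  em$sample_ids[order(em$values[marker, ])]
}

#' Moderated two-group differential expression
#'
#' Per-gene two-sample t statistic on log2 intensities with gene-wise
#' variance shrunk toward the cohort-median pooled variance:
#' `s2_tilde = w * median(s2) + (1 - w) * s2_gene` with fixed weight
#' `w = shrink` (default 0.5). P-values from the t distribution on the
#' pooled degrees of freedom, two-sided; q-values by Benjamini-Hochberg.
#' Deterministic, and invariant to sample column order within phenotype
#' groups.
#'
#' @param em an [expression_matrix()] with a two-level phenotype and at
#'   least two samples per level.
#' @param shrink shrinkage weight toward the median pooled variance,
#'   in `[0, 1]`.
#' @return Data frame of class `de_result` with columns `gene_id`,
#'   `log_fold_change` (log2, group1 - group2 where group1 is the first
#'   phenotype level encountered), `statistic`, `p_value`, `q_value`,
#'   sorted by `p_value`.
#' @export
differential_expression <- function(em, shrink = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$phenotype)) stop("matrix carries no phenotype labels")
  lev <- unique(em$phenotype)
  if (length(lev) != 2L) {
    stop("differential expression needs exactly two phenotype groups, got ", length(lev))
  }
  g1 <- em$phenotype == lev[1]
  g2 <- em$phenotype == lev[2]
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("need at least two samples per phenotype group")
  if (shrink < 0 || shrink > 1) stop("shrink must be in [0, 1]")
  lx <- log2(em$values)
  m1 <- rowMeans(lx[, g1, drop = FALSE])
  m2 <- rowMeans(lx[, g2, drop = FALSE])
  v1 <- apply(lx[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(lx[, g2, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  s2_tilde <- shrink * stats::median(s2) + (1 - shrink) * s2
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  stat <- ifelse(se == 0 & m1 == m2, 0, (m1 - m2) / se)
  p <- 2 * stats::pt(-abs(stat), df = df)
  out <- data.frame(
    gene_id = em$gene_ids,
    log_fold_change = m1 - m2,
    statistic = stat,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select the master-regulator core set
#'
#' Intersects the four data-mining constraints over the differentially
#' expressed genes: significant differential expression at
#' `q <= q_threshold`, known transcription-factor activity, literature
#' association with breast (score 2) or other solid (score 1) tumors,
#' metabolic-pathway membership, and availability of a complete
#' thermodynamic characterization. On the breast-carcinoma cohort this
#' intersection yields the four master regulators MNDA, POU2AF1, MEF2C
#' and SMAD3.
#'
#' @param annotations an [annotation_table()] covering the DE genes.
#' @param de a `de_result` from [differential_expression()].
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @return Character vector of core-set gene ids, ordered by decreasing
#'   cancer score then gene id (breast-associated genes first).
#' @export
select_core_set <- function(annotations, de, q_threshold = 0.05) {
  stopifnot(inherits(annotations, "annotation_table"))
  sig <- de$gene_id[de$q_value <= q_threshold]
  ann <- annotations[annotations$gene_id %in% sig, , drop = FALSE]
  keep <- ann$is_tf & ann$cancer_score >= 1 & ann$is_metabolic & ann$has_thermo_params
  core <- ann[keep, , drop = FALSE]
  core$gene_id[order(-core$cancer_score, core$gene_id)]
}
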