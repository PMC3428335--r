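#' Gene sets matching a synthetic cohort
#'
#' Builds a gene-set collection for enrichment testing on simulated data:
#' one set per regulator holding its planted targets, one set holding all
#' differentially expressed genes, and `n_random` random background sets.
#'
#' @param truth a `ground_truth` from [simulate_expression()].
#' @param universe character vector of all simulated gene ids.
#' @param n_random number of random decoy sets.
#' @param set_size size of each random set.
#' @param seed integer seed for the decoy draw.
#' @return Named list of gene sets.
#' @export
synthetic_gene_sets <- function(truth, universe, n_random = 20L, set_size = 15L,
                                seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  sets <- list()
  for (tf in unique(truth$true_edges$regulator)) {
    sets[[paste0("TARGETS_", tf)]] <- truth$true_edges$target[truth$true_edges$regulator == tf]
  }
  if (length(truth$de_genes)) sets[["DE_MODULE"]] <- truth$de_genes
  set.seed(seed)
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(universe, min(set_size, length(universe)))
  }
  sets
}

#' Pipeline configuration
#'
#' Bundles the stage configurations and input paths of the full analysis
#' workflow. When `expression` is `NULL` the cohort is synthesized from
#' `synthetic` (with its annotations, parameters and gene sets generated
#' alongside); otherwise `expression`, `phenotype`, `annotations`,
#' `thermo_params` and `gene_sets` name the input files. All stage
#' randomness is fanned out deterministically from `seed`.
#'
#' @param expression optional path to a TSV/GCT expression matrix.
#' @param phenotype optional path to a CLS phenotype file.
#' @param annotations optional path to an annotation table.
#' @param thermo_params optional path to a hybridization-parameter table.
#' @param gene_sets optional path to a GMT collection.
#' @param synthetic a [synthetic_config()] used when `expression` is NULL.
#' @param ibs an [ibs_config()] for the network stage.
#' @param marker progression-marker gene id.
#' @param q_threshold DE significance cutoff for core-set selection and
#'   ORA hits.
#' @param gsea_permutations,weight_exponent GSEA stage settings.
#' @param seed global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, phenotype = NULL,
                            annotations = NULL, thermo_params = NULL,
                            gene_sets = NULL,
                            synthetic = synthetic_config(),
                            ibs = ibs_config(),
                            marker = "201848_s_at",
                            q_threshold = 0.05,
                            gsea_permutations = 1000L,
                            weight_exponent = 1,
                            seed = 1L) {
  for (p in c(expression, phenotype, annotations, thermo_params, gene_sets)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(
    list(
      expression = expression, phenotype = phenotype,
      annotations = annotations, thermo_params = thermo_params,
      gene_sets = gene_sets, synthetic = synthetic, ibs = ibs,
      marker = marker, q_threshold = q_threshold,
      gsea_permutations = as.integer(gsea_permutations),
      weight_exponent = weight_exponent, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# stage provenance record; no timestamps so reruns are byte-identical
.write_provenance <- function(out_dir, stage, inputs, seed, config_hash) {
  jsonlite::write_json(
    list(
      stage = stage, inputs = as.list(inputs), seed = seed,
      config_hash = config_hash,
      version = as.character(utils::packageVersion("thermoreg"))
    ),
    file.path(out_dir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, digits = NA
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) cohort synthesis, differential
#' expression, core-set selection, progression ordering by the marker
#' gene, thermodynamic profiling, IBS network inference, hypergeometric
#' over-representation and GSEA. Each stage writes its result table plus a
#' JSON provenance record (stage inputs, seed, config hash, package
#' version) into `out_dir`. Re-running with the same configuration
#' produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")), cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  seed_syn <- config$seed + 11L
  seed_ibs <- config$seed + 101L
  seed_gsea <- config$seed + 202L

  stage <- "synthesis"
  res <- list()
  tryCatch(
    {
      if (is.null(config$expression)) {
        syn <- config$synthetic
        syn$seed <- seed_syn
        sim <- simulate_expression(syn)
        em <- sim$matrix
        params <- sim$params
        annotations <- make_annotations(syn)
        gene_sets <- synthetic_gene_sets(sim$truth, em$gene_ids, seed = seed_syn)
        write_expression(em, file.path(out_dir, "expression.tsv"))
        write_cls(em$phenotype, file.path(out_dir, "phenotype.cls"))
        write_truth(sim$truth, file.path(out_dir, "truth.json"))
        write_hyb_params(params, file.path(out_dir, "thermo_params.tsv"))
        write_annotations(annotations, file.path(out_dir, "annotations.tsv"))
        write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
        .write_provenance(out_dir, stage, "synthetic_config", seed_syn, config_hash)
        res$truth <- sim$truth
      } else {
        em <- read_expression(config$expression, phenotype = config$phenotype)
        params <- if (!is.null(config$thermo_params)) {
          read_hyb_params(config$thermo_params)
        } else {
          core_params()
        }
        annotations <- read_annotations(config$annotations)
        gene_sets <- read_gmt(config$gene_sets)
      }
      res$matrix <- em

      stage <- "differential_expression"
      de <- differential_expression(em)
      utils::write.table(de, file.path(out_dir, "de.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      .write_provenance(out_dir, stage, "expression.tsv", config$seed, config_hash)
      res$de <- de

      stage <- "core_set"
      core <- select_core_set(annotations, de, config$q_threshold)
      writeLines(core, file.path(out_dir, "core_set.txt"))
      .write_provenance(out_dir, stage, "de.tsv", config$seed, config_hash)
      res$core <- core

      stage <- "marker_ordering"
      ord <- order_samples_by_marker(em, config$marker)
      writeLines(ord, file.path(out_dir, "sample_order.txt"))
      .write_provenance(out_dir, stage, "expression.tsv", config$seed, config_hash)
      em_ord <- em[, ord]
      res$order <- ord

      stage <- "thermo_profile"
      prof <- thermo_profile(em_ord, params)
      write_thermo_profile(prof, file.path(out_dir, "thermo_profile.tsv"))
      utils::write.table(rank_by_chemical_potential(prof),
        file.path(out_dir, "mu_ranking.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      .write_provenance(out_dir, stage, "thermo_params.tsv", config$seed, config_hash)
      res$profile <- prof

      stage <- "ibs_network"
      ibs_cfg <- config$ibs
      ibs_cfg$seed <- seed_ibs
      edges <- build_network(em_ord, core, annotations, ibs_cfg)
      write_sif(edges, file.path(out_dir, "network.sif"))
      write_edge_attributes(edges, file.path(out_dir, "network_edges.tsv"))
      deg <- degree_summary(edges, core)
      utils::write.table(
        data.frame(core_gene = names(deg$degree), degree = unname(deg$degree)),
        file.path(out_dir, "network_degree.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      .write_provenance(out_dir, stage, "core_set.txt", seed_ibs, config_hash)
      res$network <- edges

      stage <- "ora"
      hits <- de$gene_id[de$q_value <= config$q_threshold]
      ora <- ora_table(hits, gene_sets, em$gene_ids)
      utils::write.table(ora, file.path(out_dir, "ora.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      .write_provenance(out_dir, stage, "gene_sets.gmt", config$seed, config_hash)
      res$ora <- ora

      stage <- "gsea"
      gsea <- gsea_significance(em, gene_sets,
        n_permutations = config$gsea_permutations,
        seed = seed_gsea, weight_exponent = config$weight_exponent
      )
      utils::write.table(as.data.frame(gsea), file.path(out_dir, "gsea.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      .write_provenance(out_dir, stage, "gene_sets.gmt", seed_gsea, config_hash)
      res$gsea <- gsea
    },
    error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  res$out_dir <- out_dir
  invisible(res)
}
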