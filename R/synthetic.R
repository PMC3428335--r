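#' Configuration for the synthetic expression-cohort generator
#'
#' Describes a synthetic tumor/control cohort with the statistical
#' structure the downstream analyses assume: a latent progression variable
#' per sample, a strictly monotone progression-marker gene, a set of
#' master-regulator transcription factors (TFs) with distinct smooth
#' latent-concentration curves along progression, target genes generated
#' from their TF's latent concentration through a link function, background
#' genes with independent biological variation, a tumor/control effect on
#' the regulated genes, and intensities produced by the forward
#' hybridization isotherm plus multiplicative log-normal technical noise.
#'
#' @param n_tf number of TF (regulator) genes; defaults to the four
#'   calibrated master-regulator probes of [core_params()].
#' @param n_targets_per_tf targets generated per TF.
#' @param n_background unregulated background genes.
#' @param n_tumor,n_control samples per phenotype (`n_tumor + n_control >= 2`).
#' @param tf_params [hyb_params()] for the TF genes; rows beyond `n_tf` are
#'   ignored, extra TFs beyond the supplied rows get parameters drawn from
#'   `target_param_ranges`.
#' @param target_param_ranges list with two-element ranges `delta_g_hyb`
#'   and `saturation` for the non-TF genes.
#' @param link_function TF-to-target link: `"linear"`,
#'   `"monotone-nonlinear"` (power law) or `"threshold"`.
#' @param noise_sd technical noise standard deviation on the log2-intensity
#'   scale (>= 0).
#' @param tf_bio_sd biological per-sample fluctuation of each TF's latent
#'   log2-concentration around its zigzag progression program; targets
#'   inherit program and fluctuation through the link function. Kept small
#'   by default: the serial (program) component along the progression
#'   ordering is the signal the permutation-thresholded IBS stage can
#'   recover, while exchangeable per-sample fluctuation is invisible to a
#'   sample-permutation null.
#' @param bg_sd biological (per-sample) variation of background genes on
#'   the log2-concentration scale; kept, like `tf_bio_sd`, separate from
#'   `noise_sd` so noise-free runs still have non-degenerate cohort
#'   structure.
#' @param marker_name probe id of the progression marker.
#' @param de_effect_size tumor-vs-control shift, in log2 units, applied to
#'   the latent concentrations of the regulated (TF and, through the link,
#'   target) genes.
#' @param seed integer seed; the whole simulation is deterministic given
#'   the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tf = 4,
                             n_targets_per_tf = 10,
                             n_background = 500,
                             n_tumor = 100,
                             n_control = 100,
                             tf_params = core_params(),
                             target_param_ranges = list(
                               delta_g_hyb = c(430, 480),
                               saturation = c(2000, 6000)
                             ),
                             link_function = c("linear", "monotone-nonlinear", "threshold"),
                             noise_sd = 0.1,
                             tf_bio_sd = 0.05,
                             bg_sd = 0.5,
                             marker_name = "201848_s_at",
                             de_effect_size = 1,
                             seed = 1L) {
  link_function <- match.arg(link_function)
  counts <- c(
    n_tf = n_tf, n_targets_per_tf = n_targets_per_tf,
    n_background = n_background, n_tumor = n_tumor, n_control = n_control
  )
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("all counts must be non-negative integers")
  }
  if (n_tumor + n_control < 2) stop("need at least 2 samples in total")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tf_bio_sd < 0) stop("tf_bio_sd must be >= 0")
  if (bg_sd < 0) stop("bg_sd must be >= 0")
  stopifnot(inherits(tf_params, "hyb_params"))
  if (any(tf_params$saturation <= 0)) stop("tf_params saturation constants must be > 0")
  rng <- target_param_ranges
  if (!all(c("delta_g_hyb", "saturation") %in% names(rng))) {
    stop("target_param_ranges needs 'delta_g_hyb' and 'saturation' ranges")
  }
  structure(
    list(
      n_tf = as.integer(n_tf), n_targets_per_tf = as.integer(n_targets_per_tf),
      n_background = as.integer(n_background),
      n_tumor = as.integer(n_tumor), n_control = as.integer(n_control),
      tf_params = tf_params, target_param_ranges = rng,
      link_function = link_function, noise_sd = noise_sd,
      tf_bio_sd = tf_bio_sd, bg_sd = bg_sd,
      marker_name = marker_name, de_effect_size = de_effect_size,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# target link functions; elementwise, strictly monotone except "threshold"
.apply_link <- function(link, conc, b) {
  switch(link,
    "linear" = b * conc,
    "monotone-nonlinear" = b * 1000^(1 - 1.6) * conc^1.6,
    "threshold" = 120 + 600 * b * (conc > 1500)
  )
}

#' Simulate a synthetic expression cohort with recorded ground truth
#'
#' Generates the cohort described by a [synthetic_config()]. The latent
#' progression (malignancy) variable is uniform per sample, with controls
#' drawn from the low segment of the axis (`[0, 0.35]`) and tumors from
#' the high segment (`[0.25, 1]`), as expected of a progression marker
#' that separates phenotypes; the marker gene's
#' latent concentration is a strictly monotone (affine in log2) map of it;
#' each TF's latent log2-concentration follows a distinct piecewise-linear
#' zigzag program along progression (a unique motif of up/down steps,
#' which is what makes regulators mutually distinguishable by the rank
#' profile of their increment words) plus a small independent per-sample
#' biological fluctuation (`tf_bio_sd`); each target is an elementwise
#' link-function image of its TF's latent concentration, so it shares its
#' regulator's motif exactly; tumor samples shift the regulated genes by
#' `de_effect_size` log2 units; intensities are the forward isotherm of
#' the latent concentrations with multiplicative log-normal technical noise
#' truncated below each gene's saturation constant.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]),
#'   `truth` (a `ground_truth` with `true_edges`, `progression_order`,
#'   `de_genes`, `per_gene_concentration`), and `params` (a [hyb_params()]
#'   table covering every simulated gene).
#' @examples
#' sim <- simulate_expression(synthetic_config(
#'   n_targets_per_tf = 2,
#'   n_background = 5, n_tumor = 10, n_control = 10
#' ))
#' sim$matrix
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_samp <- config$n_tumor + config$n_control
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  phenotype <- c(rep("tumor", config$n_tumor), rep("control", config$n_control))

  # latent progression (malignancy) per sample: uniform, with controls on
  # the low segment of the axis and tumors higher, as expected of a
  # malignancy marker; the two ranges overlap slightly
  u <- stats::runif(n_samp)
  t_lat <- ifelse(phenotype == "tumor", 0.30 + 0.70 * u, 0.32 * u)

  # gene inventory
  n_tf <- config$n_tf
  tf_ids <- character(0)
  if (n_tf > 0) {
    n_known <- min(n_tf, nrow(config$tf_params))
    tf_ids <- config$tf_params$gene_id[seq_len(n_known)]
    if (n_tf > n_known) {
      tf_ids <- c(tf_ids, sprintf("TF%02d", seq.int(n_known + 1L, n_tf)))
    }
  }
  tg_ids <- if (config$n_targets_per_tf > 0 && n_tf > 0) {
    as.vector(t(outer(tf_ids, seq_len(config$n_targets_per_tf),
      function(g, j) sprintf("%s.t%02d", g, j)
    )))
  } else {
    character(0)
  }
  bg_ids <- if (config$n_background > 0) {
    sprintf("bg%04d", seq_len(config$n_background))
  } else {
    character(0)
  }
  gene_ids <- c(tf_ids, tg_ids, bg_ids, config$marker_name)

  # per-target link slopes (low fractional occupancy relative to TFs)
  n_tg <- length(tg_ids)
  b_tg <- stats::runif(n_tg, 0.15, 0.45)

  # hybridization parameters: known TF rows, drawn ranges for the rest
  rng <- config$target_param_ranges
  n_drawn <- length(gene_ids) - min(n_tf, nrow(config$tf_params))
  dg_drawn <- stats::runif(n_drawn, rng$delta_g_hyb[1], rng$delta_g_hyb[2])
  sat_drawn <- stats::runif(n_drawn, rng$saturation[1], rng$saturation[2])
  n_known <- min(n_tf, nrow(config$tf_params))
  params <- hyb_params(
    gene_id = gene_ids,
    delta_g_hyb = c(config$tf_params$delta_g_hyb[seq_len(n_known)], dg_drawn),
    saturation = c(config$tf_params$saturation[seq_len(n_known)], sat_drawn),
    temperature = config$tf_params$temperature[1],
    gas_constant = config$tf_params$gas_constant[1]
  )

  # background genes sit at low-to-moderate abundance; regulators operate
  # at distinctly higher fractional occupancy of their probes, which is
  # what gives them the lowest chemical potentials of transcription
  bg_mean <- stats::runif(config$n_background, 100, 350)
  bg_eps <- matrix(
    stats::rnorm(config$n_background * n_samp, 0, config$bg_sd),
    config$n_background, n_samp
  )

  # latent concentrations (pM), genes x samples
  conc <- matrix(NA_real_, length(gene_ids), n_samp,
    dimnames = list(gene_ids, sample_ids)
  )
  de_shift <- ifelse(phenotype == "tumor", 2^config$de_effect_size, 1)
  tf_eps <- matrix(stats::rnorm(n_tf * n_samp, 0, config$tf_bio_sd), n_tf, n_samp)
  # Distinct zigzag regulatory programs along progression: each TF takes
  # one up/down log2 step per progression rank following a periodic motif
  # unique to that regulator. The motifs were chosen (combinatorial search
  # over balanced cyclic words without 4-runs) to maximize the worst-case
  # IBS rank-profile distance between different regulators and to the
  # monotone marker, so a regulator's word profile is shared exactly with
  # its own targets (through the link) but far from every other program.
  motifs <- list(
    c(1, 1, 1, 0, 0, 0),
    c(1, 1, 0, 1, 0, 0),
    c(1, 0, 1, 1, 0, 0),
    c(1, 0, 1, 1, 1, 0, 1, 0, 1, 0, 0, 0)
  )
  step_h <- 0.9 # log2 per progression-rank step
  rnk <- rank(t_lat, ties.method = "first")
  for (g in seq_along(tf_ids)) {
    mo <- motifs[[(g - 1) %% length(motifs) + 1]]
    steps <- (2 * mo - 1)[(seq_len(n_samp - 1) - 1) %% length(mo) + 1]
    path <- cumsum(c(0, steps))
    path <- path - mean(range(path))
    base <- 400
    conc[tf_ids[g], ] <- base * 2^(step_h * path[rnk] + tf_eps[g, ]) * de_shift
  }
  if (n_tg > 0) {
    for (k in seq_len(n_tg)) {
      tf_of <- tf_ids[(k - 1) %/% config$n_targets_per_tf + 1L]
      conc[tg_ids[k], ] <- .apply_link(config$link_function, conc[tf_of, ], b_tg[k])
    }
  }
  if (config$n_background > 0) {
    conc[bg_ids, ] <- bg_mean * 2^bg_eps
  }
  # marker: strictly monotone (affine in log2) in the latent progression
  conc[config$marker_name, ] <- 2^(log2(20) + t_lat * (log2(2000) - log2(20)))

  # forward isotherm, then truncated multiplicative log-normal noise
  vals <- conc
  for (g in gene_ids) {
    vals[g, ] <- concentration_to_intensity(conc[g, ], .param_row(params, g))
  }
  if (config$noise_sd > 0) {
    eps <- matrix(
      stats::rnorm(length(vals), 0, config$noise_sd),
      nrow(vals), ncol(vals)
    )
    vals <- vals * 2^eps
    vals <- pmin(vals, params$saturation[match(rownames(vals), params$gene_id)] * (1 - 1e-6))
  }

  truth <- structure(
    list(
      true_edges = if (n_tg > 0) {
        data.frame(
          regulator = tf_ids[(seq_len(n_tg) - 1) %/% config$n_targets_per_tf + 1L],
          target = tg_ids, stringsAsFactors = FALSE
        )
      } else {
        data.frame(regulator = character(0), target = character(0))
      },
      progression_order = sample_ids[order(t_lat)],
      de_genes = c(tf_ids, tg_ids),
      per_gene_concentration = conc
    ),
    class = "ground_truth"
  )
  list(
    matrix = expression_matrix(vals, phenotype = phenotype),
    truth = truth,
    params = params
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "ground_truth:", nrow(x$true_edges), "planted edges,",
    length(x$de_genes), "DE genes,",
    length(x$progression_order), "samples\n"
  )
  invisible(x)
}

#' Write or read a simulation ground truth as JSON
#'
#' Serialization is lossless: edge sets, the progression order, the DE gene
#' list and the latent concentration matrix round-trip exactly.
#'
#' @param truth a `ground_truth` from [simulate_expression()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    true_edges = truth$true_edges,
    progression_order = truth$progression_order,
    de_genes = truth$de_genes,
    concentration = list(
      gene_ids = rownames(truth$per_gene_concentration),
      sample_ids = colnames(truth$per_gene_concentration),
      values = as.vector(truth$per_gene_concentration)
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns the `ground_truth` object.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conc <- matrix(
    as.numeric(obj$concentration$values),
    nrow = length(obj$concentration$gene_ids),
    dimnames = list(obj$concentration$gene_ids, obj$concentration$sample_ids)
  )
  edges <- obj$true_edges
  if (length(edges) == 0 || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(regulator = character(0), target = character(0))
  } else {
    edges <- data.frame(
      regulator = as.character(edges$regulator),
      target = as.character(edges$target), stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      true_edges = edges,
      progression_order = as.character(obj$progression_order),
      de_genes = as.character(obj$de_genes),
      per_gene_concentration = conc
    ),
    class = "ground_truth"
  )
}

#' Annotation table matching a synthetic cohort
#'
#' Builds the gene-annotation table (TF flag, cancer-association score,
#' metabolic-pathway membership, thermodynamic-characterization flag) for
#' the genes of a synthetic cohort such that exactly the TF genes satisfy
#' all four master-regulator constraints while decoy genes each fail at
#' least one: some targets carry cancer/metabolic flags without TF status,
#' and a deterministic subset of background genes carries all four flags
#' but is not differentially expressed.
#'
#' @param config the [synthetic_config()] used for the simulation.
#' @return An annotation data frame (see [annotation_table()]).
#' @export
make_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sim_ids <- local({
    n_tf <- config$n_tf
    n_known <- min(n_tf, nrow(config$tf_params))
    tf <- config$tf_params$gene_id[seq_len(n_known)]
    if (n_tf > n_known) tf <- c(tf, sprintf("TF%02d", seq.int(n_known + 1L, n_tf)))
    tg <- if (config$n_targets_per_tf > 0 && n_tf > 0) {
      as.vector(t(outer(tf, seq_len(config$n_targets_per_tf),
        function(g, j) sprintf("%s.t%02d", g, j)
      )))
    } else {
      character(0)
    }
    bg <- if (config$n_background > 0) sprintf("bg%04d", seq_len(config$n_background)) else character(0)
    list(tf = tf, tg = tg, bg = bg)
  })
  n_tg <- length(sim_ids$tg)
  n_bg <- length(sim_ids$bg)
  ann <- rbind(
    data.frame(
      gene_id = sim_ids$tf, is_tf = TRUE, cancer_score = 2L,
      is_metabolic = TRUE, has_thermo_params = TRUE, stringsAsFactors = FALSE
    ),
    if (n_tg > 0) {
      data.frame(
        gene_id = sim_ids$tg, is_tf = FALSE,
        cancer_score = rep_len(c(2L, 1L, 0L), n_tg),
        is_metabolic = rep_len(c(TRUE, FALSE), n_tg),
        has_thermo_params = FALSE, stringsAsFactors = FALSE
      )
    },
    if (n_bg > 0) {
      data.frame(
        gene_id = sim_ids$bg,
        is_tf = seq_len(n_bg) %% 7 == 0,
        cancer_score = rep_len(c(0L, 0L, 1L, 0L, 2L), n_bg),
        is_metabolic = seq_len(n_bg) %% 3 == 0,
        # every 21st background gene passes all four static constraints,
        # exercising the DE filter of the core-set intersection
        has_thermo_params = seq_len(n_bg) %% 21 == 0,
        stringsAsFactors = FALSE
      )
    },
    data.frame(
      gene_id = config$marker_name, is_tf = FALSE, cancer_score = 2L,
      is_metabolic = FALSE, has_thermo_params = TRUE, stringsAsFactors = FALSE
    )
  )
  annotation_table(ann)
}
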