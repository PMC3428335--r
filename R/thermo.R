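# Two-state competitive-hybridization model:
#   I(c) = s c / (c + K),  K = delta_g_hyb / (R T)  [pM reference scale]
#   mu(I) = delta_g_hyb (1 - I/s)   -- zero exactly at the saturation constant
#   A_i   = sum_j Lambda_ij mu_j(I_j) dc_j/dI_j

# half-saturation concentration (pM) implied by a parameter row
.half_sat <- function(params) {
  params$delta_g_hyb / (params$gas_constant * params$temperature)
}

.check_single_params <- function(params) {
  if (!inherits(params, "hyb_params") || nrow(params) != 1L) {
    stop("'params' must be a single-row hyb_params object")
  }
  params
}

#' Convert probe intensity to transcript concentration
#'
#' Inverts the two-state competitive-hybridization isotherm: for intensity
#' `I` strictly inside `(0, saturation)`, the concentration is
#' `K * I / (saturation - I)` with `K = delta_g_hyb / (R T)` picomolar.
#' Strictly increasing and continuous in intensity, diverging at the
#' saturation constant.
#'
#' @param intensity numeric vector of intensities, `0 < I < saturation`.
#' @param params single-row [hyb_params()] object.
#' @return Concentrations in picomolar, same length as `intensity`.
#' @examples
#' p <- core_params()
#' intensity_to_concentration(1000, p[1, ])
#' @export
intensity_to_concentration <- function(intensity, params) {
  params <- .check_single_params(params)
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (any(intensity <= 0)) stop("intensity must be > 0")
  if (any(intensity >= params$saturation)) {
    stop(
      "intensity at or above the saturation constant (",
      params$saturation, ") for gene ", params$gene_id
    )
  }
  .half_sat(params) * intensity / (params$saturation - intensity)
}

#' Convert transcript concentration to probe intensity
#'
#' Forward two-state competitive-hybridization isotherm
#' `I = saturation * c / (c + K)`: strictly increasing in concentration,
#' zero at zero (background-corrected convention) and bounded above by the
#' saturation constant.
#'
#' @param concentration non-negative numeric vector, picomolar.
#' @inheritParams intensity_to_concentration
#' @return Intensities in `[0, saturation)`, same length as `concentration`.
#' @examples
#' p <- core_params()
#' concentration_to_intensity(300, p[1, ])
#' @export
concentration_to_intensity <- function(concentration, params) {
  params <- .check_single_params(params)
  if (any(!is.finite(concentration))) stop("concentration must be finite")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  params$saturation * concentration / (concentration + .half_sat(params))
}

#' Chemical potential of transcription
#'
#' `mu(I) = delta_g_hyb * (1 - I / saturation)` in kcal/mol: the
#' activation-energy barrier for synthesizing the transcript. Positive
#' below the saturation constant, zero exactly at it, negative above;
#' monotone decreasing in intensity, so it changes sign exactly once.
#'
#' @param intensity positive numeric vector of intensities.
#' @inheritParams intensity_to_concentration
#' @return Chemical potentials in kcal/mol.
#' @examples
#' p <- core_params()
#' chemical_potential(p$saturation[1], p[1, ]) # 0 at saturation
#' @export
chemical_potential <- function(intensity, params) {
  params <- .check_single_params(params)
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (any(intensity <= 0)) stop("intensity must be > 0")
  params$delta_g_hyb * (1 - intensity / params$saturation)
}

# derivative dc/dI of the isotherm inverse, used by the affinity
.dconc_dintensity <- function(intensity, params) {
  k <- .half_sat(params)
  k * params$saturation / (params$saturation - intensity)^2
}

#' Transcriptional affinity of a gene system
#'
#' The thermodynamic conjugate variable to probe intensity. For gene `i`,
#' `A_i = sum_j Lambda_ij * mu_j(I_j) * (dc_j/dI_j)(I_j)`, where `Lambda`
#' is the matrix of cross-regulation coupling coefficients. With the
#' default identity coupling each gene's affinity depends only on its own
#' intensity and parameters (decoupling), and the product of an affinity
#' with an intensity change carries energy units (kcal pM / mol per
#' intensity).
#'
#' @param intensities named numeric vector of intensities (names are gene
#'   ids), each strictly inside `(0, saturation)` of its gene.
#' @param params_set [hyb_params()] covering every gene in `intensities`.
#' @param coupling square numeric matrix of coupling coefficients aligned
#'   with `intensities` (dimnames optional but checked when present), or
#'   `NULL` for identity.
#' @return Named numeric vector of affinities.
#' @examples
#' p <- core_params()
#' transcriptional_affinity(c(MNDA = 1000, SMAD3 = 2000), p)
#' @export
transcriptional_affinity <- function(intensities, params_set, coupling = NULL) {
  genes <- names(intensities)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("'intensities' must be a named vector with unique gene names")
  }
  n <- length(intensities)
  if (is.null(coupling)) {
    coupling <- diag(n)
  }
  if (!is.matrix(coupling) || nrow(coupling) != n || ncol(coupling) != n) {
    stop("'coupling' must be a ", n, " x ", n, " matrix aligned with the genes")
  }
  if (!is.null(rownames(coupling)) && !identical(rownames(coupling), genes)) {
    stop("coupling dimnames do not match the gene vector")
  }
  if (any(!is.finite(coupling))) stop("coupling entries must be finite")
  base <- vapply(genes, function(g) {
    p <- .param_row(params_set, g)
    i <- intensities[[g]]
    if (!is.finite(i) || i <= 0 || i >= p$saturation) {
      stop("intensity for gene '", g, "' outside (0, saturation)")
    }
    chemical_potential(i, p) * .dconc_dintensity(i, p)
  }, numeric(1))
  out <- drop(coupling %*% base)
  names(out) <- genes
  out
}

#' Thermodynamic profile of an expression matrix
#'
#' Applies the isotherm inversion, transcriptional affinity and chemical
#' potential elementwise to every gene with known hybridization parameters
#' and summarizes each quantity per gene (mean and variance across
#' samples). Genes without parameters are excluded and reported in the
#' `excluded` attribute. Intensities at or above a gene's saturation
#' constant (possible in noisy data) are clamped to
#' `saturation * (1 - 1e-6)` with a warning.
#'
#' @param em an [expression_matrix()].
#' @param params_set [hyb_params()] for (a subset of) the genes.
#' @param coupling optional coupling matrix over the profiled genes passed
#'   to [transcriptional_affinity()]; identity when `NULL`.
#' @return An object of class `thermo_profile`: a list with gene x sample
#'   matrices `concentration` (pM), `affinity`, `chemical_potential`
#'   (kcal/mol), the clamped `intensity` matrix, and per-gene summary data
#'   frame `summary`.
#' @examples
#' sim <- simulate_expression(synthetic_config(n_background = 0, n_targets_per_tf = 0))
#' thermo_profile(sim$matrix, core_params())
#' @export
thermo_profile <- function(em, params_set, coupling = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  genes <- intersect(em$gene_ids, params_set$gene_id)
  excluded <- setdiff(em$gene_ids, genes)
  if (length(genes) == 0L) {
    stop("no overlap between matrix genes and hybridization parameters")
  }
  vals <- em$values[genes, , drop = FALSE]
  ns <- ncol(vals)
  conc <- aff <- mu <- matrix(NA_real_, length(genes), ns,
    dimnames = dimnames(vals)
  )
  clamped <- 0L
  for (g in genes) {
    p <- .param_row(params_set, g)
    x <- vals[g, ]
    hi <- x >= p$saturation
    if (any(hi)) {
      clamped <- clamped + sum(hi)
      x[hi] <- p$saturation * (1 - 1e-6)
      vals[g, ] <- x
    }
    conc[g, ] <- intensity_to_concentration(x, p)
    mu[g, ] <- chemical_potential(x, p)
  }
  if (clamped > 0L) {
    warning(clamped, " intensities at or above saturation clamped to saturation*(1-1e-6)")
  }
  if (is.null(coupling)) {
    # identity coupling: affinity decouples into per-gene elementwise maps
    for (g in genes) {
      p <- .param_row(params_set, g)
      aff[g, ] <- mu[g, ] * .dconc_dintensity(vals[g, ], p)
    }
  } else {
    for (j in seq_len(ns)) {
      aff[, j] <- transcriptional_affinity(vals[, j], params_set, coupling)
    }
  }
  summ <- data.frame(
    gene_id = genes,
    mean_concentration = rowMeans(conc),
    var_concentration = apply(conc, 1, stats::var),
    mean_affinity = rowMeans(aff),
    var_affinity = apply(aff, 1, stats::var),
    mean_mu = rowMeans(mu),
    var_mu = apply(mu, 1, stats::var),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      concentration = conc, affinity = aff, chemical_potential = mu,
      intensity = vals, summary = summ, sample_ids = colnames(vals)
    ),
    excluded = excluded,
    class = "thermo_profile"
  )
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(
    "Thermodynamic transcription profile:", nrow(x$concentration), "genes x",
    ncol(x$concentration), "samples\n"
  )
  excl <- attr(x, "excluded")
  if (length(excl)) {
    cat("  excluded (no parameters):", length(excl), "genes\n")
  }
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.thermo_profile <- function(object, ...) object$summary

#' @export
as.data.frame.thermo_profile <- function(x, ...) {
  genes <- rownames(x$concentration)
  samples <- colnames(x$concentration)
  data.frame(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = length(genes)),
    intensity = as.vector(x$intensity),
    concentration = as.vector(x$concentration),
    affinity = as.vector(x$affinity),
    mu = as.vector(x$chemical_potential),
    stringsAsFactors = FALSE
  )
}

#' Plot per-gene thermodynamic trajectories along the sample ordering
#'
#' @param x a `thermo_profile`.
#' @param what one of `"concentration"`, `"affinity"`,
#'   `"chemical_potential"`, `"intensity"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.thermo_profile <- function(x, what = c(
                                  "concentration", "affinity",
                                  "chemical_potential", "intensity"
                                ), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::matplot(t(m),
    type = "l", lty = 1, xlab = "sample (progression order)",
    ylab = what, ...
  )
  graphics::legend("topright", legend = rownames(m), lty = 1, col = seq_len(nrow(m)), cex = 0.7)
  invisible(x)
}

#' Write a thermodynamic profile as a long tab-delimited table
#'
#' Columns: gene, sample, intensity, concentration, affinity, mu.
#'
#' @param profile a `thermo_profile`.
#' @param path output file.
#' @export
write_thermo_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Rank genes by mean chemical potential of transcription
#'
#' Genes sorted ascending by their mean chemical potential (lowest
#' activation-energy barrier first, the regime expected of master-regulator
#' transcription factors); ties broken lexicographically by gene id.
#'
#' @param profile a [thermo_profile()].
#' @return Data frame with columns `gene_id` and `mean_mu`, ascending.
#' @export
rank_by_chemical_potential <- function(profile) {
  stopifnot(inherits(profile, "thermo_profile"))
  s <- profile$summary
  if (nrow(s) == 0L) stop("empty profile")
  out <- s[order(s$mean_mu, s$gene_id), c("gene_id", "mean_mu")]
  rownames(out) <- NULL
  out
}
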