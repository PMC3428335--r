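#' Per-gene hybridization thermodynamic parameters
#'
#' Container for the constants required by the thermodynamic model of
#' transcription: the free energy of hybridization of a probe
#' (`delta_g_hyb`, kcal/mol), the saturation constant of the hybridization
#' isotherm (`saturation`, intensity units, the intensity at which the
#' chemical potential of transcription crosses zero), and the
#' intensity-scale constant (`intensity_scale`, mol/kcal times intensity)
#' that relates the two: `saturation = intensity_scale * delta_g_hyb`.
#'
#' @param gene_id character vector of gene/probe identifiers (unique).
#' @param delta_g_hyb positive free energy of hybridization, kcal/mol.
#' @param saturation positive saturation constant, intensity units.
#' @param intensity_scale intensity-scale constant; defaults to
#'   `saturation / delta_g_hyb` so the triplet is self-consistent.
#' @param temperature absolute temperature in kelvin; default physiological
#'   temperature 310.15 K.
#' @param gas_constant gas constant in kcal/(mol K).
#'
#' @return A data frame of class `hyb_params` with one row per gene.
#' @examples
#' hyb_params("MNDA", delta_g_hyb = 433.97, saturation = 3105)
#' @export
hyb_params <- function(gene_id, delta_g_hyb, saturation,
                       intensity_scale = saturation / delta_g_hyb,
                       temperature = 310.15,
                       gas_constant = 0.0019872) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in hybridization parameters")
  }
  n <- length(gene_id)
  p <- data.frame(
    gene_id = gene_id,
    delta_g_hyb = rep_len(as.numeric(delta_g_hyb), n),
    saturation = rep_len(as.numeric(saturation), n),
    intensity_scale = rep_len(as.numeric(intensity_scale), n),
    temperature = rep_len(as.numeric(temperature), n),
    gas_constant = rep_len(as.numeric(gas_constant), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(p$delta_g_hyb)) || any(p$delta_g_hyb <= 0)) {
    stop("delta_g_hyb must be finite and > 0")
  }
  if (any(!is.finite(p$saturation)) || any(p$saturation <= 0)) {
    stop("saturation must be finite and > 0")
  }
  if (any(p$temperature <= 0)) stop("temperature must be > 0")
  if (any(p$gas_constant <= 0)) stop("gas_constant must be > 0")
  class(p) <- c("hyb_params", "data.frame")
  p
}

#' Thermodynamic parameters of the four master-regulator probes
#'
#' The calibrated hybridization parameters for the MNDA, POU2AF1, MEF2C and
#' SMAD3 probe sets on the HGU133A platform (free energy of hybridization in
#' kcal/mol and saturation constant in intensity units), at physiological
#' temperature.
#'
#' @return A `hyb_params` data frame with four rows.
#' @examples
#' core_params()
#' @export
core_params <- function() {
  hyb_params(
    gene_id = c("MNDA", "POU2AF1", "MEF2C", "SMAD3"),
    delta_g_hyb = c(433.97, 473.5, 472.81, 465.08),
    saturation = c(3105, 4684, 5110, 4497)
  )
}

#' Read or write hybridization parameters as a tab-delimited table
#'
#' The table has columns `gene_id`, `delta_g_hyb`, `saturation`,
#' `intensity_scale` (and optionally `temperature`, `gas_constant`).
#'
#' @param path file path.
#' @return `read_hyb_params` returns a `hyb_params` data frame.
#' @export
read_hyb_params <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "delta_g_hyb", "saturation")
  if (!all(need %in% names(tab))) {
    stop("parameter table must contain columns: ", paste(need, collapse = ", "))
  }
  args <- list(
    gene_id = tab$gene_id,
    delta_g_hyb = tab$delta_g_hyb,
    saturation = tab$saturation
  )
  for (opt in c("intensity_scale", "temperature", "gas_constant")) {
    if (opt %in% names(tab)) args[[opt]] <- tab[[opt]]
  }
  do.call(hyb_params, args)
}

#' @param params a `hyb_params` data frame.
#' @rdname read_hyb_params
#' @export
write_hyb_params <- function(params, path) {
  utils::write.table(as.data.frame(params), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# single-gene row lookup, always returns a one-row hyb_params
.param_row <- function(params_set, gene) {
  i <- match(gene, params_set$gene_id)
  if (is.na(i)) stop("no hybridization parameters for gene '", gene, "'")
  params_set[i, , drop = FALSE]
}
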