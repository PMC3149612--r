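#' PSM score filtering thresholds
#'
#' Per-charge XCorr minima plus DeltaCn, peptide-count, unique-peptide and
#' spectra floors used to filter peptide-spectrum matches and to assemble
#' protein identifications. Defaults are the conservative values standard
#' for LTQ/Orbitrap SEQUEST searches: XCorr >= 1.8/2.5/3.5 for charge
#' 1+/2+/3+, DeltaCn >= 0.08, at least two distinct peptides per protein of
#' which at least one unique, and a minimum of two spectra.
#'
#' @slot xcorr_by_charge named numeric, minimum XCorr per precursor charge;
#'   charges above the largest named charge reuse its threshold.
#' @slot min_delta_cn numeric(1), minimum DeltaCn.
#' @slot min_peptides_per_protein integer(1), distinct-peptide floor.
#' @slot min_unique_peptides integer(1), unique-peptide floor.
#' @slot min_spectra integer(1), per-protein total-spectra floor.
#'
#' @export
setClass("FilterThresholds",
  representation(
    xcorr_by_charge = "numeric",
    min_delta_cn = "numeric",
    min_peptides_per_protein = "integer",
    min_unique_peptides = "integer",
    min_spectra = "integer"
  ),
  prototype(
    xcorr_by_charge = c(`1` = 1.8, `2` = 2.5, `3` = 3.5),
    min_delta_cn = 0.08,
    min_peptides_per_protein = 2L,
    min_unique_peptides = 1L,
    min_spectra = 2L
  )
)

setValidity("FilterThresholds", function(object) {
  msgs <- character()
  x <- object@xcorr_by_charge
  if (length(x) == 0L || is.null(names(x)) || anyNA(suppressWarnings(as.integer(names(x)))))
    msgs <- c(msgs, "xcorr_by_charge must be a named numeric (names = charges)")
  if (any(x < 0)) msgs <- c(msgs, "XCorr thresholds must be non-negative")
  if (length(object@min_delta_cn) != 1L || object@min_delta_cn < 0 || object@min_delta_cn > 1)
    msgs <- c(msgs, "min_delta_cn must be a single value in [0, 1]")
  if (object@min_peptides_per_protein < 1L)
    msgs <- c(msgs, "min_peptides_per_protein must be >= 1")
  if (object@min_unique_peptides < 0L)
    msgs <- c(msgs, "min_unique_peptides must be >= 0")
  if (object@min_spectra < 0L)
    msgs <- c(msgs, "min_spectra must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct filtering thresholds
#'
#' @param xcorr_by_charge named numeric of per-charge XCorr minima.
#' @param min_delta_cn minimum DeltaCn in \[0, 1\].
#' @param min_peptides_per_protein distinct peptides required per protein.
#' @param min_unique_peptides unique peptides required per protein.
#' @param min_spectra minimum total spectra per protein.
#' @return A \linkS4class{FilterThresholds} object.
#' @examples
#' filterThresholds()
#' filterThresholds(min_spectra = 1)
#' @export
filterThresholds <- function(xcorr_by_charge = c(`1` = 1.8, `2` = 2.5, `3` = 3.5),
                             min_delta_cn = 0.08,
                             min_peptides_per_protein = 2,
                             min_unique_peptides = 1,
                             min_spectra = 2) {
  new("FilterThresholds",
    xcorr_by_charge = xcorr_by_charge,
    min_delta_cn = min_delta_cn,
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    min_unique_peptides = as.integer(min_unique_peptides),
    min_spectra = as.integer(min_spectra)
  )
}

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds\n")
  cat("  XCorr by charge:",
    paste(sprintf("%s+ >= %.2f", names(object@xcorr_by_charge), object@xcorr_by_charge),
      collapse = ", "), "\n")
  cat(sprintf("  DeltaCn >= %.2f\n", object@min_delta_cn))
  cat(sprintf("  peptides >= %d (unique >= %d), spectra >= %d\n",
    object@min_peptides_per_protein, object@min_unique_peptides, object@min_spectra))
})

#' Container for layered spectral-count matrices
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding proteins x
#' runs matrices for the layers of the spectral-count normalization chain:
#' \describe{
#'   \item{SpC}{raw per-protein spectral counts; spectra of shared peptides
#'     are counted in full for every sharing protein (the classic,
#'     homology-inflated convention).}
#'   \item{aSpC}{balanced counts after shared-peptide spectra are
#'     apportioned among sharers proportionally to unique-peptide evidence;
#'     per run, aSpC sums to the number of assigned spectra.}
#'   \item{NSAF}{length-normalized relative abundance; columns sum to 1.}
#'   \item{nSpC}{NSAF rescaled by a constant pseudo-count total.}
#'   \item{RSpC}{nSpC after cross-condition re-normalization of one
#'     organism's proteins.}
#' }
#' Row metadata carries the protein annotations (organism, length, arCOG,
#' TMD/signal-peptide flags, operon); column metadata carries run id,
#' condition and replicate index. `metadata()` stores `scale_constant` and
#' the per-run assigned-spectra totals (`run_totals`).
#'
#' @export
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
  msgs <- character()
  need <- c("condition", "replicate")
  if (!all(need %in% colnames(colData(object))))
    msgs <- c(msgs, "colData must contain 'condition' and 'replicate'")
  if (!"length_aa" %in% colnames(rowData(object)))
    msgs <- c(msgs, "rowData must contain 'length_aa'")
  else if (any(rowData(object)$length_aa < 1))
    msgs <- c(msgs, "protein lengths must be >= 1")
  for (l in assayNames(object)) {
    a <- assay(object, l)
    if (any(a < 0, na.rm = TRUE)) msgs <- c(msgs, sprintf("assay '%s' has negative values", l))
  }
  sc <- metadata(object)$scale_constant
  if (!is.null(sc) && (!is.numeric(sc) || sc <= 0))
    msgs <- c(msgs, "scale_constant must be a positive number")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SpectralCountExperiment", function(object) {
  cat("SpectralCountExperiment:", nrow(object), "proteins x", ncol(object), "runs\n")
  cat("  layers:", paste(assayNames(object), collapse = ", "), "\n")
  cond <- table(colData(object)$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(cond), cond), collapse = ", "), "\n")
  org <- table(rowData(object)$organism)
  cat("  organisms:", paste(sprintf("%s (%d)", names(org), org), collapse = ", "), "\n")
  sc <- metadata(object)$scale_constant
  if (!is.null(sc)) cat("  scale constant:", sc, "\n")
})

#' @describeIn SpectralCountExperiment scale constant used for the nSpC layer
#' @param x a `SpectralCountExperiment`
#' @export
scaleConstant <- function(x) metadata(x)$scale_constant

#' @describeIn SpectralCountExperiment per-protein organism labels
#' @export
proteinOrganism <- function(x) setNames(as.character(rowData(x)$organism), rownames(x))

#' @describeIn SpectralCountExperiment per-protein lengths in amino acids
#' @export
proteinLengths <- function(x) setNames(as.numeric(rowData(x)$length_aa), rownames(x))

#' @describeIn SpectralCountExperiment run ids belonging to a condition
#' @param condition condition label to look up
#' @export
conditionRuns <- function(x, condition) {
  hit <- colData(x)$condition == condition
  if (!any(hit)) stop("unknown condition: ", condition, call. = FALSE)
  colnames(x)[hit]
}

#' Configuration of the synthetic two-organism benchmark
#'
#' Defines the study conditions emulated by the generator: proteome sizes of
#' a host (1444 proteins) and an obligate symbiont (556 proteins), about
#' 46,541 MS/MS spectra per run, three technical replicates for each of the
#' pure host culture, the co-culture and the purified symbiont fraction, a
#' transmembrane-protein subpopulation with roughly three-fold depressed
#' spectral yield, cross-species homolog pairs sharing tryptic peptides,
#' condition fold-effects on a subset of host proteins, a 10% host
#' carry-over contamination in the purified symbiont sample, and an optional
#' set of genuinely transferred host proteins enriched in that sample.
#'
#' @slot n_host_proteins,n_symbiont_proteins proteome sizes.
#' @slot length_meanlog,length_sdlog log-normal protein length (aa).
#' @slot abundance_meanlog,abundance_sdlog log-normal molar abundance.
#' @slot tmd_fraction fraction of proteins with transmembrane domains.
#' @slot tmd_depression factor by which TMD proteins under-produce spectra.
#' @slot n_homolog_pairs cross-species pairs sharing tryptic peptides.
#' @slot spectra_per_run assigned MS/MS spectra per run.
#' @slot replicates_per_condition technical replicates per sample.
#' @slot coculture_symbiont_fraction fraction of co-culture spectra from the
#'   symbiont (0.315 emulates the observed 68.5/31.5 split).
#' @slot effect_fraction fraction of host proteins given a co-culture fold
#'   effect when no explicit `effect_table` is supplied.
#' @slot effect_fold_range fold range (log-uniform, random direction) for
#'   auto-generated effects.
#' @slot effect_table explicit data.frame(accession, condition, fold);
#'   overrides auto-generation when non-empty.
#' @slot contamination_fraction fraction of purified-sample spectra drawn
#'   from host proteins (carry-over).
#' @slot n_transfer,transfer_fold number of designated transferred host
#'   proteins and their relative enrichment in the purified sample.
#' @slot transfer_set explicit data.frame(accession, fold); overrides
#'   auto-selection when non-empty.
#' @slot decoy append reversed decoy entries to the database.
#' @slot decoy_psm_rate rate of filter-passing decoy PSMs relative to the
#'   per-run spectra total.
#' @slot peptide_min_len,peptide_max_len detectability window (aa) for
#'   tryptic peptides.
#' @slot seed integer seed; all generator randomness derives from it.
#' @export
setClass("SyntheticConfig",
  representation(
    n_host_proteins = "integer",
    n_symbiont_proteins = "integer",
    length_meanlog = "numeric",
    length_sdlog = "numeric",
    abundance_meanlog = "numeric",
    abundance_sdlog = "numeric",
    tmd_fraction = "numeric",
    tmd_depression = "numeric",
    n_homolog_pairs = "integer",
    spectra_per_run = "integer",
    replicates_per_condition = "integer",
    coculture_symbiont_fraction = "numeric",
    effect_fraction = "numeric",
    effect_fold_range = "numeric",
    effect_table = "data.frame",
    contamination_fraction = "numeric",
    n_transfer = "integer",
    transfer_fold = "numeric",
    transfer_set = "data.frame",
    decoy = "logical",
    decoy_psm_rate = "numeric",
    peptide_min_len = "integer",
    peptide_max_len = "integer",
    seed = "integer"
  ),
  prototype(
    n_host_proteins = 1444L,
    n_symbiont_proteins = 556L,
    length_meanlog = log(280),
    length_sdlog = 0.45,
    abundance_meanlog = 0,
    abundance_sdlog = 1.5,
    tmd_fraction = 0.25,
    tmd_depression = 3.0,
    n_homolog_pairs = 20L,
    spectra_per_run = 46541L,
    replicates_per_condition = 3L,
    coculture_symbiont_fraction = 0.315,
    effect_fraction = 0.10,
    effect_fold_range = c(2, 5),
    effect_table = data.frame(),
    contamination_fraction = 0.10,
    n_transfer = 10L,
    transfer_fold = 5,
    transfer_set = data.frame(),
    decoy = TRUE,
    decoy_psm_rate = 0.015,
    peptide_min_len = 6L,
    peptide_max_len = 50L,
    seed = 1L
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  frac <- c(
    tmd_fraction = object@tmd_fraction,
    coculture_symbiont_fraction = object@coculture_symbiont_fraction,
    effect_fraction = object@effect_fraction,
    contamination_fraction = object@contamination_fraction
  )
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad)) msgs <- c(msgs, paste("fractions outside [0, 1]:", paste(bad, collapse = ", ")))
  if (object@tmd_depression <= 0) msgs <- c(msgs, "tmd_depression must be > 0")
  if (object@transfer_fold <= 0) msgs <- c(msgs, "transfer_fold must be > 0")
  if (any(object@effect_fold_range <= 0)) msgs <- c(msgs, "effect folds must be > 0")
  if (nrow(object@effect_table) && any(object@effect_table$fold <= 0))
    msgs <- c(msgs, "effect_table folds must be > 0")
  if (object@spectra_per_run < 1L) msgs <- c(msgs, "spectra_per_run must be >= 1")
  if (object@replicates_per_condition < 1L) msgs <- c(msgs, "replicates_per_condition must be >= 1")
  if (object@n_homolog_pairs > min(object@n_host_proteins, object@n_symbiont_proteins))
    msgs <- c(msgs, "n_homolog_pairs exceeds proteome size")
  if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic-benchmark configuration
#'
#' All arguments default to the emulated study conditions; see
#' \linkS4class{SyntheticConfig} for their meaning.
#'
#' @param ... slot values overriding the defaults, e.g.
#'   `syntheticConfig(n_host_proteins = 100, seed = 7)`.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(n_host_proteins = 50, n_symbiont_proteins = 20,
#'                        spectra_per_run = 2000, seed = 42)
#' @export
syntheticConfig <- function(...) {
  args <- list(...)
  for (nm in c("n_host_proteins", "n_symbiont_proteins", "n_homolog_pairs",
               "spectra_per_run", "replicates_per_condition", "n_transfer",
               "peptide_min_len", "peptide_max_len", "seed")) {
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  }
  do.call(new, c(list(Class = "SyntheticConfig"), args))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  proteomes: host %d, symbiont %d (homolog pairs %d, decoy %s)\n",
    object@n_host_proteins, object@n_symbiont_proteins,
    object@n_homolog_pairs, object@decoy))
  cat(sprintf("  spectra/run %d x %d replicates/condition\n",
    object@spectra_per_run, object@replicates_per_condition))
  cat(sprintf("  TMD: fraction %.2f, depression %.1fx; contamination %.2f\n",
    object@tmd_fraction, object@tmd_depression, object@contamination_fraction))
  cat(sprintf("  transfer: %d proteins at %.1fx; seed %d\n",
    object@n_transfer, object@transfer_fold, object@seed))
})
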