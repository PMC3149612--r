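#' Balance shared-peptide spectra for one run
#'
#' Unique peptides keep their full spectral count. Each shared (non-unique)
#' peptide's spectra are apportioned among the proteins that share it,
#' proportionally to those proteins' unique-peptide spectral totals in the
#' same run; when none of the sharers has unique spectra in the run, the
#' count is split equally (a deterministic fallback that conserves
#' spectra). The balanced per-protein totals are the adjusted spectral
#' counts (aSpC); summed over proteins they equal the number of spectra
#' assigned in the run.
#'
#' @param evidence protein evidence from [assembleProteins()].
#' @param run run identifier.
#' @return named numeric vector of aSpC over all retained proteins
#'   (zero for proteins without spectra in the run).
#' @export
balanceSpectra <- function(evidence, run) {
  proteins <- attr(evidence, "protein_table")$accession
  if (is.null(proteins)) .stop("evidence lacks a protein_table attribute")
  aspc <- setNames(numeric(length(proteins)), proteins)
  ev <- evidence[evidence$run_id == run, , drop = FALSE]
  if (nrow(ev) == 0L) return(aspc)
  # unique contributions
  uev <- ev[ev$is_unique, , drop = FALSE]
  if (nrow(uev)) {
    u <- tapply(uev$spc, uev$accession, sum)
    aspc[names(u)] <- u
  }
  # shared peptides: apportion by unique totals in this run
  sev <- ev[!ev$is_unique, , drop = FALSE]
  if (nrow(sev)) {
    dt <- data.table(accession = sev$accession, peptide = sev$peptide,
                     spc = sev$spc)
    dt[, u := aspc[accession]]
    dt[, tot := sum(u), by = "peptide"]
    dt[, n := .N, by = "peptide"]
    dt[, share := ifelse(tot > 0, spc * u / tot, spc / n)]
    sh <- dt[, list(share = sum(share)), by = "accession"]
    aspc[sh$accession] <- aspc[sh$accession] + sh$share
  }
  aspc
}

#' Build a SpectralCountExperiment from protein evidence
#'
#' Assembles the raw SpC and balanced aSpC layers over all runs and
#' attaches protein annotations and run metadata. The SpC layer counts
#' every spectrum of a shared peptide in full for each sharing protein
#' (the homology-inflated convention that the aSpC balancing corrects);
#' the aSpC layer conserves the per-run spectrum total.
#'
#' @param evidence protein evidence from [assembleProteins()].
#' @param run_info data.frame with columns `run_id`, `condition`,
#'   `replicate`, one row per run; must cover every run in the evidence.
#' @param scale_constant positive scale for the later nSpC layer, or `NULL`
#'   to use the mean of the per-run assigned-spectra totals.
#' @return a \linkS4class{SpectralCountExperiment} with layers `SpC`, `aSpC`.
#' @export
SpectralCountExperiment <- function(evidence, run_info, scale_constant = 46541) {
  ptab <- attr(evidence, "protein_table")
  db <- attr(evidence, "db")
  run_totals <- attr(evidence, "run_totals")
  if (is.null(ptab) || is.null(db)) .stop("evidence must come from assembleProteins()")
  need <- c("run_id", "condition", "replicate")
  if (!all(need %in% names(run_info)))
    .stop("run_info needs columns: ", paste(need, collapse = ", "))
  missing_runs <- setdiff(unique(evidence$run_id), run_info$run_id)
  if (length(missing_runs))
    .stop("run(s) absent from run_info: ", paste(missing_runs, collapse = ", "))

  proteins <- ptab$accession
  runs <- as.character(run_info$run_id)
  spc <- matrix(0, length(proteins), length(runs),
                dimnames = list(proteins, runs))
  dt <- data.table(accession = evidence$accession, run_id = evidence$run_id,
                   spc = evidence$spc)
  agg <- dt[, list(spc = sum(spc)), by = c("accession", "run_id")]
  spc[cbind(match(agg$accession, proteins), match(agg$run_id, runs))] <- agg$spc
  aspc <- vapply(runs, function(r) balanceSpectra(evidence, r),
                 numeric(length(proteins)))
  if (length(proteins) == 1L) aspc <- matrix(aspc, nrow = 1L,
    dimnames = list(proteins, runs))
  if (is.null(scale_constant)) scale_constant <- mean(run_totals[runs], na.rm = TRUE)
  if (!is.numeric(scale_constant) || scale_constant <= 0)
    .stop("scale_constant must be positive")

  tot <- setNames(numeric(length(runs)), runs)
  tot[names(run_totals)] <- run_totals
  rd <- DataFrame(db[match(proteins, db$accession),
    c("accession", "organism", "length_aa", "arcog_id", "arcog_class",
      "has_tmd", "has_signal_peptide", "operon_id"), drop = FALSE])
  rownames(rd) <- proteins
  cd <- DataFrame(run_id = runs, condition = as.character(run_info$condition),
                  replicate = as.integer(run_info$replicate), row.names = runs)
  se <- SummarizedExperiment(
    assays = list(SpC = spc, aSpC = aspc),
    rowData = rd, colData = cd,
    metadata = list(scale_constant = scale_constant, run_totals = tot)
  )
  new("SpectralCountExperiment", se)
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Length-corrected relative abundance: for protein i with balanced count
#' aSpC_i and length L_i, `NSAF_i = (aSpC_i / L_i) / sum_j(aSpC_j / L_j)`,
#' computed per run over the proteins detected in that run (aSpC > 0).
#' Each run's NSAF values sum to 1; undetected proteins get NSAF 0.
#'
#' @param x a \linkS4class{SpectralCountExperiment} (adds the `NSAF`
#'   assay), or a numeric aSpC vector.
#' @param lengths named numeric of protein lengths (vector method only).
#' @return the augmented experiment, or an NSAF vector.
#' @examples
#' computeNSAF(c(A = 10, B = 10), lengths = c(A = 100, B = 200))
#' @export
setGeneric("computeNSAF", function(x, lengths) standardGeneric("computeNSAF"))

#' @rdname computeNSAF
#' @export
setMethod("computeNSAF", "numeric", function(x, lengths) {
  if (any(lengths < 1)) .stop("protein lengths must be >= 1")
  if (!is.null(names(x)) && !is.null(names(lengths))) lengths <- lengths[names(x)]
  if (length(lengths) != length(x)) .stop("lengths do not match the aSpC vector")
  if (all(x == 0)) .stop("all-zero spectral count vector: NSAF undefined")
  sl <- x / lengths
  sl / sum(sl)
})

#' @rdname computeNSAF
#' @export
setMethod("computeNSAF", "SpectralCountExperiment", function(x, lengths) {
  aspc <- assay(x, "aSpC")
  len <- proteinLengths(x)
  zero_runs <- colnames(x)[colSums(aspc) == 0]
  if (length(zero_runs))
    .stop("run(s) without spectra, NSAF undefined: ",
          paste(zero_runs, collapse = ", "))
  sl <- aspc / len
  nsaf <- sweep(sl, 2L, colSums(sl), "/")
  assay(x, "NSAF") <- nsaf
  validObject(x)
  x
})

#' Scale NSAF to pseudo-spectral counts (nSpC)
#'
#' Multiplies NSAF by a constant (by default the experiment's
#' `scale_constant`, nominally the average per-run assigned-spectra total)
#' so that relative abundances read as spectral counts. Each run's nSpC
#' values sum to the constant. Downstream fold ratios are invariant to its
#' choice.
#'
#' @param x a \linkS4class{SpectralCountExperiment} with an `NSAF` assay,
#'   or an NSAF numeric vector.
#' @param scale_constant positive scale; for the experiment method,
#'   defaults to `scaleConstant(x)`.
#' @return the augmented experiment, or an nSpC vector.
#' @export
setGeneric("scaleNSpC", function(x, scale_constant) standardGeneric("scaleNSpC"))

#' @rdname scaleNSpC
#' @export
setMethod("scaleNSpC", "numeric", function(x, scale_constant) {
  if (!is.numeric(scale_constant) || length(scale_constant) != 1L ||
      scale_constant <= 0)
    .stop("scale_constant must be a positive number")
  x * scale_constant
})

#' @rdname scaleNSpC
#' @export
setMethod("scaleNSpC", "SpectralCountExperiment", function(x, scale_constant) {
  if (missing(scale_constant)) scale_constant <- scaleConstant(x)
  if (!is.numeric(scale_constant) || scale_constant <= 0)
    .stop("scale_constant must be a positive number")
  if (!"NSAF" %in% assayNames(x)) .stop("compute the NSAF layer first")
  assay(x, "nSpC") <- assay(x, "NSAF") * scale_constant
  metadata(x)$scale_constant <- scale_constant
  validObject(x)
  x
})

#' Cross-condition re-normalization (RSpC)
#'
#' Re-normalizes one organism's nSpC values so that the organism's total in
#' the target condition equals its total in the reference condition,
#' correcting for the dilution of that organism's spectra by the increased
#' proteome complexity of a mixed sample. By default a single global factor
#' (ratio of condition totals summed over replicates) is applied to the
#' organism's proteins in the target-condition runs; `per_replicate = TRUE`
#' instead pairs replicate indices and applies one factor per pair. All
#' other values (reference condition, other organisms, other conditions)
#' pass through unchanged.
#'
#' @param x a \linkS4class{SpectralCountExperiment} with an `nSpC` assay.
#' @param organism organism whose proteins are re-normalized.
#' @param reference_condition condition supplying the target total.
#' @param target_condition condition being rescaled.
#' @param per_replicate pair replicates instead of using condition totals.
#' @return the experiment with an `RSpC` assay added.
#' @export
renormalizeRSpC <- function(x, organism = "host",
                            reference_condition = "pure_host",
                            target_condition = "coculture",
                            per_replicate = FALSE) {
  if (!"nSpC" %in% assayNames(x)) .stop("compute the nSpC layer first")
  org_rows <- proteinOrganism(x) == organism
  if (!any(org_rows)) .stop("no proteins of organism '", organism, "'")
  ref_runs <- conditionRuns(x, reference_condition)
  tgt_runs <- conditionRuns(x, target_condition)
  nspc <- assay(x, "nSpC")
  rspc <- nspc
  if (per_replicate) {
    ref_rep <- setNames(ref_runs, colData(x)[ref_runs, "replicate"])
    tgt_rep <- setNames(tgt_runs, colData(x)[tgt_runs, "replicate"])
    if (!setequal(names(ref_rep), names(tgt_rep)))
      .stop("replicate indices do not pair across conditions")
    for (rep_i in names(tgt_rep)) {
      denom <- sum(nspc[org_rows, tgt_rep[[rep_i]]])
      if (denom == 0) .stop("zero ", organism, " total in ", tgt_rep[[rep_i]])
      rspc[org_rows, tgt_rep[[rep_i]]] <-
        nspc[org_rows, tgt_rep[[rep_i]]] *
        sum(nspc[org_rows, ref_rep[[rep_i]]]) / denom
    }
  } else {
    denom <- sum(nspc[org_rows, tgt_runs])
    if (denom == 0)
      .stop("zero ", organism, " total in condition ", target_condition)
    f <- sum(nspc[org_rows, ref_runs]) / denom
    rspc[org_rows, tgt_runs] <- nspc[org_rows, tgt_runs] * f
  }
  assay(x, "RSpC") <- rspc
  validObject(x)
  x
}

#' Pearson correlation between two replicate runs
#'
#' Computed over the proteins detected (value > 0) in at least one of the
#' two runs; zeros in the other run are retained. `log2_transform` applies
#' `log2(v + 1)` first (the transform used is otherwise the identity).
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param run_a,run_b run identifiers.
#' @param layer assay to correlate (default `"RSpC"`).
#' @param log2_transform correlate on `log2(v + 1)`.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
replicateCorrelation <- function(x, run_a, run_b, layer = "RSpC",
                                 log2_transform = FALSE) {
  if (!layer %in% assayNames(x)) .stop("no layer '", layer, "'")
  m <- assay(x, layer)
  if (!all(c(run_a, run_b) %in% colnames(m))) .stop("unknown run id")
  a <- m[, run_a]; b <- m[, run_b]
  keep <- a > 0 | b > 0
  a <- a[keep]; b <- b[keep]
  if (log2_transform) { a <- log2(a + 1); b <- log2(b + 1) }
  if (sd(a) == 0 || sd(b) == 0)
    .stop("correlation undefined: constant vector in ", run_a, " or ", run_b)
  cor(a, b, method = "pearson")
}

#' Spectral-yield bias of transmembrane proteins
#'
#' Whole-cell shotgun proteomics systematically under-samples membrane
#' proteins. For each run this summarizes the mean balanced count of
#' detected proteins with and without predicted transmembrane domains and
#' their ratio (non-TMD / TMD; about 3 in deep archaeal whole-cell data).
#' Runs without detected TMD (or non-TMD) proteins get an `NA` ratio and
#' are flagged.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param layer assay to summarize (default `"aSpC"`).
#' @return data.frame with one row per run: `run_id`, `condition`,
#'   `n_tmd`, `n_non_tmd`, `mean_tmd`, `mean_non_tmd`, `ratio`.
#' @export
tmdBiasSummary <- function(x, layer = "aSpC") {
  if (!layer %in% assayNames(x)) .stop("no layer '", layer, "'")
  m <- assay(x, layer)
  tmd <- as.logical(rowData(x)$has_tmd)
  out <- lapply(colnames(m), function(r) {
    v <- m[, r]
    det <- v > 0
    n_t <- sum(det & tmd); n_n <- sum(det & !tmd)
    mt <- if (n_t) mean(v[det & tmd]) else NA_real_
    mn <- if (n_n) mean(v[det & !tmd]) else NA_real_
    data.frame(run_id = r,
               condition = as.character(colData(x)[r, "condition"]),
               n_tmd = n_t, n_non_tmd = n_n,
               mean_tmd = mt, mean_non_tmd = mn,
               ratio = if (n_t && n_n && mt > 0) mn / mt else NA_real_)
  })
  res <- do.call(rbind, out)
  if (anyNA(res$ratio))
    .msg("TMD bias undefined (empty class) in run(s): ",
         paste(res$run_id[is.na(res$ratio)], collapse = ", "))
  res
}
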