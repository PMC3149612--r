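# shared fixture builders; everything is generated in code at test time

suppressMessages({
  library(SummarizedExperiment)
})
options(NSAFquant.quiet = TRUE)

# minimal protein database data.frame
make_db <- function(accessions, organism = "host", length_aa = 100L) {
  data.frame(
    accession = accessions,
    organism = rep_len(organism, length(accessions)),
    length_aa = rep_len(as.integer(length_aa), length(accessions)),
    sequence = "", arcog_id = NA_character_, arcog_class = NA_character_,
    has_tmd = FALSE, has_signal_peptide = FALSE, operon_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

# minimal PSM data.frame in the internal representation
make_psms <- function(peptide, accessions, run_id = "r1", charge = 2L,
                      xcorr = 3, deltacn = 0.2, is_decoy = FALSE) {
  n <- length(peptide)
  data.frame(
    run_id = rep_len(run_id, n), peptide = peptide,
    charge = rep_len(as.integer(charge), n),
    xcorr = rep_len(xcorr, n), deltacn = rep_len(deltacn, n),
    accessions = accessions, is_decoy = rep_len(is_decoy, n),
    stringsAsFactors = FALSE
  )
}

# evidence data.frame in the assembleProteins() output shape, built directly
# (for exercising balanceSpectra on hand-constructed sharing structures)
make_evidence <- function(accession, peptide, run_id, spc, is_unique,
                          lengths = NULL) {
  ev <- data.frame(accession = accession, peptide = peptide, run_id = run_id,
                   spc = spc, is_unique = is_unique, stringsAsFactors = FALSE)
  prots <- unique(accession)
  attr(ev, "protein_table") <- data.frame(
    accession = prots, n_peptides = NA_integer_, n_unique = NA_integer_,
    total_spc = NA_real_, is_decoy = FALSE
  )
  attr(ev, "peptide_map") <- split(ev$accession, ev$peptide)
  rt <- tapply(ev$spc[!duplicated(paste(ev$peptide, ev$run_id))],
               ev$run_id[!duplicated(paste(ev$peptide, ev$run_id))], sum)
  attr(ev, "run_totals") <- setNames(as.numeric(rt), names(rt))
  db <- make_db(prots)
  if (!is.null(lengths)) db$length_aa <- as.integer(lengths[prots])
  attr(ev, "db") <- db
  class(ev) <- c("protein_evidence", class(ev))
  ev
}

# build a SpectralCountExperiment directly from an aSpC (= SpC) matrix
sce_from_matrix <- function(counts, conditions, replicates = NULL,
                            organism = "host", lengths = NULL,
                            has_tmd = NULL, scale_constant = 46541) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("run%02d", seq_len(ncol(counts)))
  if (is.null(replicates)) replicates <- stats::ave(seq_along(conditions),
                                                    conditions, FUN = seq_along)
  if (is.null(lengths)) lengths <- rep(100L, nrow(counts))
  if (is.null(has_tmd)) has_tmd <- rep(FALSE, nrow(counts))
  rd <- S4Vectors::DataFrame(
    accession = rownames(counts),
    organism = rep_len(organism, nrow(counts)),
    length_aa = as.integer(lengths),
    arcog_id = NA_character_, arcog_class = NA_character_,
    has_tmd = has_tmd, has_signal_peptide = FALSE,
    operon_id = NA_character_, row.names = rownames(counts)
  )
  cd <- S4Vectors::DataFrame(run_id = colnames(counts),
                             condition = conditions,
                             replicate = as.integer(replicates),
                             row.names = colnames(counts))
  se <- SummarizedExperiment(
    assays = list(SpC = counts, aSpC = counts),
    rowData = rd, colData = cd,
    metadata = list(scale_constant = scale_constant,
                    run_totals = colSums(counts))
  )
  new("SpectralCountExperiment", se)
}

# set an assay layer, aligning dimnames with the container
set_layer <- function(x, name, m) {
  m <- as.matrix(m)
  dimnames(m) <- dimnames(x)
  SummarizedExperiment::assay(x, name) <- m
  x
}

# full normalization chain on a hand-built matrix
normalized_sce <- function(counts, conditions, ...) {
  x <- sce_from_matrix(counts, conditions, ...)
  x <- scaleNSpC(computeNSAF(x))
  renormalizeRSpC(x)
}

# protein database for a synthetic proteome, including any decoy
# accessions referenced by the PSMs
synth_db <- function(proteomes, psms = NULL) {
  p <- proteomes$proteins
  db <- data.frame(
    accession = p$accession, organism = p$organism, length_aa = p$length_aa,
    sequence = p$sequence, arcog_id = p$arcog_id, arcog_class = p$arcog_class,
    has_tmd = p$has_tmd, has_signal_peptide = p$has_signal_peptide,
    operon_id = p$operon_id, stringsAsFactors = FALSE
  )
  if (!is.null(psms) && any(psms$is_decoy)) {
    dec <- unique(unlist(strsplit(psms$accessions[psms$is_decoy], ";",
                                  fixed = TRUE)))
    db <- rbind(db, data.frame(
      accession = dec, organism = "decoy", length_aa = 100L, sequence = "",
      arcog_id = NA_character_, arcog_class = NA_character_, has_tmd = FALSE,
      has_signal_peptide = FALSE, operon_id = NA_character_
    ))
  }
  db
}

# small synthetic dataset shared across test files (memoized per session)
.fixture_env <- new.env(parent = emptyenv())

small_synthetic <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- syntheticConfig(
      n_host_proteins = 80, n_symbiont_proteins = 30, n_homolog_pairs = 5,
      spectra_per_run = 5000, n_transfer = 3, seed = 11
    )
    pr <- simulateProteomes(cfg)
    sim <- simulateCounts(cfg, pr)
    .fixture_env$small <- list(cfg = cfg, proteomes = pr, sim = sim)
  }
  .fixture_env$small
}

# the full analysis chain on the small synthetic dataset
small_sce <- function() {
  if (is.null(.fixture_env$small_sce)) {
    fx <- small_synthetic()
    psms <- filterPsms(fx$sim$psms)
    ev <- assembleProteins(psms, synth_db(fx$proteomes, psms))
    x <- SpectralCountExperiment(ev, fx$sim$run_info)
    x <- x[proteinOrganism(x) != "decoy", ]
    x <- renormalizeRSpC(scaleNSpC(computeNSAF(x)))
    .fixture_env$small_sce <- x
  }
  .fixture_env$small_sce
}
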