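#' Read a table of peptide-spectrum matches
#'
#' Reads a tab-delimited PSM table (one row per peptide-spectrum match) with
#' columns `run_id`, `peptide`, `charge`, `xcorr`, `deltacn`, `accessions`
#' (semicolon-separated protein accessions) and optionally `decoy` (0/1).
#' Differently named columns are remapped through `dialect`. Rows whose
#' mandatory fields cannot be parsed (missing charge, empty peptide,
#' non-standard residues, no accession, scores out of range) are rejected,
#' counted and reported; the count is attached as attribute `n_rejected`.
#'
#' When a `decoy` column is absent, decoy status is derived from
#' `decoy_prefix` on the accessions. A PSM whose accession set mixes target
#' and decoy entries is treated as a target match (the usual convention for
#' concatenated target-decoy searches); the number of such PSMs is logged.
#'
#' @param path path to the tab-separated PSM table.
#' @param dialect optional named character vector mapping standard column
#'   names to the file's column names, e.g. `c(peptide = "Sequence")`.
#' @param decoy_prefix accession prefix identifying decoy entries.
#' @return data.frame with columns `run_id`, `peptide`, `charge`, `xcorr`,
#'   `deltacn`, `accessions` (semicolon string, sorted), `is_decoy`.
#' @export
readPsmTable <- function(path, dialect = NULL, decoy_prefix = "Reverse_") {
  if (!file.exists(path)) .stop("PSM table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1),
              data.table = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L) .stop("empty PSM table: ", path)
  std <- c("run_id", "peptide", "charge", "xcorr", "deltacn", "accessions", "decoy")
  if (!is.null(dialect)) {
    for (nm in names(dialect)) {
      if (dialect[[nm]] %in% names(dt)) data.table::setnames(dt, dialect[[nm]], nm)
    }
  }
  mandatory <- setdiff(std, "decoy")
  missing_cols <- setdiff(mandatory, names(dt))
  if (length(missing_cols))
    .stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  psms <- data.frame(
    run_id = as.character(dt$run_id),
    peptide = toupper(as.character(dt$peptide)),
    charge = suppressWarnings(as.integer(dt$charge)),
    xcorr = suppressWarnings(as.numeric(dt$xcorr)),
    deltacn = suppressWarnings(as.numeric(dt$deltacn)),
    accessions = as.character(dt$accessions),
    stringsAsFactors = FALSE
  )
  # normalize accession strings: sorted, unique
  acc_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  acc_list <- lapply(acc_list, function(a) sort(unique(a[nzchar(a)])))
  psms$accessions <- vapply(acc_list, paste, "", collapse = ";")

  ok <- nzchar(psms$run_id) &
    nzchar(psms$peptide) &
    !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), psms$peptide) &
    !is.na(psms$charge) & psms$charge >= 1L &
    !is.na(psms$xcorr) & psms$xcorr >= 0 &
    !is.na(psms$deltacn) & psms$deltacn >= 0 & psms$deltacn <= 1 &
    nzchar(psms$accessions)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L)
    .msg(n_rejected, " PSM row(s) rejected (unparseable mandatory fields)")
  psms <- psms[ok, , drop = FALSE]
  acc_list <- acc_list[ok]
  if (nrow(psms) == 0L) .stop("no valid PSM rows in ", path)

  n_decoy_acc <- vapply(acc_list, function(a) sum(startsWith(a, decoy_prefix)), 0L)
  n_acc <- lengths(acc_list)
  if ("decoy" %in% names(dt)) {
    is_decoy <- as.integer(dt$decoy)[ok] == 1L
  } else {
    is_decoy <- n_decoy_acc == n_acc
  }
  mixed <- n_decoy_acc > 0L & n_decoy_acc < n_acc
  if (any(mixed)) {
    .msg(sum(mixed), " PSM(s) with mixed target/decoy accessions treated as target")
    is_decoy[mixed] <- FALSE
  }
  psms$is_decoy <- is_decoy
  rownames(psms) <- NULL
  attr(psms, "n_rejected") <- n_rejected
  psms
}

#' Write a PSM table
#'
#' Writes the tab-separated dialect read by [readPsmTable()].
#'
#' @param psms PSM data.frame as returned by [readPsmTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePsmTable <- function(psms, path) {
  out <- data.table(
    run_id = psms$run_id, peptide = psms$peptide, charge = psms$charge,
    xcorr = psms$xcorr, deltacn = psms$deltacn,
    accessions = psms$accessions, decoy = as.integer(psms$is_decoy)
  )
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter PSMs on per-charge XCorr and DeltaCn thresholds
#'
#' Retains matches with `xcorr >= threshold(charge)` and
#' `deltacn >= min_delta_cn`. Charges above the largest charge listed in
#' the thresholds reuse that largest charge's threshold (a conservative
#' extension of the usual +1/+2/+3 table). Input order is preserved and
#' filtering is idempotent.
#'
#' @param psms PSM data.frame (see [readPsmTable()]).
#' @param thresholds a \linkS4class{FilterThresholds} object.
#' @return the retained subset of `psms`.
#' @examples
#' t <- filterThresholds()
#' psms <- data.frame(run_id = "r1", peptide = "ELVISK", charge = 2L,
#'                    xcorr = 2.4, deltacn = 0.10, accessions = "P1",
#'                    is_decoy = FALSE)
#' filterPsms(psms, t)  # removed: XCorr 2.4 < 2.5 for charge 2
#' @export
filterPsms <- function(psms, thresholds = filterThresholds()) {
  stopifnot(is(thresholds, "FilterThresholds"))
  if (nrow(psms) == 0L) return(psms)
  thr_by_charge <- thresholds@xcorr_by_charge
  charges <- as.integer(names(thr_by_charge))
  o <- order(charges)
  charges <- charges[o]; thr_by_charge <- thr_by_charge[o]
  idx <- findInterval(psms$charge, charges)
  idx[idx == 0L] <- 1L  # charges below the smallest listed use its threshold
  thr <- thr_by_charge[idx]
  keep <- psms$xcorr >= thr & psms$deltacn >= thresholds@min_delta_cn
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy false-discovery rate
#'
#' Estimates the FDR of a concatenated target-decoy search from decoy
#' flags, using `2 * D / (T + D)` (capped at 1), the standard estimator for
#' concatenated databases; `D / T` is available via `formula = "simple"`.
#' Works on PSM tables, protein tables (any data.frame with an `is_decoy`
#' column) or a bare logical vector of decoy flags, so the estimate can be
#' computed at either the PSM or the protein level.
#'
#' @param x data.frame with an `is_decoy` column, or a logical vector.
#' @param formula `"concatenated"` for `2D/(T+D)` or `"simple"` for `D/T`.
#' @return FDR estimate in \[0, 1\].
#' @examples
#' estimateFdr(c(rep(FALSE, 98), rep(TRUE, 2)))  # 0.04
#' @export
estimateFdr <- function(x, formula = c("concatenated", "simple")) {
  formula <- match.arg(formula)
  flags <- if (is.data.frame(x)) {
    if (!"is_decoy" %in% names(x)) .stop("x has no 'is_decoy' column")
    x$is_decoy
  } else if (is.logical(x)) x else .stop("x must be a data.frame or logical vector")
  if (anyNA(flags)) .stop("is_decoy flags contain NA")
  D <- sum(flags); T <- sum(!flags)
  if (T + D == 0L) .stop("cannot estimate FDR from an empty set")
  if (D == 0L) return(0)
  fdr <- switch(formula,
    concatenated = 2 * D / (T + D),
    simple = if (T == 0L) Inf else D / T
  )
  min(fdr, 1)
}

#' Read a protein database (FASTA + annotations)
#'
#' Reads a FASTA proteome (target plus optional reversed decoy entries) and
#' merges per-protein annotations. Accessions are the first whitespace
#' token of each FASTA header. Entries whose accession starts with
#' `decoy_prefix` are labelled organism `"decoy"`; target entries absent
#' from the annotation table are labelled `"contaminant"`.
#'
#' @param fasta path to the FASTA file.
#' @param annotations optional annotation data.frame (see
#'   [readAnnotations()]) or path to the annotation TSV.
#' @param decoy_prefix accession prefix identifying decoy entries.
#' @return data.frame with columns `accession`, `organism`, `length_aa`,
#'   `sequence`, `arcog_id`, `arcog_class`, `has_tmd`,
#'   `has_signal_peptide`, `operon_id`.
#' @export
readProteinDb <- function(fasta, annotations = NULL, decoy_prefix = "Reverse_") {
  if (!file.exists(fasta)) .stop("FASTA file not found: ", fasta)
  seqs <- readAAStringSet(fasta)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(acc)) .stop("duplicate accessions in FASTA: ",
    paste(head(unique(acc[duplicated(acc)])), collapse = ", "))
  db <- data.frame(
    accession = acc,
    organism = ifelse(startsWith(acc, decoy_prefix), "decoy", NA_character_),
    length_aa = width(seqs),
    sequence = as.character(seqs),
    arcog_id = NA_character_, arcog_class = NA_character_,
    has_tmd = FALSE, has_signal_peptide = FALSE,
    operon_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) readAnnotations(annotations) else annotations
    i <- match(db$accession, ann$accession)
    hit <- !is.na(i) & is.na(db$organism)
    for (col in c("organism", "arcog_id", "arcog_class", "operon_id"))
      db[[col]][hit] <- as.character(ann[[col]][i[hit]])
    for (col in c("has_tmd", "has_signal_peptide"))
      db[[col]][hit] <- as.logical(ann[[col]][i[hit]])
  }
  unk <- is.na(db$organism)
  if (any(unk)) {
    .msg(sum(unk), " unannotated target entr(ies) labelled 'contaminant'")
    db$organism[unk] <- "contaminant"
  }
  rownames(db) <- db$accession
  db
}

#' Read a protein annotation table
#'
#' Tab-separated, one row per protein, with columns `accession`,
#' `organism`, `length`, and optionally `arcog_id`, `arcog_class`, `tmd`,
#' `signal_peptide`, `operon_id`. Flag columns accept 0/1 or TRUE/FALSE.
#'
#' @param path path to the annotation TSV.
#' @return normalized data.frame (`length` becomes `length_aa`, flags
#'   become `has_tmd` / `has_signal_peptide` logicals).
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) .stop("annotation table not found: ", path)
  ann <- as.data.frame(fread(path, sep = "\t", header = TRUE, showProgress = FALSE))
  need <- c("accession", "organism", "length")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    .stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(
    accession = as.character(ann$accession),
    organism = as.character(ann$organism),
    length_aa = as.integer(ann$length),
    arcog_id = if ("arcog_id" %in% names(ann)) as.character(ann$arcog_id) else NA_character_,
    arcog_class = if ("arcog_class" %in% names(ann)) as.character(ann$arcog_class) else NA_character_,
    has_tmd = if ("tmd" %in% names(ann))
      ann$tmd %in% c(1L, "1", TRUE, "TRUE", "true") else FALSE,
    has_signal_peptide = if ("signal_peptide" %in% names(ann))
      ann$signal_peptide %in% c(1L, "1", TRUE, "TRUE", "true") else FALSE,
    operon_id = if ("operon_id" %in% names(ann)) as.character(ann$operon_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  out$arcog_class[!is.na(out$arcog_class) & !nzchar(out$arcog_class)] <- NA_character_
  out$operon_id[!is.na(out$operon_id) & !nzchar(out$operon_id)] <- NA_character_
  if (any(out$length_aa < 1, na.rm = TRUE)) .stop("annotation lengths must be >= 1")
  out
}

# protein/peptide bookkeeping for one candidate retained set:
# pep_dt: (peptide, run_id, spc); pep_acc: list peptide -> accession set
.protein_pass <- function(pep_dt, pep_acc, retained) {
  sets <- lapply(pep_acc, intersect, retained)
  keep_pep <- lengths(sets) > 0L
  sets <- sets[keep_pep]
  if (!length(sets)) return(list(table = NULL, unique_of = character()))
  map <- data.table(
    peptide = rep(names(sets), lengths(sets)),
    accession = unlist(sets, use.names = FALSE)
  )
  uniq <- names(sets)[lengths(sets) == 1L]
  pep_spc <- pep_dt[, list(spc = sum(spc)), by = "peptide"]
  map <- merge(map, pep_spc, by = "peptide", all.x = TRUE)
  map[is.na(spc), spc := 0]
  map[, is_unique := peptide %in% uniq]
  tab <- map[, list(
    n_peptides = length(unique(peptide)),
    n_unique = sum(is_unique),
    total_spc = sum(spc)
  ), by = "accession"]
  list(table = tab, map = map)
}

#' Assemble protein identifications from filtered PSMs
#'
#' Consolidates peptide-spectrum matches into protein-level evidence under
#' the two-peptide rule: a protein is retained only if it has at least
#' `min_peptides_per_protein` distinct peptides, of which at least
#' `min_unique_peptides` map to no other retained protein, and at least
#' `min_spectra` total spectra. Peptide uniqueness is evaluated against the
#' retained set: after a first pass over all matched proteins, assembly is
#' re-run once against the survivors, so a peptide shared only with a
#' discarded protein becomes unique.
#'
#' @param psms filtered PSM data.frame (see [filterPsms()]).
#' @param db protein database data.frame (see [readProteinDb()]); every
#'   accession referenced by `psms` must be present.
#' @param thresholds a \linkS4class{FilterThresholds} object.
#' @return long-format evidence data.frame with columns `accession`,
#'   `peptide`, `run_id`, `spc` (spectra for that peptide in that run) and
#'   `is_unique`, restricted to retained proteins. Attributes:
#'   `protein_table` (per-protein peptide/spectra tallies with `is_decoy`),
#'   `peptide_map` (list: peptide -> retained accessions), `run_totals`
#'   (named vector: spectra per run, each spectrum counted once) and
#'   `db` (the database rows of retained proteins).
#' @export
assembleProteins <- function(psms, db, thresholds = filterThresholds()) {
  stopifnot(is(thresholds, "FilterThresholds"))
  if (nrow(psms) == 0L) .stop("no PSMs to assemble")
  acc_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  all_acc <- unique(unlist(acc_list, use.names = FALSE))
  unknown <- setdiff(all_acc, db$accession)
  if (length(unknown))
    .stop("accession(s) not in database: ", paste(head(unknown, 5L), collapse = ", "))

  # per (peptide, run) spectral counts -- each PSM is one spectrum
  pep_dt <- data.table(peptide = psms$peptide, run_id = psms$run_id)
  pep_dt <- pep_dt[, list(spc = .N), by = c("peptide", "run_id")]
  # peptide -> union of matched accessions over all its PSMs
  acc_dt <- data.table(
    peptide = rep(psms$peptide, lengths(acc_list)),
    accession = unlist(acc_list, use.names = FALSE)
  )
  acc_dt <- unique(acc_dt)
  pep_acc <- split(acc_dt$accession, acc_dt$peptide)

  retain_rule <- function(tab) {
    tab$accession[
      tab$n_peptides >= thresholds@min_peptides_per_protein &
      tab$n_unique >= thresholds@min_unique_peptides &
      tab$total_spc >= thresholds@min_spectra
    ]
  }
  pass1 <- .protein_pass(pep_dt, pep_acc, all_acc)
  retained <- retain_rule(pass1$table)
  pass2 <- .protein_pass(pep_dt, pep_acc, retained)
  retained <- retain_rule(pass2$table)
  final <- .protein_pass(pep_dt, pep_acc, retained)

  if (!length(retained)) {
    .msg("no proteins satisfy the assembly thresholds")
    ev <- data.frame(accession = character(), peptide = character(),
                     run_id = character(), spc = numeric(), is_unique = logical())
  } else {
    map <- final$map[accession %in% retained]
    ev <- merge(as.data.frame(map[, c("accession", "peptide", "is_unique")]),
                as.data.frame(pep_dt), by = "peptide")
    ev <- ev[, c("accession", "peptide", "run_id", "spc", "is_unique")]
    ev <- ev[order(ev$accession, ev$peptide, ev$run_id), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ptab <- if (is.null(final$table)) {
    data.frame(accession = character(), n_peptides = integer(),
               n_unique = integer(), total_spc = numeric())
  } else as.data.frame(final$table[accession %in% retained])
  ptab$is_decoy <- db$organism[match(ptab$accession, db$accession)] == "decoy"

  run_tot <- pep_dt[, list(total = sum(spc)), by = "run_id"]
  attr(ev, "protein_table") <- ptab
  attr(ev, "peptide_map") <- if (is.null(final$map)) list() else
    split(final$map$accession, final$map$peptide)
  attr(ev, "run_totals") <- setNames(run_tot$total, run_tot$run_id)
  attr(ev, "db") <- db[match(retained, db$accession), , drop = FALSE]
  class(ev) <- c("protein_evidence", class(ev))
  ev
}
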