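#' Per-gene classification track along the genome
#'
#' Classifies every gene of an annotation table by its proteomic response:
#' `not_detected` (absent from the differential table), `up_ge1.5` /
#' `down_ge1.5` (fold change of at least 1.5 in either direction, censored
#' ratios included) or `stable`. Gene order of the annotation table is
#' preserved (annotation tables are expected in genome order) and operon /
#' organism columns are passed through, giving the per-gene genome track
#' used to relate abundance changes to operon structure.
#'
#' @param diff_table data.frame from [differentialTable()].
#' @param annotations annotation data.frame (see [readAnnotations()]).
#' @param threshold fold threshold for calling a change (default 1.5).
#' @return data.frame with one row per annotation gene: `accession`,
#'   `status`, `ratio`, `organism`, `operon_id`.
#' @export
genomeTrack <- function(diff_table, annotations, threshold = 1.5) {
  i <- match(annotations$accession, diff_table$accession)
  ratio <- diff_table$ratio[i]
  status <- ifelse(is.na(i), "not_detected",
            ifelse(ratio >= threshold, "up_ge1.5",
            ifelse(ratio <= 1 / threshold, "down_ge1.5", "stable")))
  data.frame(
    accession = annotations$accession,
    status = status,
    ratio = ratio,
    organism = annotations$organism,
    operon_id = annotations$operon_id,
    stringsAsFactors = FALSE
  )
}

# serialize a count matrix as TSV (columns run.layer) + YAML sidecar
.write_count_matrix <- function(x, path_tsv, path_yaml) {
  layers <- assayNames(x)
  cols <- list(accession = rownames(x))
  for (l in layers) {
    m <- assay(x, l)
    for (r in colnames(x)) cols[[paste(r, l, sep = ".")]] <- round(m[, r], 6)
  }
  fwrite(as.data.table(cols), path_tsv, sep = "\t", quote = FALSE)
  write_yaml(list(
    runs = as.list(setNames(as.character(colData(x)$condition), colnames(x))),
    replicates = as.list(setNames(as.integer(colData(x)$replicate), colnames(x))),
    layers = layers,
    scale_constant = scaleConstant(x)
  ), path_yaml)
  invisible(path_tsv)
}

.as_thresholds <- function(t) {
  if (is(t, "FilterThresholds")) return(t)
  if (is.null(t)) return(filterThresholds())
  args <- t
  if (!is.null(args$xcorr_by_charge)) args$xcorr_by_charge <- unlist(args$xcorr_by_charge)
  do.call(filterThresholds, args)
}

.as_run_info <- function(ri) {
  if (is.data.frame(ri)) return(ri)
  # YAML form: named list run_id -> list(condition, replicate)
  data.frame(
    run_id = names(ri),
    condition = vapply(ri, function(v) as.character(v$condition), ""),
    replicate = vapply(ri, function(v) as.integer(v$replicate), 0L),
    stringsAsFactors = FALSE
  )
}

#' Run the full spectral-count analysis pipeline
#'
#' Executes, in order: PSM reading and score filtering, protein assembly,
#' spectral balancing and the NSAF / nSpC / RSpC normalization chain,
#' differential abundance between the reference and target conditions, the
#' transfer-enrichment screen against the purified sample (skipped with a
#' warning when that condition is absent), gene-set enrichment over arCOG
#' classes and operons (skipped with a warning when gene-set input is
#' unavailable), replicate-correlation / FDR / TMD-bias QC, and the
#' per-gene genome track. Every stage's output is written as TSV before
#' the next stage begins, and a YAML manifest records the seed, input file
#' digests and per-stage counts, so identical inputs and seed give
#' byte-identical output bundles.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   `psm_tables` (character vector of PSM table paths), `fasta`,
#'   `annotations` (paths), `run_info` (data.frame or named list:
#'   run_id -> condition/replicate; must cover at least the reference and
#'   target conditions), and optionally `thresholds` (list of
#'   [filterThresholds()] arguments), `scale_constant` (default 46541),
#'   `organism` (default `"host"`), `reference_condition`
#'   (`"pure_host"`), `target_condition` (`"coculture"`),
#'   `purified_condition` (`"purified_symbiont"`), `alpha` (0.05),
#'   `phi_min` (2), `min_rspc` (20), `gene_sets` (kinds to build from the
#'   annotations and/or GMT paths; default `c("arcog_class", "operon")`;
#'   `NULL` skips enrichment), `gsea` (list: `n_permutations`,
#'   `weight_exponent`), `seed`.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the in-memory results: `experiment`,
#'   `differential`, `transfer`, `enrichment`, `qc`, `genome_track`,
#'   `manifest`.
#' @export
runAll <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) config <- read_yaml(config)
  for (nm in c("psm_tables", "fasta", "annotations", "run_info"))
    if (is.null(config[[nm]])) .stop("config lacks '", nm, "'")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  thresholds <- .as_thresholds(config$thresholds)
  run_info <- .as_run_info(config$run_info)
  organism <- config$organism %||% "host"
  ref_cond <- config$reference_condition %||% "pure_host"
  tgt_cond <- config$target_condition %||% "coculture"
  pur_cond <- config$purified_condition %||% "purified_symbiont"
  need_conds <- c(ref_cond, tgt_cond)
  missing_conds <- setdiff(need_conds, run_info$condition)
  if (length(missing_conds))
    .stop("run_info lacks condition(s): ", paste(missing_conds, collapse = ", "))

  stage <- function(name, ...) .msg("stage ", name, ": ", ...)
  manifest <- list(seed = seed,
                   package_version = as.character(packageVersion("NSAFquant")),
                   inputs = list(), stages = list())
  for (f in c(config$psm_tables, config$fasta, config$annotations))
    manifest$inputs[[basename(f)]] <- unname(md5sum(f))

  # stage 1: PSM io + filtering + assembly ---------------------------------
  psms <- do.call(rbind, lapply(config$psm_tables, readPsmTable))
  n_raw <- nrow(psms)
  psms <- filterPsms(psms, thresholds)
  stage("psm_io", n_raw, " PSMs read, ", nrow(psms), " pass score filters")
  db <- readProteinDb(config$fasta, config$annotations)
  evidence <- assembleProteins(psms, db, thresholds)
  ptab <- attr(evidence, "protein_table")
  stage("assembly", sum(!ptab$is_decoy), " target proteins retained (",
        sum(ptab$is_decoy), " decoy)")
  manifest$stages$psm_io <- list(psms_read = n_raw, psms_filtered = nrow(psms),
                                 proteins_retained = sum(!ptab$is_decoy),
                                 decoy_proteins = sum(ptab$is_decoy))

  # stage 2: quantification chain ------------------------------------------
  sce <- SpectralCountExperiment(evidence, run_info,
                                 scale_constant = config$scale_constant %||% 46541)
  # drop decoy proteins from the quantitative container
  sce <- sce[proteinOrganism(sce) != "decoy", ]
  sce <- computeNSAF(sce)
  sce <- scaleNSpC(sce)
  sce <- renormalizeRSpC(sce, organism = organism,
                         reference_condition = ref_cond,
                         target_condition = tgt_cond)
  .write_count_matrix(sce, file.path(outdir, "count_matrix.tsv"),
                      file.path(outdir, "count_matrix.yaml"))
  stage("quantify", nrow(sce), " proteins x ", ncol(sce), " runs")
  manifest$stages$quantify <- list(proteins = nrow(sce), runs = ncol(sce),
                                   scale_constant = scaleConstant(sce))

  # stage 3: differential abundance ----------------------------------------
  diff <- differentialTable(sce, reference_condition = ref_cond,
                            target_condition = tgt_cond, organism = organism,
                            alpha = config$alpha %||% 0.05)
  fwrite(as.data.table(lapply(diff, function(c) if (is.numeric(c)) round(c, 6) else c)),
         file.path(outdir, "differential.tsv"), sep = "\t", quote = FALSE)
  stage("differential", nrow(diff), " proteins, ",
        sum(diff$significant, na.rm = TRUE), " significant")
  manifest$stages$differential <- list(proteins = nrow(diff),
                                       significant = sum(diff$significant, na.rm = TRUE))

  # stage 4: transfer-enrichment screen -------------------------------------
  transfer <- NULL
  if (pur_cond %in% run_info$condition) {
    transfer <- screenCandidates(sce, phi_min = config$phi_min %||% 2,
                                 min_rspc = config$min_rspc %||% 20,
                                 organism = organism,
                                 purified_condition = pur_cond,
                                 coculture_condition = tgt_cond)
    fwrite(as.data.table(lapply(transfer, function(c) if (is.numeric(c)) round(c, 6) else c)),
           file.path(outdir, "transfer.tsv"), sep = "\t", quote = FALSE)
    stage("transfer", nrow(transfer), " candidates, ",
          sum(transfer$passes_screen), " pass the screen")
    manifest$stages$transfer <- list(candidates = nrow(transfer),
                                     passes = sum(transfer$passes_screen))
  } else {
    warning("purified condition '", pur_cond,
            "' absent; transfer stage skipped", call. = FALSE)
  }

  # stage 5: gene-set enrichment --------------------------------------------
  enrichment <- NULL
  gs_spec <- if ("gene_sets" %in% names(config)) config$gene_sets else
    c("arcog_class", "operon")
  if (!is.null(gs_spec)) {
    ann <- readAnnotations(config$annotations)
    sets <- list()
    for (g in gs_spec) {
      s <- if (g %in% c("arcog_class", "operon")) loadGeneSets(ann, g)
           else if (file.exists(g)) loadGeneSets(g, "custom")
           else { warning("gene-set input '", g, "' not found; skipped",
                          call. = FALSE); NULL }
      if (!is.null(s)) {
        kind <- attr(s, "kind")
        names(s) <- paste(kind, names(s), sep = ":")
        sets <- c(sets, lapply(s, identity))
      }
    }
    if (length(sets)) {
      ranked <- rankSignalToNoise(sce, condition_a = tgt_cond,
                                  condition_b = ref_cond, organism = organism)
      enrichment <- runGsea(ranked, sets,
                            n_permutations = config$gsea$n_permutations %||% 1000,
                            seed = seed,
                            weight_exponent = config$gsea$weight_exponent %||% 1)
      fwrite(as.data.table(lapply(enrichment,
               function(c) if (is.numeric(c)) round(c, 6) else c)),
             file.path(outdir, "enrichment.tsv"), sep = "\t", quote = FALSE)
      stage("set_enrichment", nrow(enrichment), " gene sets evaluated")
      manifest$stages$set_enrichment <- list(sets = nrow(enrichment))
    } else {
      warning("no usable gene sets; enrichment stage skipped", call. = FALSE)
    }
  } else {
    warning("no gene-set input; enrichment stage skipped", call. = FALSE)
  }

  # stage 6: QC --------------------------------------------------------------
  qc <- list()
  qc[[1]] <- data.frame(metric = "fdr_psm", item = "all",
                        value = estimateFdr(psms))
  qc[[2]] <- data.frame(metric = "fdr_protein", item = "all",
                        value = estimateFdr(ptab))
  for (cond in unique(run_info$condition)) {
    runs <- run_info$run_id[run_info$condition == cond]
    if (length(runs) >= 2L) {
      cmb <- utils::combn(runs, 2L)
      for (j in seq_len(ncol(cmb))) {
        val <- tryCatch(replicateCorrelation(sce, cmb[1, j], cmb[2, j]),
                        error = function(e) NA_real_)
        qc[[length(qc) + 1]] <- data.frame(
          metric = "replicate_correlation",
          item = paste(cmb[1, j], cmb[2, j], sep = "|"), value = val)
      }
    }
  }
  tmd <- tmdBiasSummary(sce)
  for (j in seq_len(nrow(tmd)))
    qc[[length(qc) + 1]] <- data.frame(metric = "tmd_bias_ratio",
                                       item = tmd$run_id[j],
                                       value = tmd$ratio[j])
  qc_df <- do.call(rbind, qc)
  qc_df$value <- round(qc_df$value, 6)
  fwrite(as.data.table(qc_df), file.path(outdir, "qc.tsv"), sep = "\t",
         quote = FALSE)
  stage("qc", nrow(qc_df), " metrics")

  # stage 7: genome track -----------------------------------------------------
  ann_all <- readAnnotations(config$annotations)
  track <- genomeTrack(diff, ann_all[ann_all$organism == organism, , drop = FALSE])
  track$ratio <- round(track$ratio, 6)
  fwrite(as.data.table(track), file.path(outdir, "genome_track.tsv"),
         sep = "\t", quote = FALSE)
  stage("genome_track", nrow(track), " genes")
  manifest$stages$genome_track <- list(genes = nrow(track))

  write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(list(experiment = sce, differential = diff, transfer = transfer,
                 enrichment = enrichment, qc = qc_df, genome_track = track,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
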