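# arCOG single-letter functional classes used for synthetic annotation
.ARCOG_CLASSES <- c("J", "K", "L", "D", "O", "M", "N", "P", "T",
                    "C", "G", "E", "F", "H", "I", "Q", "R", "S")

# draw a random protein sequence of length L
.rand_seq <- function(L) paste(sample(.AA20, L, replace = TRUE), collapse = "")

# find, in a host sequence, a block of >= 2 consecutive fully-cleaved
# detectable peptides not touching either terminus; returns the block
# string or NULL
.shared_block <- function(sequence, min_len, max_len) {
  frag <- digestTryptic(sequence, missed_cleavages = 0, min_len = 1,
                        max_len = .Machine$integer.max)
  m <- nrow(frag)
  if (m < 4L) return(NULL)
  ok <- frag$end - frag$start + 1L >= min_len &
        frag$end - frag$start + 1L <= max_len
  ok[c(1L, m)] <- FALSE  # interior fragments only
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  good <- which(r$values & r$lengths >= 2L)
  if (!length(good)) return(NULL)
  i <- good[1L]
  last <- ends[i]
  first <- last - r$lengths[i] + 1L
  last <- min(last, first + 3L)  # at most 4 shared peptides
  substring(sequence, frag$start[first], frag$end[last])
}

# insertion point in a symbiont sequence: after K/R not followed by P
.insertion_point <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  k <- which(res %in% c("K", "R"))
  k <- k[k < n - 1L & res[k + 1L] != "P"]
  if (!length(k)) return(NA_integer_)
  k[ceiling(length(k) / 2)]
}

#' Simulate a two-organism proteome pair
#'
#' Draws random amino-acid sequences with log-normal lengths and molar
#' abundances for a host and a symbiont proteome, assigns transmembrane /
#' signal-peptide flags, arCOG functional classes and operon memberships,
#' constructs cross-species homolog pairs by copying a block of consecutive
#' tryptic peptides from a host protein into a symbiont protein (so the
#' pair shares tryptic peptides and exercises shared-peptide balancing),
#' and resolves the condition fold-effect table and the designated
#' transferred-protein set. Transfer candidates are drawn from the top
#' abundance-weight quartile of the host proteome — the quantifiable
#' regime in which a spectral-count screen is meaningful. All randomness
#' derives from `config@seed`; re-running with the same configuration is
#' byte-identical.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir optional output directory; when given, writes
#'   `proteomes.fasta` (targets plus reversed decoys if configured),
#'   `annotations.tsv` and `ground_truth.yaml`.
#' @return object of class `"synthetic_proteomes"`: a list with
#'   `proteins` (accession, organism, sequence, length_aa, abundance,
#'   annotations), `homolog_pairs`, `effect_table`, `transfer_set` and
#'   `config`.
#' @export
simulateProteomes <- function(config = syntheticConfig(), dir = NULL) {
  validObject(config)
  set.seed(config@seed)
  n_h <- config@n_host_proteins
  n_s <- config@n_symbiont_proteins
  acc <- c(sprintf("HOST_%04d", seq_len(n_h)), sprintf("SYMB_%04d", seq_len(n_s)))
  organism <- rep(c("host", "symbiont"), c(n_h, n_s))
  n <- n_h + n_s
  len <- pmin(pmax(round(rlnorm(n, config@length_meanlog, config@length_sdlog)), 60L), 3000L)
  seqs <- vapply(len, .rand_seq, "")
  abundance <- rlnorm(n, config@abundance_meanlog, config@abundance_sdlog)
  has_tmd <- runif(n) < config@tmd_fraction
  has_sig <- runif(n) < 0.10
  arcog_class <- sample(.ARCOG_CLASSES, n, replace = TRUE)
  arcog_id <- sprintf("arCOG%05d", sample.int(99999L, n))
  # operons: consecutive blocks of 1-5 genes within each organism
  operon_of <- function(n_org, prefix) {
    ids <- character(n_org); i <- 1L; op <- 0L
    while (i <= n_org) {
      op <- op + 1L
      size <- sample.int(5L, 1L)
      j <- min(i + size - 1L, n_org)
      ids[i:j] <- sprintf("%s%04d", prefix, op)
      i <- j + 1L
    }
    ids
  }
  operon_id <- c(operon_of(n_h, "opH"), operon_of(n_s, "opS"))

  # homolog pairs sharing tryptic peptides (exact block copies)
  pairs <- list()
  if (config@n_homolog_pairs > 0L) {
    host_order <- sample.int(n_h)
    symb_pick <- sample.int(n_s, config@n_homolog_pairs)
    made <- 0L
    for (hi in host_order) {
      if (made == config@n_homolog_pairs) break
      block <- .shared_block(seqs[hi], config@peptide_min_len, config@peptide_max_len)
      if (is.null(block)) next
      si <- n_h + symb_pick[made + 1L]
      at <- .insertion_point(seqs[si])
      if (is.na(at)) next
      seqs[si] <- paste0(substring(seqs[si], 1L, at), block,
                         substring(seqs[si], at + 1L, nchar(seqs[si])))
      len[si] <- nchar(seqs[si])
      made <- made + 1L
      pairs[[made]] <- data.frame(
        host_accession = acc[hi], symbiont_accession = acc[si],
        block = block, stringsAsFactors = FALSE
      )
    }
    if (made < config@n_homolog_pairs)
      .stop("could only construct ", made, " of ", config@n_homolog_pairs,
            " homolog pairs; increase protein lengths")
  }
  homolog_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(host_accession = character(), symbiont_accession = character(),
               block = character())

  proteins <- data.frame(
    accession = acc, organism = organism, length_aa = len,
    abundance = abundance, has_tmd = has_tmd, has_signal_peptide = has_sig,
    arcog_id = arcog_id, arcog_class = arcog_class, operon_id = operon_id,
    sequence = seqs, stringsAsFactors = FALSE
  )

  # condition fold effects (host response to the co-culture by default)
  if (nrow(config@effect_table)) {
    effect_table <- config@effect_table
    missing_acc <- setdiff(effect_table$accession, acc)
    if (length(missing_acc))
      .stop("effect_table accession(s) not in proteome: ",
            paste(head(missing_acc), collapse = ", "))
  } else {
    n_eff <- round(config@effect_fraction * n_h)
    if (n_eff > 0L) {
      eff_acc <- sort(sample(acc[organism == "host"], n_eff))
      fold <- exp(runif(n_eff, log(config@effect_fold_range[1]),
                        log(config@effect_fold_range[2])))
      down <- runif(n_eff) < 0.5
      fold[down] <- 1 / fold[down]
      effect_table <- data.frame(accession = eff_acc, condition = "coculture",
                                 fold = fold, stringsAsFactors = FALSE)
    } else {
      effect_table <- data.frame(accession = character(), condition = character(),
                                 fold = numeric(), stringsAsFactors = FALSE)
    }
  }

  # designated transferred proteins: top abundance-weight quartile of host
  if (nrow(config@transfer_set)) {
    transfer_set <- config@transfer_set
  } else if (config@n_transfer > 0L) {
    w <- abundance * ifelse(has_tmd, 1 / config@tmd_depression, 1)
    host_w <- w[organism == "host"]
    eligible <- acc[organism == "host"][host_w >= stats::quantile(host_w, 0.75)]
    transfer_set <- data.frame(
      accession = sort(sample(eligible, min(config@n_transfer, length(eligible)))),
      fold = config@transfer_fold, stringsAsFactors = FALSE
    )
  } else {
    transfer_set <- data.frame(accession = character(), fold = numeric())
  }

  out <- list(proteins = proteins, homolog_pairs = homolog_pairs,
              effect_table = effect_table, transfer_set = transfer_set,
              config = config)
  class(out) <- "synthetic_proteomes"
  if (!is.null(dir)) writeProteomeFiles(out, dir)
  out
}

#' Write the synthetic proteome files
#'
#' Emits `proteomes.fasta` (targets, plus reversed `Reverse_` decoy
#' entries when configured), `annotations.tsv` in the dialect read by
#' [readAnnotations()], and `ground_truth.yaml` (see [groundTruth()]).
#'
#' @param proteomes a `"synthetic_proteomes"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeProteomeFiles <- function(proteomes, dir) {
  stopifnot(inherits(proteomes, "synthetic_proteomes"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- proteomes$proteins
  seqs <- p$sequence
  names(seqs) <- p$accession
  if (proteomes$config@decoy) {
    rev_seqs <- vapply(strsplit(p$sequence, "", fixed = TRUE),
                       function(s) paste(rev(s), collapse = ""), "")
    names(rev_seqs) <- paste0("Reverse_", p$accession)
    seqs <- c(seqs, rev_seqs)
  }
  writeXStringSet(AAStringSet(seqs), file.path(dir, "proteomes.fasta"))
  ann <- data.table(
    accession = p$accession, organism = p$organism, length = p$length_aa,
    arcog_id = p$arcog_id, arcog_class = p$arcog_class,
    tmd = as.integer(p$has_tmd), signal_peptide = as.integer(p$has_signal_peptide),
    operon_id = p$operon_id
  )
  fwrite(ann, file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE)
  write_yaml(groundTruth(proteomes), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Ground-truth ledger of a synthetic proteome
#'
#' Machine-readable record of every simulated parameter: the seed, the
#' per-protein truth (abundance, TMD flag, organism), homolog pairs,
#' condition fold effects, designated transferred proteins and the
#' contamination fraction — everything recovery tests need.
#'
#' @param proteomes a `"synthetic_proteomes"` object.
#' @return a named list (YAML-serializable).
#' @export
groundTruth <- function(proteomes) {
  stopifnot(inherits(proteomes, "synthetic_proteomes"))
  p <- proteomes$proteins
  cfg <- proteomes$config
  list(
    seed = cfg@seed,
    n_host_proteins = cfg@n_host_proteins,
    n_symbiont_proteins = cfg@n_symbiont_proteins,
    spectra_per_run = cfg@spectra_per_run,
    replicates_per_condition = cfg@replicates_per_condition,
    tmd_depression = cfg@tmd_depression,
    contamination_fraction = cfg@contamination_fraction,
    coculture_symbiont_fraction = cfg@coculture_symbiont_fraction,
    accessions = p$accession,
    organism = p$organism,
    abundance = p$abundance,
    length_aa = p$length_aa,
    has_tmd = p$has_tmd,
    homolog_pairs = as.list(proteomes$homolog_pairs[
      c("host_accession", "symbiont_accession")]),
    effect_table = as.list(proteomes$effect_table),
    transfer_set = as.list(proteomes$transfer_set)
  )
}

# fold multipliers for one condition from the effect table
.condition_folds <- function(proteomes, condition) {
  p <- proteomes$proteins
  fold <- setNames(rep(1, nrow(p)), p$accession)
  eff <- proteomes$effect_table
  if (nrow(eff)) {
    hit <- eff$condition == condition
    fold[eff$accession[hit]] <- eff$fold[hit]
  }
  fold
}

# per-protein spectrum-allocation weights for one condition (normalized)
.condition_weights <- function(proteomes, condition, detectable) {
  cfg <- proteomes$config
  p <- proteomes$proteins
  base <- p$abundance * p$length_aa *
    ifelse(p$has_tmd, 1 / cfg@tmd_depression, 1) * detectable
  names(base) <- p$accession
  host <- p$organism == "host"
  fold <- .condition_folds(proteomes, condition)
  w <- base * fold
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  if (condition == "pure_host") {
    out <- norm(w * host)
  } else if (condition == "coculture") {
    out <- norm(w * host) * (1 - cfg@coculture_symbiont_fraction) +
           norm(w * !host) * cfg@coculture_symbiont_fraction
  } else if (condition == "purified_symbiont") {
    # host carry-over proportional to co-culture host weights, with the
    # designated transferred proteins genuinely enriched
    wc <- base * .condition_folds(proteomes, "coculture")
    tr <- setNames(rep(1, nrow(p)), p$accession)
    ts <- proteomes$transfer_set
    if (nrow(ts)) tr[ts$accession] <- ts$fold
    out <- norm(wc * tr * host) * cfg@contamination_fraction +
           norm(w * !host) * (1 - cfg@contamination_fraction)
  } else .stop("unknown condition: ", condition)
  if (sum(out) == 0) .stop("zero total weight for condition ", condition)
  out / sum(out)
}

#' Expected per-run spectral counts under the generator model
#'
#' The multinomial expectation `spectra_per_run x weight` for each protein
#' in one run of a condition; useful for conditioning recovery tests on
#' proteins above a quantification floor.
#'
#' @param proteomes a `"synthetic_proteomes"` object.
#' @param condition condition label.
#' @return named numeric vector of expected spectra per run.
#' @export
expectedCounts <- function(proteomes, condition) {
  detectable <- .detectable_flags(proteomes)
  w <- .condition_weights(proteomes, condition, detectable)
  w * proteomes$config@spectra_per_run
}

# 0-missed-cleavage detectable peptides per protein + peptide -> accession
# index over the whole target database
.peptide_index <- function(proteomes) {
  cfg <- proteomes$config
  p <- proteomes$proteins
  peps <- lapply(p$sequence, function(s)
    digestTryptic(s, missed_cleavages = 0, min_len = cfg@peptide_min_len,
                  max_len = cfg@peptide_max_len)$peptide)
  names(peps) <- p$accession
  long <- data.table(
    accession = rep(p$accession, lengths(peps)),
    peptide = unlist(peps, use.names = FALSE)
  )
  long <- unique(long)
  acc_of <- long[, list(accessions = paste(sort(accession), collapse = ";")),
                 by = "peptide"]
  list(peptides = peps,
       acc_str = setNames(acc_of$accessions, acc_of$peptide))
}

.detectable_flags <- function(proteomes) {
  idx <- attr(proteomes, ".pep_idx")
  if (is.null(idx)) idx <- .peptide_index(proteomes)
  as.numeric(lengths(idx$peptides)[proteomes$proteins$accession] > 0L)
}

#' Simulate replicate PSM tables
#'
#' For every run, `spectra_per_run` MS/MS spectra are allocated
#' multinomially over proteins with weights
#' `abundance x length x (1 / tmd_depression for TMD proteins) x condition
#' fold effects`, then distributed uniformly over each protein's
#' detectable fully-cleaved tryptic peptides. Pure-host runs contain only
#' host spectra; co-culture runs mix host and symbiont spectra at the
#' configured split; purified-symbiont runs mix symbiont spectra with a
#' `contamination_fraction` of host spectra drawn proportionally to the
#' co-culture host weights, with designated transferred proteins
#' up-weighted by their enrichment fold. PSM scores are drawn above the
#' default filter thresholds. When decoys are configured, filter-passing
#' decoy PSMs are added at `decoy_psm_rate` so that target-decoy FDR
#' estimation is exercised. All randomness derives from `config@seed`.
#'
#' @param config the \linkS4class{SyntheticConfig} used for the proteomes.
#' @param proteomes object from [simulateProteomes()].
#' @param dir optional output directory; writes one `psm_<run_id>.tsv`
#'   per run.
#' @return list with `psms` (one PSM data.frame, all runs, in the dialect
#'   of [readPsmTable()]) and `run_info` (run_id, condition, replicate).
#' @export
simulateCounts <- function(config, proteomes, dir = NULL) {
  stopifnot(inherits(proteomes, "synthetic_proteomes"))
  set.seed(config@seed + 99991L)
  idx <- .peptide_index(proteomes)
  peps <- idx$peptides
  detectable <- as.numeric(lengths(peps)[proteomes$proteins$accession] > 0L)
  dropped <- sum(detectable == 0)
  if (dropped)
    .msg(dropped, " protein(s) without detectable tryptic peptides produce no spectra")

  # decoy peptide pool (reversed sequences), excluding target collisions
  decoy_pool <- NULL
  if (config@decoy && config@decoy_psm_rate > 0) {
    rev_seqs <- vapply(strsplit(proteomes$proteins$sequence, "", fixed = TRUE),
                       function(s) paste(rev(s), collapse = ""), "")
    dpeps <- lapply(rev_seqs, function(s)
      digestTryptic(s, missed_cleavages = 0, min_len = config@peptide_min_len,
                    max_len = config@peptide_max_len)$peptide)
    dacc <- paste0("Reverse_", proteomes$proteins$accession)
    dlong <- data.table(accession = rep(dacc, lengths(dpeps)),
                        peptide = unlist(dpeps, use.names = FALSE))
    dlong <- dlong[!peptide %in% names(idx$acc_str)]
    if (nrow(dlong)) {
      dagg <- dlong[, list(accessions = paste(sort(accession), collapse = ";")),
                    by = "peptide"]
      decoy_pool <- dagg
    }
  }

  conditions <- c("pure_host", "coculture", "purified_symbiont")
  reps <- config@replicates_per_condition
  run_info <- data.frame(
    run_id = paste0(rep(conditions, each = reps), "_r", rep(seq_len(reps), 3)),
    condition = rep(conditions, each = reps),
    replicate = rep(seq_len(reps), 3),
    stringsAsFactors = FALSE
  )

  thr <- c(`1` = 1.8, `2` = 2.5, `3` = 3.5)
  draw_scores <- function(n) {
    charge <- sample(c(1L, 2L, 3L), n, replace = TRUE, prob = c(0.05, 0.60, 0.35))
    data.frame(
      charge = charge,
      xcorr = round(thr[as.character(charge)] + rexp(n, rate = 2), 4),
      deltacn = round(0.08 + runif(n) * 0.25, 4)
    )
  }

  out_runs <- vector("list", nrow(run_info))
  for (r in seq_len(nrow(run_info))) {
    cond <- run_info$condition[r]
    w <- .condition_weights(proteomes, cond, detectable)
    counts <- as.vector(rmultinom(1L, config@spectra_per_run, w))
    names(counts) <- names(w)
    nz <- which(counts > 0L)
    pep_vec <- vector("list", length(nz))
    for (k in seq_along(nz)) {
      accn <- names(counts)[nz[k]]
      pp <- peps[[accn]]
      ci <- counts[nz[k]]
      if (length(pp) == 1L) {
        pep_vec[[k]] <- rep(pp, ci)
      } else {
        pc <- as.vector(rmultinom(1L, ci, rep(1 / length(pp), length(pp))))
        pep_vec[[k]] <- rep(pp, pc)
      }
    }
    pep_all <- unlist(pep_vec, use.names = FALSE)
    n <- length(pep_all)
    sc <- draw_scores(n)
    run_psms <- data.frame(
      run_id = run_info$run_id[r], peptide = pep_all,
      charge = sc$charge, xcorr = unname(sc$xcorr), deltacn = sc$deltacn,
      accessions = unname(idx$acc_str[pep_all]),
      is_decoy = FALSE, stringsAsFactors = FALSE
    )
    if (!is.null(decoy_pool)) {
      n_dec <- rbinom(1L, config@spectra_per_run, config@decoy_psm_rate)
      if (n_dec > 0L) {
        di <- sample.int(nrow(decoy_pool), n_dec, replace = TRUE)
        dsc <- draw_scores(n_dec)
        run_psms <- rbind(run_psms, data.frame(
          run_id = run_info$run_id[r], peptide = decoy_pool$peptide[di],
          charge = dsc$charge, xcorr = unname(dsc$xcorr), deltacn = dsc$deltacn,
          accessions = decoy_pool$accessions[di],
          is_decoy = TRUE, stringsAsFactors = FALSE
        ))
      }
    }
    out_runs[[r]] <- run_psms
  }
  psms <- do.call(rbind, out_runs)
  rownames(psms) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (rid in run_info$run_id)
      writePsmTable(psms[psms$run_id == rid, , drop = FALSE],
                    file.path(dir, paste0("psm_", rid, ".tsv")))
  }
  list(psms = psms, run_info = run_info)
}
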