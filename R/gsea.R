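#' Rank proteins by signal-to-noise between two conditions
#'
#' For each protein the score is
#' `(mean_a - mean_b) / (sd_a + sd_b)` over replicate values of a layer,
#' the signal-to-noise ranking metric standard in gene-set enrichment
#' analysis. Each standard deviation is floored at `sd_floor * |mean|`
#' (and at `sd_floor` when the mean is zero), the usual guard against
#' near-constant profiles; set `sd_floor = 0` for the unguarded statistic.
#' Proteins are returned in decreasing score order with deterministic
#' alphabetical tie-breaking, so the ranking is invariant to input order.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param condition_a,condition_b condition labels; positive scores mean
#'   higher abundance in `condition_a`.
#' @param layer assay to use (default `"NSAF"`).
#' @param organism optional organism restriction.
#' @param sd_floor relative standard-deviation floor (default 0.2).
#' @return data.frame with columns `accession` and `score`, ordered by
#'   decreasing score.
#' @export
rankSignalToNoise <- function(x, condition_a = "coculture",
                              condition_b = "pure_host", layer = "NSAF",
                              organism = NULL, sd_floor = 0.2) {
  if (!layer %in% assayNames(x)) .stop("no layer '", layer, "'")
  runs_a <- conditionRuns(x, condition_a)
  runs_b <- conditionRuns(x, condition_b)
  if (length(runs_a) < 2L || length(runs_b) < 2L)
    .stop("signal-to-noise ranking needs >= 2 replicates per condition")
  m <- assay(x, layer)
  if (!is.null(organism)) m <- m[proteinOrganism(x) == organism, , drop = FALSE]
  a <- m[, runs_a, drop = FALSE]; b <- m[, runs_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- apply(a, 1L, sd); sb <- apply(b, 1L, sd)
  floor_of <- function(s, mu) {
    f <- pmax(s, sd_floor * abs(mu))
    if (sd_floor > 0) f[f == 0] <- sd_floor
    f
  }
  sa <- floor_of(sa, ma); sb <- floor_of(sb, mb)
  denom <- sa + sb
  score <- ifelse(denom == 0, 0, (ma - mb) / denom)
  out <- data.frame(accession = rownames(m), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# core running-sum computation on an already-ordered score vector
.es_core <- function(scores, hit, weight_exponent) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight_exponent
  nr <- sum(w[hit])
  step <- numeric(n)
  step[hit] <- if (nr > 0) w[hit] / nr else 1 / nh  # all-zero hit scores: flat
  step[!hit] <- -1 / (n - nh)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating `|score|^w / sum(|score|^w)` at each
#' gene-set member ("hit") and `-1 / (N - Nh)` at each non-member; the
#' enrichment score (ES) is the signed maximum deviation of this running
#' sum from zero, the weighted Kolmogorov-Smirnov statistic of gene-set
#' enrichment analysis. `weight_exponent = 0` gives the classic unweighted
#' KS statistic.
#'
#' @param ranked data.frame from [rankSignalToNoise()] (columns
#'   `accession`, `score`, already ordered), or a named numeric score
#'   vector in ranked order.
#' @param members character vector of gene-set member accessions; must
#'   intersect the ranked list and must not cover it entirely.
#' @param weight_exponent hit-weighting exponent (default 1).
#' @return list with `es` (signed ES in \[-1, 1\]), `running` (running-sum
#'   profile) and `hits` (logical hit indicator along the list).
#' @export
enrichmentScore <- function(ranked, members, weight_exponent = 1) {
  if (is.data.frame(ranked)) {
    scores <- setNames(ranked$score, ranked$accession)
  } else scores <- ranked
  if (is.null(names(scores))) .stop("ranked scores must be named by accession")
  hit <- names(scores) %in% members
  if (!any(hit)) .stop("gene set does not intersect the ranked list")
  if (all(hit)) .stop("gene set covers the entire ranked list")
  res <- .es_core(scores, hit, weight_exponent)
  list(es = res$es, running = res$running, hits = hit)
}

#' Permutation-normalized enrichment score
#'
#' Computes the enrichment score of a gene set, then a null distribution
#' by gene-set (tag) permutation: `n_permutations` random sets of the same
#' size drawn from the ranked list. The normalized enrichment score (NES)
#' is the ES divided by the mean |ES| of same-sign permutations, and the
#' p-value is the fraction of same-sign permutations at least as extreme,
#' with a +1 pseudocount in numerator and denominator. Gene-set
#' permutation is used because with three replicates per condition the
#' number of distinct phenotype relabellings is far too small for a
#' permutation null. Fixing `seed` makes the result reproducible.
#'
#' @param ranked ranked scores (see [enrichmentScore()]).
#' @param members gene-set member accessions.
#' @param n_permutations number of random same-size sets (>= 100).
#' @param seed optional integer seed for the permutations.
#' @param weight_exponent hit-weighting exponent (default 1).
#' @param set_id optional label copied to the output.
#' @return one-row data.frame: `set_id`, `size` (members in the list),
#'   `es`, `nes`, `p_value`, `direction`
#'   (`coculture_enriched` for positive ES, i.e. enrichment in the
#'   condition given first to the ranking; `pure_enriched` otherwise) and
#'   `n_same_sign` (permutations supporting the null tail).
#' @export
normalizeES <- function(ranked, members, n_permutations = 1000, seed = NULL,
                        weight_exponent = 1, set_id = NA_character_) {
  if (n_permutations < 100L) .stop("n_permutations must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  obs <- enrichmentScore(ranked, members, weight_exponent)
  scores <- if (is.data.frame(ranked)) setNames(ranked$score, ranked$accession) else ranked
  n <- length(scores)
  size <- sum(obs$hits)
  es_perm <- vapply(seq_len(n_permutations), function(i) {
    hit <- logical(n)
    hit[sample.int(n, size)] <- TRUE
    .es_core(scores, hit, weight_exponent)$es
  }, numeric(1))
  same <- es_perm[sign(es_perm) == sign(obs$es)]
  n_same <- length(same)
  if (n_same == 0L) {
    .msg("no same-sign permutations for set ", set_id,
         "; p floored at 1/(n+1), NES undefined")
    nes <- NA_real_
    p <- 1 / (n_permutations + 1)
  } else {
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + n_same)
  }
  data.frame(
    set_id = set_id, size = size, es = obs$es, nes = nes, p_value = p,
    direction = if (obs$es >= 0) "coculture_enriched" else "pure_enriched",
    n_same_sign = n_same, stringsAsFactors = FALSE
  )
}

#' Gene-set enrichment over a collection of sets
#'
#' Evaluates every gene set of a collection against one ranked list. Sets
#' that do not intersect the list (or cover all of it) are skipped. The
#' gene-set permutation null of the enrichment score depends only on the
#' set's size (random same-size draws from the fixed ranked list), so one
#' null distribution of `n_permutations` scores is computed per distinct
#' set size and shared by all sets of that size — numerically equivalent
#' to per-set permutation and much cheaper for large collections such as
#' genome-wide operon tables. NES and p-values follow [normalizeES()].
#'
#' @param ranked ranked scores (see [enrichmentScore()]).
#' @param gene_sets named list of accession vectors, e.g. from
#'   [loadGeneSets()].
#' @param n_permutations random same-size sets per distinct set size.
#' @param seed optional integer seed.
#' @param weight_exponent hit-weighting exponent (default 1).
#' @return data.frame with one row per evaluated set, ordered by p-value.
#' @export
runGsea <- function(ranked, gene_sets, n_permutations = 1000, seed = NULL,
                    weight_exponent = 1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  scores <- if (is.data.frame(ranked)) setNames(ranked$score, ranked$accession) else ranked
  n <- length(scores)
  members <- lapply(gene_sets, function(s) which(names(scores) %in% s))
  sizes <- lengths(members)
  usable <- sizes > 0L & sizes < n
  if (any(!usable))
    .msg("skipping ", sum(!usable), " gene set(s) with empty or full overlap")
  members <- members[usable]
  ids <- names(gene_sets)[usable]
  sizes <- sizes[usable]
  if (!length(members))
    return(data.frame(set_id = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(),
                      direction = character(), n_same_sign = integer()))
  null_by_size <- lapply(sort(unique(sizes)), function(sz) {
    vapply(seq_len(n_permutations), function(i) {
      hit <- logical(n)
      hit[sample.int(n, sz)] <- TRUE
      .es_core(scores, hit, weight_exponent)$es
    }, numeric(1))
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))
  rows <- lapply(seq_along(members), function(i) {
    hit <- logical(n)
    hit[members[[i]]] <- TRUE
    es <- .es_core(scores, hit, weight_exponent)$es
    same <- null_by_size[[as.character(sizes[i])]]
    same <- same[sign(same) == sign(es)]
    if (length(same) == 0L) {
      nes <- NA_real_
      p <- 1 / (n_permutations + 1)
    } else {
      nes <- es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    }
    data.frame(set_id = ids[i], size = sizes[i], es = es, nes = nes,
               p_value = p,
               direction = if (es >= 0) "coculture_enriched" else "pure_enriched",
               n_same_sign = length(same), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load gene sets from annotations, GMT or two-column TSV
#'
#' Builds gene sets either by grouping an annotation table (arCOG
#' single-letter functional classes, or operon identifiers — operons are
#' consumed as given, treated as sets of adjacent co-transcribed genes) or
#' by parsing a GMT file (`set_id <TAB> description <TAB> members...`) or a
#' two-column TSV (`accession <TAB> set_id`). Singleton sets are dropped
#' with a message since a one-gene set cannot be tested for enrichment.
#'
#' @param x annotation data.frame (see [readAnnotations()]) or a file path
#'   ending in `.gmt` or `.tsv`.
#' @param kind `"arcog_class"`, `"operon"` or `"custom"`; for annotation
#'   input, selects the grouping column.
#' @return named list of accession vectors, with attribute `kind`.
#' @export
loadGeneSets <- function(x, kind = c("arcog_class", "operon", "custom")) {
  kind <- match.arg(kind)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) .stop("gene-set file not found: ", x)
    if (grepl("\\.gmt$", x, ignore.case = TRUE)) {
      lines <- readLines(x)
      nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
      bad <- which(nzchar(lines) & nf < 3L)
      if (length(bad))
        .stop("malformed GMT line ", bad[1L], " in ", x,
              " (need set_id, description, >=1 member)")
      if (requireNamespace("fgsea", quietly = TRUE)) {
        sets <- fgsea::gmtPathways(x)
      } else {
        fields <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
        sets <- setNames(lapply(fields, function(f) f[-(1:2)]),
                         vapply(fields, `[`, "", 1L))
      }
    } else {
      tab <- as.data.frame(fread(x, sep = "\t", header = TRUE, showProgress = FALSE))
      if (ncol(tab) < 2L) .stop("two-column TSV expected in ", x)
      sets <- split(as.character(tab[[1L]]), as.character(tab[[2L]]))
    }
  } else if (is.data.frame(x)) {
    col <- switch(kind, arcog_class = "arcog_class", operon = "operon_id",
                  custom = .stop("kind='custom' needs a file path"))
    keep <- !is.na(x[[col]]) & nzchar(x[[col]])
    sets <- split(x$accession[keep], x[[col]][keep])
  } else .stop("x must be an annotation data.frame or a file path")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  singleton <- lengths(sets) < 2L
  if (any(singleton))
    .msg("dropping ", sum(singleton), " singleton gene set(s)")
  sets <- sets[!singleton]
  attr(sets, "kind") <- kind
  sets
}
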