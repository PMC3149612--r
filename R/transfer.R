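#' Interspecies-transfer enrichment factor
#'
#' For a host protein detected in a purified symbiont sample, the
#' enrichment factor compares the protein's abundance relative to the total
#' host proteome between the purified sample and the co-culture:
#' `phi = (p_n / t_n) / (p_in / t_in)`, where `p_n`/`t_n` are the protein
#' and total host counts in the purified sample and `p_in`/`t_in` the same
#' in the co-culture. `phi` near 1 is what plain carry-over contamination
#' produces; `phi > 2` flags candidate transfer. A protein absent from the
#' co-culture (`p_in = 0`) returns `Inf`, a sentinel excluded from
#' rankings. `phi` is invariant to any common rescaling of either sample's
#' counts.
#'
#' @param p_n,p_in protein counts in the purified sample and co-culture.
#' @param t_n,t_in total host-proteome counts in the two samples (> 0).
#' @return numeric vector of enrichment factors (full precision; published
#'   values are conventionally reported to one decimal).
#' @examples
#' enrichmentFactor(190, 11878, 133, 75139)  # ~9.0
#' @export
enrichmentFactor <- function(p_n, t_n, p_in, t_in) {
  if (any(t_n <= 0) || any(t_in <= 0))
    .stop("total proteome counts must be positive")
  if (any(p_n < 0) || any(p_in < 0)) .stop("protein counts must be non-negative")
  ifelse(p_in == 0, Inf, (p_n / t_n) / (p_in / t_in))
}

#' Screen host proteins for enrichment in the purified symbiont sample
#'
#' Computes per-protein enrichment factors for all host proteins detected
#' in the purified symbiont sample, using host-proteome totals summed over
#' all detected host proteins in each sample ("relative to the total host
#' proteome"), and applies the screen `phi > phi_min` and purified-sample
#' abundance `>= min_rspc` (low counts make `phi` statistically
#' unreliable). Candidates are sorted by decreasing finite `phi`;
#' infinite-`phi` sentinels (absent from the co-culture) are appended
#' unranked at the end.
#'
#' @param x a \linkS4class{SpectralCountExperiment} with the layer present.
#' @param phi_min screen threshold on `phi` (default 2, strict).
#' @param min_rspc abundance floor on the purified-sample value
#'   (default 20).
#' @param layer assay to use (default `"RSpC"`).
#' @param organism host organism label (default `"host"`).
#' @param purified_condition,coculture_condition condition labels.
#' @param require_both also require the co-culture value `>= min_rspc`.
#' @return data.frame with one row per candidate: `accession`, `p_in`,
#'   `p_n`, `t_in`, `t_n`, `phi`, `passes_screen`, plus annotation
#'   columns (`arcog_id`, `arcog_class`, `has_tmd`, `has_signal_peptide`,
#'   `length_aa`).
#' @export
screenCandidates <- function(x, phi_min = 2, min_rspc = 20, layer = "RSpC",
                             organism = "host",
                             purified_condition = "purified_symbiont",
                             coculture_condition = "coculture",
                             require_both = FALSE) {
  p_n_all <- summarizeCondition(x, purified_condition, layer)
  p_in_all <- summarizeCondition(x, coculture_condition, layer)
  org <- proteinOrganism(x) == organism
  t_n <- sum(p_n_all[org])
  t_in <- sum(p_in_all[org])
  cand <- org & p_n_all > 0
  if (!any(cand)) {
    .msg("no ", organism, " proteins detected in ", purified_condition)
    return(data.frame(accession = character(), p_in = numeric(),
                      p_n = numeric(), t_in = numeric(), t_n = numeric(),
                      phi = numeric(), passes_screen = logical()))
  }
  acc <- rownames(x)[cand]
  p_n <- p_n_all[acc]; p_in <- p_in_all[acc]
  phi <- enrichmentFactor(p_n, t_n, p_in, t_in)
  passes <- phi > phi_min & p_n >= min_rspc
  if (require_both) passes <- passes & p_in >= min_rspc
  rd <- as.data.frame(rowData(x)[acc,
    c("arcog_id", "arcog_class", "has_tmd", "has_signal_peptide", "length_aa"),
    drop = FALSE])
  out <- data.frame(
    accession = acc, p_in = unname(p_in), p_n = unname(p_n),
    t_in = t_in, t_n = t_n, phi = unname(phi),
    passes_screen = unname(passes), rd,
    stringsAsFactors = FALSE, row.names = NULL
  )
  finite <- is.finite(out$phi)
  out <- rbind(
    out[finite, ][order(-out$phi[finite], out$accession[finite]), ],
    out[!finite, ][order(out$accession[!finite]), ]
  )
  rownames(out) <- NULL
  out
}
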