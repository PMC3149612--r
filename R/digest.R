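#' In-silico tryptic digestion
#'
#' Cleaves an amino-acid sequence C-terminally to lysine (K) or arginine (R)
#' except when the following residue is proline, the standard trypsin rule.
#' Peptides spanning up to `missed_cleavages` internal cleavage sites are
#' also produced; peptides outside the `[min_len, max_len]` length window
#' are removed. The window stands in for MS detectability criteria
#' (very short and very long tryptic peptides escape identification).
#'
#' @param sequence single uppercase amino-acid string (20 standard residues).
#' @param missed_cleavages maximum number of internal missed cleavage sites
#'   (default 2).
#' @param min_len,max_len inclusive peptide length bounds (defaults 6 and
#'   50 residues).
#' @return data.frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive coordinates on the input sequence) and `missed` (number of
#'   internal missed cleavages).
#' @examples
#' digestTryptic("AAKGG", missed_cleavages = 0, min_len = 1, max_len = Inf)
#' digestTryptic("AKPG", missed_cleavages = 0, min_len = 1, max_len = Inf)
#' @export
digestTryptic <- function(sequence, missed_cleavages = 2, min_len = 6,
                          max_len = 50) {
  .check_sequence(sequence)
  if (missed_cleavages < 0) .stop("missed_cleavages must be >= 0")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # cleavage after position i: residue i is K/R and residue i+1 is not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  # fully cleaved fragment boundaries
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  out <- vector("list", missed_cleavages + 1L)
  for (mc in 0:missed_cleavages) {
    i <- seq_len(max(nfrag - mc, 0L))
    if (!length(i)) break
    s <- starts[i]
    e <- ends[i + mc]
    keep <- (e - s + 1L) >= min_len & (e - s + 1L) <= max_len
    out[[mc + 1L]] <- data.frame(
      peptide = substring(sequence, s[keep], e[keep]),
      start = s[keep], end = e[keep], missed = rep.int(mc, sum(keep)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer())
  res[order(res$start, res$end), , drop = FALSE]
}
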