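# internal helpers

.msg <- function(...) {
  if (!isTRUE(getOption("NSAFquant.quiet", FALSE)))
    message("[NSAFquant] ", ...)
}

.stop <- function(...) stop(..., call. = FALSE)

# amino-acid alphabet used throughout
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    .stop("sequence must be a single non-empty amino-acid string")
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), .AA20)
  if (length(bad))
    .stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
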