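write_psm_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("run_id\tpeptide\tcharge\txcorr\tdeltacn\taccessions\tdecoy",
               lines), path)
  path
}

test_that("a well-formed table reads one record per row", {
  p <- write_psm_tsv(c(
    "r1\tELVISK\t2\t3.1\t0.15\tP1\t0",
    "r1\tPEPTIDER\t3\t3.9\t0.30\tP1;P2\t0",
    "r2\tAAAGGGK\t1\t2.0\t0.12\tP3\t0"
  ))
  psms <- readPsmTable(p)
  expect_equal(nrow(psms), 3L)
  expect_equal(attr(psms, "n_rejected"), 0L)
  expect_equal(psms$accessions[2], "P1;P2")
  expect_false(any(psms$is_decoy))
})

test_that("rows with unparseable mandatory fields are rejected and counted", {
  p <- write_psm_tsv(c(
    "r1\tELVISK\t2\t3.1\t0.15\tP1\t0",
    "r1\tPEPTIDER\t\t3.9\t0.30\tP1\t0",   # missing charge
    "r2\tAAAGGGK\t1\t2.0\t0.12\tP3\t0"
  ))
  withr::with_options(list(NSAFquant.quiet = FALSE),
    expect_message(psms <- readPsmTable(p), "rejected"))
  expect_equal(nrow(psms), 2L)
  expect_equal(attr(psms, "n_rejected"), 1L)
})

test_that("missing file, missing column and empty table raise typed errors", {
  expect_error(readPsmTable(tempfile()), "not found")
  p <- tempfile(fileext = ".tsv")
  writeLines(c("run_id\tpeptide\tcharge", "r1\tAAK\t2"), p)
  expect_error(readPsmTable(p), "mandatory column")
})

test_that("mixed target/decoy accession sets become target matches", {
  p <- write_psm_tsv(c(
    "r1\tELVISK\t2\t3.1\t0.15\tP1;Reverse_P2\t1",
    "r1\tAAAGGGK\t2\t3.1\t0.15\tReverse_P2\t1"
  ))
  psms <- suppressMessages(readPsmTable(p))
  expect_equal(psms$is_decoy, c(FALSE, TRUE))
})

test_that("synthetic PSM tables round-trip losslessly", {
  fx <- small_synthetic()
  sub <- fx$sim$psms[fx$sim$psms$run_id == fx$sim$run_info$run_id[1], ]
  path <- tempfile(fileext = ".tsv")
  writePsmTable(sub, path)
  back <- readPsmTable(path)
  rownames(sub) <- NULL
  attr(back, "n_rejected") <- NULL
  expect_equal(back, sub, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("score filtering honors per-charge XCorr and DeltaCn thresholds", {
  t <- filterThresholds()
  # charge-2 PSM below the 2.5 XCorr threshold is removed
  expect_equal(nrow(filterPsms(make_psms("ELVISK", "P1", charge = 2,
                                         xcorr = 2.4, deltacn = 0.10), t)), 0L)
  # empty input passes through
  empty <- make_psms(character(0), character(0))
  expect_equal(nrow(filterPsms(empty, t)), 0L)
  # charges above 3 reuse the charge-3 threshold
  four <- make_psms(c("AAK", "GGK"), "P1", charge = 4L, xcorr = c(3.4, 3.6),
                    deltacn = 0.2)
  expect_equal(filterPsms(four, t)$xcorr, 3.6)
})

test_that("filtering matches an exhaustive per-record check and is idempotent", {
  set.seed(7)
  n <- 100
  psms <- make_psms(rep("ELVISK", n), "P1",
                    charge = sample(1:4, n, TRUE),
                    xcorr = runif(n, 0, 5), deltacn = runif(n, 0, 0.4))
  t <- filterThresholds()
  got <- filterPsms(psms, t)
  thr <- c(1.8, 2.5, 3.5, 3.5)  # charge 4 -> charge-3 threshold
  keep <- sapply(seq_len(n), function(i)
    psms$xcorr[i] >= thr[psms$charge[i]] && psms$deltacn[i] >= 0.08)
  expect_equal(nrow(got), sum(keep))
  expect_equal(got$xcorr, psms$xcorr[keep])  # order preserved
  expect_identical(filterPsms(got, t), got)
})

test_that("target-decoy FDR follows 2D/(T+D) with cap and zero cases", {
  expect_equal(estimateFdr(rep(FALSE, 50)), 0)
  expect_equal(estimateFdr(c(rep(FALSE, 98), rep(TRUE, 2))), 0.04)
  expect_equal(estimateFdr(rep(c(TRUE, FALSE), 10)), 1)  # D = T, capped
  expect_equal(estimateFdr(c(rep(FALSE, 98), rep(TRUE, 2)), formula = "simple"),
               2 / 98)
  expect_error(estimateFdr(logical(0)), "empty")
  # monotone non-decreasing in D at fixed T
  fdrs <- sapply(0:20, function(D) estimateFdr(c(rep(FALSE, 50), rep(TRUE, D))))
  expect_true(all(diff(fdrs) >= 0))
})

test_that("two-peptide/one-unique assembly retains and drops correctly", {
  db <- make_db(c("A", "B"))
  # A: unique p1 (3 spectra) + shared p2 -> retained
  # B: only the shared peptide -> dropped (one peptide, none unique)
  psms <- make_psms(c("PEPTIDEA", "PEPTIDEA", "PEPTIDEA", "SHAREDPEP"),
                    c("A", "A", "A", "A;B"))
  ev <- suppressMessages(assembleProteins(psms, db))
  tab <- attr(ev, "protein_table")
  expect_setequal(tab$accession, "A")
  # after B drops, the shared peptide becomes unique to A on the re-pass
  expect_true(all(ev$is_unique))
})

test_that("a protein with a single unique peptide only is dropped", {
  db <- make_db("A")
  psms <- make_psms(c("PEPTIDEA", "PEPTIDEA"), c("A", "A"))
  ev <- suppressMessages(assembleProteins(psms, db))
  expect_equal(nrow(attr(ev, "protein_table")), 0L)
})

test_that("unknown accessions raise a typed error naming them", {
  db <- make_db("A")
  psms <- make_psms("PEPTIDEA", "GHOST")
  expect_error(assembleProteins(psms, db), "GHOST")
})

# independent brute-force assembly: same two-pass semantics, coded from the
# raw peptide/protein incidence structure without the package's data.table path
assembly_oracle <- function(psms, thresholds = filterThresholds()) {
  acc_of <- lapply(strsplit(psms$accessions, ";"), unique)
  peps <- unique(psms$peptide)
  pep_set <- lapply(peps, function(p)
    unique(unlist(acc_of[psms$peptide == p])))
  names(pep_set) <- peps
  pep_n <- table(psms$peptide)
  pass <- function(retained) {
    keep <- character()
    for (a in retained) {
      mine <- peps[vapply(pep_set, function(s) a %in% s, TRUE)]
      mine <- mine[vapply(pep_set[mine],
                          function(s) length(intersect(s, retained)) > 0, TRUE)]
      n_u <- sum(vapply(pep_set[mine], function(s)
        length(intersect(s, retained)) == 1, TRUE))
      spc <- sum(pep_n[mine])
      if (length(mine) >= thresholds@min_peptides_per_protein &&
          n_u >= thresholds@min_unique_peptides &&
          spc >= thresholds@min_spectra) keep <- c(keep, a)
    }
    keep
  }
  all_acc <- unique(unlist(acc_of))
  pass(pass(all_acc))
}

test_that("assembly agrees with a brute-force oracle on random instances", {
  set.seed(13)
  for (rep_i in 1:10) {
    prots <- sprintf("P%02d", 1:10)
    peps <- sprintf("%sK", sapply(1:30, function(i)
      paste(sample(c("A","G","L","S","V","T","N","E"), 7, TRUE), collapse = "")))
    owners <- lapply(seq_along(peps), function(i)
      sample(prots, sample(c(1, 1, 1, 2, 3), 1)))
    idx <- sample(seq_along(peps), 60, replace = TRUE)
    psms <- make_psms(peps[idx],
                      vapply(owners[idx], function(o) paste(sort(o), collapse = ";"), ""))
    db <- make_db(prots)
    ev <- suppressMessages(assembleProteins(psms, db))
    got <- sort(attr(ev, "protein_table")$accession)
    expect_identical(got, sort(assembly_oracle(psms)))
    # invariant: unique-peptide floor holds for every retained protein
    tab <- attr(ev, "protein_table")
    if (nrow(tab)) expect_true(all(tab$n_unique >= 1))
  }
})
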