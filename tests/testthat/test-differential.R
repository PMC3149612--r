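test_that("condition sums aggregate replicate runs", {
  counts <- cbind(r1 = c(3, 1), r2 = c(4, 1), r3 = c(5, 1), s1 = c(2, 2))
  x <- sce_from_matrix(counts, c("coculture", "coculture", "coculture",
                                 "pure_host"))
  x <- set_layer(x, "RSpC", counts)
  expect_equal(unname(summarizeCondition(x, "coculture")[1]), 12)
  expect_equal(unname(summarizeCondition(x, "pure_host")[1]), 2)
  expect_error(summarizeCondition(x, "nope"), "unknown condition")
  # independent column-sum oracle on the shared synthetic fixture
  y <- small_sce()
  runs <- conditionRuns(y, "coculture")
  expect_equal(summarizeCondition(y, "coculture"),
               rowSums(assay(y, "RSpC")[, runs]))
})

test_that("fold ratios reproduce printed worked examples and sentinels", {
  expect_equal(foldRatio(4106, 2119)$display, "1.9")
  expect_equal(foldRatio(1836, 774)$display, "2.4")
  expect_equal(foldRatio(1618, 314, digits = 0)$display, "5")
  expect_equal(foldRatio(152, 430, digits = 2)$display, "0.35")
  expect_equal(foldRatio(77, 0)$display, ">50")
  expect_equal(foldRatio(77, 0)$value, Inf)
  expect_equal(foldRatio(123, 123)$value, 1.0)
  expect_equal(foldRatio(0, 50)$value, 0)
  expect_error(foldRatio(0, 0), "0/0")
  expect_error(foldRatio(-1, 5), "non-negative")
})

test_that("fold classification is symmetric with direction flips", {
  expect_equal(classifyChange(5), data.frame(fold_class = "ge3", direction = "up"))
  expect_equal(classifyChange(1.0),
               data.frame(fold_class = "lt1p5", direction = "unchanged"))
  expect_equal(classifyChange(0.4),
               data.frame(fold_class = "two_to_three", direction = "down"))
  expect_equal(classifyChange(Inf)$fold_class, "ge3")
  expect_equal(classifyChange(Inf)$direction, "up")
  expect_equal(classifyChange(0)$direction, "down")
  # property: r and 1/r share the class with opposite direction
  set.seed(31)
  r <- exp(runif(200, log(0.05), log(20)))
  a <- classifyChange(r); b <- classifyChange(1 / r)
  expect_equal(a$fold_class, b$fold_class)
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(flip[a$direction]), b$direction)
  # band edges: exactly 2-fold sits in the 2-3 band, 3-fold in >=3
  expect_equal(classifyChange(2)$fold_class, "two_to_three")
  expect_equal(classifyChange(3)$fold_class, "ge3")
})

test_that("log2 t-test matches stats::t.test and handles edge cases", {
  # identical groups: t = 0, p = 1
  expect_equal(ttestLog2(c(1, 2, 3), y = c(1, 2, 3)), 1)
  expect_equal(ttestLog2(c(2, 4, 8), y = c(2, 4, 8)), 1)
  # clear two-fold shift with tiny jitter is significant
  a <- c(4, 4, 4) + c(1e-6, -1e-6, 0)
  b <- c(8, 8, 8) + c(1e-6, -1e-6, 0)
  expect_lt(ttestLog2(a, y = b), 0.05)
  # exact agreement with the reference implementation on random instances
  set.seed(37)
  for (i in 1:25) {
    x <- rlnorm(3, 5, 0.3); y <- rlnorm(3, 5.5, 0.3)
    expect_equal(ttestLog2(x, y = y),
                 t.test(log2(x), log2(y), var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(ttestLog2(x, y = y, var_equal = FALSE),
                 t.test(log2(x), log2(y))$p.value, tolerance = 1e-12)
    # symmetry under swapping conditions
    expect_equal(ttestLog2(x, y = y), ttestLog2(y, y = x), tolerance = 1e-12)
  }
  # zero in any replicate: not testable, NA rather than an error
  expect_true(is.na(ttestLog2(c(0, 4, 4), y = c(8, 8, 8))))
})

test_that("the experiment method tests a named protein between conditions", {
  counts <- cbind(a1 = c(4, 1), a2 = c(4.2, 1), a3 = c(3.9, 1),
                  b1 = c(8, 1), b2 = c(8.1, 1), b3 = c(7.8, 1))
  x <- sce_from_matrix(counts, rep(c("pure_host", "coculture"), each = 3))
  x <- set_layer(x, "RSpC", counts)
  p <- ttestLog2(x, accession = "P0001", condition_a = "pure_host",
                 condition_b = "coculture")
  expect_lt(p, 0.05)
  expect_error(ttestLog2(x, accession = "nope", condition_a = "pure_host",
                         condition_b = "coculture"), "unknown accession")
})

test_that("differential table covers detected proteins with censoring intact", {
  counts <- cbind(a1 = c(6, 0, 5), a2 = c(6, 0, 5), a3 = c(6, 0, 5),
                  b1 = c(6, 4, 0), b2 = c(6, 4, 0), b3 = c(6, 4, 0))
  rownames(counts) <- c("P1", "P2", "P3")
  x <- sce_from_matrix(counts, rep(c("pure_host", "coculture"), each = 3))
  x <- set_layer(x, "RSpC", counts)
  d <- differentialTable(x)
  expect_equal(nrow(d), 3L)  # one row per detected protein
  expect_setequal(d$detection, c("both", "target_only", "reference_only"))
  expect_equal(d$ratio_display[d$accession == "P2"], ">50")
  expect_equal(d$ratio[d$accession == "P3"], 0)
  expect_equal(d$fold_class[d$accession == "P1"], "lt1p5")
  expect_equal(d$direction[d$accession == "P1"], "unchanged")
  # censored rows sort before finite ones
  expect_setequal(d$accession[1:2], c("P2", "P3"))
})

test_that("a single unchanged protein yields one unchanged row", {
  counts <- matrix(7, 1, 6,
                   dimnames = list("P1", paste0("r", 1:6)))
  x <- sce_from_matrix(counts, rep(c("pure_host", "coculture"), each = 3))
  x <- set_layer(x, "RSpC", counts)
  d <- differentialTable(x)
  expect_equal(nrow(d), 1L)
  expect_equal(d$ratio, 1)
  expect_equal(d$direction, "unchanged")
  expect_equal(d$p_value, 1)
})

test_that("planted 2.5-fold effects are recovered as >= 2-fold calls", {
  # multinomial spectral sampling over 1000 proteins, 10% with true 2.5x
  set.seed(43)
  n <- 1000
  ab <- rlnorm(n, 0, 1.5)
  eff <- sort(sample.int(n, 100))
  up <- eff[seq_len(50)]; down <- setdiff(eff, up)
  w_ref <- ab / sum(ab)
  ab_t <- ab; ab_t[up] <- ab_t[up] * 2.5; ab_t[down] <- ab_t[down] / 2.5
  w_tgt <- ab_t / sum(ab_t)
  counts <- cbind(
    sapply(1:3, function(i) rmultinom(1, 46541, w_ref)[, 1]),
    sapply(1:3, function(i) rmultinom(1, 46541, w_tgt)[, 1])
  )
  dimnames(counts) <- list(sprintf("P%04d", seq_len(n)), paste0("r", 1:6))
  x <- sce_from_matrix(counts, rep(c("pure_host", "coculture"), each = 3),
                       lengths = rep(100, n))
  x <- renormalizeRSpC(scaleNSpC(computeNSAF(x)))
  d <- differentialTable(x)
  # evaluate on effect proteins above the quantification floor in both states
  expected <- 46541 * pmin(w_ref, w_tgt)
  ok_eff <- rownames(counts)[eff][expected[eff] >= 20]
  called <- d$accession[d$fold_class %in% c("two_to_three", "ge3")]
  expect_gte(mean(ok_eff %in% called), 0.8)
})

test_that("null data keep the significant fraction near the nominal level", {
  set.seed(47)
  n <- 800
  counts <- matrix(rpois(n * 6, 100), n, 6)
  x <- sce_from_matrix(counts, rep(c("pure_host", "coculture"), each = 3))
  x <- set_layer(x, "RSpC", counts)  # raw counts as abundance
  d <- differentialTable(x)
  frac <- mean(d$p_value <= 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02); expect_lt(frac, 0.08)
})
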