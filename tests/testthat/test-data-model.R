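test_that("expression TSV round-trips and rejects malformed input", {
  m <- toy_expression()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path, reference_ids = c("R1", "R2"))
  expect_identical(dim(back), c(3L, 5L))
  expect_equal(back$values, m$values)
  expect_equal(back$is_reference, m$is_reference)

  # duplicate sample column
  lines <- readLines(path)
  lines[1] <- "gene_id\tR1\tR1\tT1\tT2\tT3"
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, dup)
  expect_error(read_expression(dup), "duplicate sample")

  # non-numeric body cell
  lines2 <- readLines(path)
  lines2[2] <- sub("^GA\t1", "GA\tabc", lines2[2])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines2, bad)
  expect_error(read_expression(bad), "non-numeric")

  expect_error(read_expression(path, reference_ids = "R9"), "not found")
})

test_that("z-scoring matches hand arithmetic and drops the reference panel", {
  vals <- matrix(c(1, 2, 3, 4, 2,
                   5, 5, 5, 9, 5),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("GA", "GB"),
                                 c("R1", "R2", "R3", "T1", "T2")))
  m <- expression_matrix(vals, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(zscore_vs_reference(m), "zero reference standard deviation.*GB")

  vals["GB", "R2"] <- 7
  m <- expression_matrix(vals, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  z <- zscore_vs_reference(m)
  # GA reference {1,2,3}: mean 2, sd 1 -> tumor 4 maps to z = 2, tumor 2 to 0
  expect_equal(unname(z$values["GA", ]), c(2, 0))
  expect_identical(colnames(z$values), c("T1", "T2"))
  expect_false(any(z$is_reference))

  one_ref <- expression_matrix(vals, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(zscore_vs_reference(one_ref), "at least 2 reference")
})

test_that("alteration calls use a strict |z| > threshold boundary", {
  z <- matrix(c(2, -2.5, 1.99, -2, 2.0001, 0),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("GA", "GB"), c("S1", "S2", "S3")))
  a <- call_alterations(expression_matrix(z))
  expect_identical(as.vector(a$calls), c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_error(call_alterations(expression_matrix(z), threshold = 0),
               "positive")
  expect_error(call_alterations(expression_matrix(z), threshold = -1),
               "positive")
})

test_that("z-score + alteration pipeline is invariant to per-gene affine transforms", {
  withr::with_seed(11, {
    vals <- matrix(rnorm(6 * 40), nrow = 6,
                   dimnames = list(paste0("G", 1:6), paste0("S", 1:40)))
  })
  is_ref <- c(rep(TRUE, 15), rep(FALSE, 25))
  base <- call_alterations(zscore_vs_reference(expression_matrix(vals, is_ref)))
  shifted <- vals
  shifted[3, ] <- 7.5 * shifted[3, ] - 2.2
  trans <- call_alterations(zscore_vs_reference(expression_matrix(shifted, is_ref)))
  expect_equal(base$calls, trans$calls)
})

test_that("pure-noise tumors are called altered at about the two-sided 2-sigma rate", {
  withr::with_seed(42, {
    n_ref <- 400; n_tum <- 500; genes <- 20
    vals <- matrix(rnorm(genes * (n_ref + n_tum)), nrow = genes,
                   dimnames = list(paste0("G", 1:genes),
                                   paste0("S", 1:(n_ref + n_tum))))
  })
  a <- call_alterations(zscore_vs_reference(
    expression_matrix(vals, c(rep(TRUE, n_ref), rep(FALSE, n_tum)))))
  n_calls <- length(a$calls)
  rate <- mean(a$calls)
  expected <- 2 * pnorm(-2)
  se <- sqrt(expected * (1 - expected) / n_calls)
  expect_lt(abs(rate - expected), 3 * se + 0.002)  # small slack for sd estimation
})

test_that("signature status is the any-gene-altered rule and is monotone", {
  calls <- matrix(c(0L, 1L, 0L,
                    0L, 0L, 0L,
                    0L, 0L, 1L),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("GA", "GB", "GC"), c("S1", "S2", "S3")))
  a <- structure(list(calls = calls, threshold = 2), class = "AlterationMatrix")
  expect_identical(unname(signature_status(a, gene_signature(c("GA", "GB")))),
                   c(0L, 1L, 0L))
  expect_error(signature_status(a, gene_signature("GX")), "not in alteration")
  expect_error(gene_signature(character(0)), "at least one gene")
  expect_error(gene_signature(c("GA", "GA")), "duplicate")

  # monotone: adding genes never flips a 1 to 0
  withr::with_seed(7, {
    big <- matrix(rbinom(8 * 30, 1, 0.2), nrow = 8,
                  dimnames = list(paste0("G", 1:8), paste0("S", 1:30)))
  })
  storage.mode(big) <- "integer"
  ab <- structure(list(calls = big, threshold = 2), class = "AlterationMatrix")
  genes <- rownames(big)
  for (k in 2:8) {
    before <- signature_status(ab, gene_signature(genes[seq_len(k - 1)]))
    after <- signature_status(ab, gene_signature(genes[seq_len(k)]))
    expect_true(all(after >= before))
  }
})

test_that("GMT parsing preserves order, deduplicates, and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tother\tC\tA\tC"), path)
  coll <- read_gmt(path)
  expect_length(coll, 2L)
  expect_identical(coll$sets[[1]]$genes, c("A", "B"))
  expect_identical(coll$sets[[2]]$genes, c("C", "A"))  # duplicate C collapsed

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc", bad)
  expect_error(read_gmt(bad), "need name, description")
  dupnames <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\td\tA", "S1\td\tB"), dupnames)
  expect_error(read_gmt(dupnames), "duplicate set names")
})

test_that("clinical table validation enforces the schema", {
  expect_error(clinical_table(data.frame(sample_id = "a", time_months = -1,
                                         event = 1)), "non-negative")
  expect_error(clinical_table(data.frame(sample_id = "a", time_months = 1,
                                         event = 2)), "0 or 1")
  expect_error(clinical_table(data.frame(sample_id = c("a", "a"),
                                         time_months = c(1, 2),
                                         event = c(0, 1))), "duplicate")
  ok <- clinical_table(data.frame(sample_id = c("a", "b"),
                                  time_months = c(1, 2), event = c(0, 1)))
  expect_s3_class(ok, "ClinicalTable")
})

test_that("the packaged ET-9 fixture holds the nine signature genes", {
  sig <- et9_signature()
  expect_s3_class(sig, "GeneSignature")
  expect_length(sig, 9L)
  expect_true(all(c("SUSD2", "ADGRG1") %in% sig$genes))
})
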