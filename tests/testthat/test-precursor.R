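test_that("signal-peptide heuristic applies the h-region and (-3,-1) rules", {
  sp <- predict_signal_peptide("MKTLLVLAVLALASAQDFFRS")
  expect_equal(sp$end, 15L)
  expect_equal(sp$source, "heuristic")
  # no h-region: rule cannot fire
  expect_null(predict_signal_peptide(
    paste0("MDDDEDDKRS", strrep("D", 30))))
  expect_error(predict_signal_peptide("KTLLVLAVLALASAQ"), "starting with M")
})

test_that("annotation mode returns the supplied span verbatim", {
  sp <- predict_signal_peptide("MDDDEDDKRSDDDDDDDDDDDDDD", "annotation",
                               span = c(0, 22))
  expect_equal(sp$end, 22L)
  expect_equal(sp$source, "annotation")
  expect_error(predict_signal_peptide("MAAA", "annotation", span = c(1, 5)),
               "start at 0")
})

test_that("completeness classification matches the hand-enumerated truth table", {
  # independently enumerated from the class definitions:
  # columns upstream_stop, start_met, terminal_stop, has_signal -> class
  truth <- list(
    list(T, T, T, T, "F", FALSE), list(F, T, T, T, "F", TRUE),
    list(T, T, F, T, "N", FALSE), list(F, T, F, T, "N", FALSE),
    list(T, F, T, T, "I", FALSE), list(F, F, T, T, "C", FALSE),
    list(T, F, F, T, "I", FALSE), list(F, F, F, T, "I", FALSE),
    list(T, T, T, F, "I", FALSE), list(F, T, T, F, "C", FALSE),
    list(T, T, F, F, "I", FALSE), list(F, T, F, F, "I", FALSE),
    list(T, F, T, F, "I", FALSE), list(F, F, T, F, "C", FALSE),
    list(T, F, F, F, "I", FALSE), list(F, F, F, F, "I", FALSE))
  got <- vapply(truth, function(row)
    classify_completeness(row[[1]], row[[2]], row[[3]], row[[4]])$class, "")
  expect_equal(got, vapply(truth, `[[`, "", 5))
  putative <- vapply(truth, function(row)
    classify_completeness(row[[1]], row[[2]], row[[3]], row[[4]])$putative_full,
    NA)
  expect_equal(putative, vapply(truth, `[[`, NA, 6))
  # classification is exhaustive and mutually exclusive by construction:
  # every combination yields exactly one class
  expect_true(all(got %in% c("F", "N", "C", "I")))
})

test_that("build_precursor trims to the start Met and attaches completeness", {
  orf <- list(protein = "AAMAAKRDDEDDEDDEDDEDDEDDEDDEDDEDDEDD",
              upstream_stop = TRUE, terminal_stop = TRUE)
  prec <- build_precursor(orf, "p1", signal_mode = "annotation",
                          signal_span = c(0, 10), min_len = 10)
  expect_s3_class(prec, "precursor")
  expect_true(startsWith(prec$protein, "M"))
  expect_equal(prec$completeness, "F")
  # too short after trimming
  expect_null(build_precursor(list(protein = "AAMAA", upstream_stop = TRUE,
                                   terminal_stop = TRUE), "p2",
                              min_len = 10))
})

test_that("candidate ORF selection prefers the mining hit over raw length", {
  orfs <- data.frame(transcript_id = "t", frame = c(1L, -2L),
                     aa_start = c(0L, 0L), aa_end = c(50L, 80L),
                     protein = c(strrep("A", 50), strrep("G", 80)),
                     upstream_stop = TRUE, start_met = FALSE,
                     terminal_stop = TRUE, stringsAsFactors = FALSE)
  # without a hit: longest
  expect_equal(select_orf(orfs)$frame, -2L)
  # with a hit in frame +1: the overlapping ORF wins
  hit <- list(frame = 1L, s_start = 10L, s_end = 40L)
  expect_equal(select_orf(orfs, hit)$frame, 1L)
  expect_null(select_orf(orfs[0, ]))
})

test_that("annotation sidecar files parse names, signal ends and loci", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "prepro-x\t22\t30,41,55", "prepro-y\t0\t"), tmp)
  ann <- read_annotations(tmp)
  expect_equal(ann[["prepro-x"]]$signal_end, 22L)
  expect_equal(ann[["prepro-x"]]$cleavage_pos, c(30L, 41L, 55L))
  expect_equal(ann[["prepro-y"]]$cleavage_pos, integer(0))
})
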