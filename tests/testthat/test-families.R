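lib <- read_motif_library(fixture_path("family_motifs.tsv"))
ftpl <- read_family_templates(fixture_path("family_templates.tsv"))

test_that("C-terminal family motifs recognize canonical members", {
  expect_equal(classify_peptide(parse_peptide("HSNYGFGLa"), lib)$family,
               "AST-A")
  expect_equal(classify_peptide(parse_peptide("GDGFAFSPRLa"), lib)$family,
               "pyrokinin")
  expect_equal(classify_peptide(parse_peptide("NRNFLRFa"), lib)$family,
               "FLRFamide")
  # ...GHLRFamide is sulfakinin, not FLRFamide
  expect_equal(classify_peptide(parse_peptide("GGGEYDDYGHLRFa"), lib)$family,
               "sulfakinin")
  # the myosuppressin full-sequence motif outranks the FLRFamide suffix
  expect_equal(classify_peptide(parse_peptide("pQDLDHVFLRFa"), lib)$family,
               "myosuppressin")
  # amidation is required: the free-acid form does not match
  expect_equal(classify_peptide(parse_peptide("NRNFLRF"), lib)$family,
               "linker")
  expect_equal(classify_peptide(parse_peptide("SSPDMEKRLLE"), lib)$family,
               "linker")
})

test_that("truncated peptides match on the intact end with min_match residues", {
  # C-terminally open leucokinin: visible FNAW is a 4-residue motif prefix
  a <- classify_peptide(parse_peptide("PSFNAW+"), lib)
  expect_equal(a$family, "leucokinin")
  # 3 matched residues are below min_match
  expect_equal(classify_peptide(parse_peptide("PSFNAW+"), lib,
                                min_match = 5L)$family, "linker")
})

test_that("exact templates and precursor precedence outrank motif scans", {
  a <- classify_peptide(parse_peptide("+GFN"), lib, ftpl)
  expect_equal(a$family, "orcokinin")
  expect_true(a$via_template)
  # precursor-of-origin disambiguation fires only when the motif also matches
  p <- parse_peptide("AYFSPRLa")
  a <- classify_peptide(p, lib, precursor_family = "pyrokinin")
  expect_true(a$via_precursor)
  a2 <- classify_peptide(p, lib, precursor_family = "AST-A")
  expect_false(a2$via_precursor)
  expect_equal(a2$family, "pyrokinin")
})

test_that("classification is total, idempotent and order-independent", {
  set.seed(31)
  peps <- lapply(1:30, function(i) {
    gp <- generate_precursor(2)
    process_precursor(precursor_from_truth(gp))
  })
  peps <- unlist(peps, recursive = FALSE)
  f1 <- vapply(peps, function(p) classify_peptide(p, lib, ftpl)$family, "")
  expect_true(all(nzchar(f1)))
  f2 <- vapply(rev(peps), function(p) classify_peptide(p, lib, ftpl)$family,
               "")
  expect_equal(rev(f2), f1)
})

test_that("generated family peptides classify to their construction family", {
  set.seed(32)
  hits <- 0; total <- 0
  for (i in 1:25) {
    gp <- generate_precursor(sample(2:6, 1))
    peps <- process_precursor(precursor_from_truth(gp))
    truth <- gp$truth$fragments$family
    got <- vapply(peps, function(p) classify_peptide(p, lib)$family, "")
    total <- total + length(got)
    hits <- hits + sum(got == truth)
  }
  expect_equal(hits, total)
})

test_that("count summaries break out full-length and partial peptides", {
  expect_equal(nrow(summarize_counts(
    data.frame(family = character(), n_open = logical(),
               c_open = logical()))), 0L)
  tab <- data.frame(family = c("AST-A", "AST-A", "leucokinin"),
                    n_open = c(FALSE, FALSE, FALSE),
                    c_open = c(FALSE, FALSE, TRUE))
  ct <- summarize_counts(tab)
  expect_equal(ct$n_distinct[ct$family == "AST-A"], 2L)
  expect_equal(ct$n_partial[ct$family == "leucokinin"], 1L)
  expect_equal(ct$n_distinct[ct$family == "total"], 3L)
})
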