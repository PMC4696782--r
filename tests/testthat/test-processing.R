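test_that("cleavage rules find dibasic and helper-supported monobasic sites", {
  s <- find_cleavage_sites("SSALAKRDDGG")
  expect_equal(s$pos, 5L)
  expect_equal(s$kind, "KR")
  expect_equal(s$width, 2L)

  # monobasic R with K at -4
  s <- find_cleavage_sites("AAKAAARAAA")
  expect_equal(s$pos, 6L)
  expect_equal(s$kind, "mono_R")
  expect_equal(s$width, 1L)

  # monobasic followed by proline is excluded
  expect_equal(nrow(find_cleavage_sites("AAARPA")), 0L)
  # and so is a monobasic without an upstream basic helper
  expect_equal(nrow(find_cleavage_sites("AAAAAARAAA")), 0L)

  # no sites inside the signal peptide
  s <- find_cleavage_sites("MKRAAAAAKRDD", signal_end = 5L)
  expect_equal(s$pos, 8L)

  # overlapping dibasics resolve leftmost-first: KRR -> KR site, lone R
  s <- find_cleavage_sites("AAAKRRAAAAAA")
  expect_equal(s$pos[1], 3L)
  expect_equal(s$kind[1], "KR")
})

test_that("enabling KK/RK only ever adds sites (monotonicity)", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_protein(60)
    # runs of three or more basics make the leftmost-first pairing itself
    # reshuffle site positions; the monotonicity property concerns isolated
    # mono-/dibasic contexts, as prohormones present them
    while (grepl("[KR]{3}", p)) p <- random_protein(60)
    with_kk <- find_cleavage_sites(p, cleavage_rules(dibasic_secondary = TRUE))
    without <- find_cleavage_sites(p, cleavage_rules(dibasic_secondary = FALSE))
    covered <- function(s) unlist(mapply(function(p0, w) p0 + seq_len(w) - 1L,
                                         s$pos, s$width, SIMPLIFY = FALSE))
    # every basic residue cleaved without KK/RK stays cleaved with them
    # (possibly absorbed into a wider dibasic site)
    expect_true(all(covered(without) %in% covered(with_kk)))
    expect_true(all(with_kk$low_confidence[with_kk$kind %in% c("KK", "RK")]))
  }
})

test_that("annotation-mode cleavage validates loci and infers widths", {
  s <- find_cleavage_sites("SSALAKRDDGG", "annotation",
                           annotation_pos = c(5L))
  expect_equal(s$width, 2L)  # K followed by R
  expect_error(
    find_cleavage_sites("SSALAKRDDGG", "annotation", annotation_pos = 2L),
    "not K/R")
})

test_that("excision conserves the precursor sequence and flags open ends", {
  prot <- "MKRAAAAAAAAKRBB"
  sites <- find_cleavage_sites(prot, signal_end = 3L)
  fr <- excise_fragments(prot, sites, signal_end = 3L, completeness = "F")
  expect_equal(fr$seq, c("AAAAAAAA", "BB"))
  recon <- paste0(substr(prot, 1, 3), paste(paste0(fr$seq, fr$removed),
                                            collapse = ""))
  expect_equal(recon, prot)

  # C-type: first fragment n_open; N-type: last fragment c_open
  fr_c <- excise_fragments(prot, sites, signal_end = 0L, completeness = "C")
  expect_true(fr_c$n_open[1])
  expect_false(any(fr_c$c_open))
  fr_n <- excise_fragments(prot, sites, signal_end = 3L, completeness = "N")
  expect_true(fr_n$c_open[nrow(fr_n)])
  fr_i <- excise_fragments(prot, sites, signal_end = 0L, completeness = "I")
  expect_true(fr_i$n_open[1] && fr_i$c_open[nrow(fr_i)])
})

test_that("PTM rules reproduce the canonical worked examples", {
  frag <- function(seq, followed = TRUE, n_open = FALSE, c_open = FALSE)
    list(seq = seq, followed_by_site = followed, n_open = n_open,
         c_open = c_open)
  # glycine before a site is consumed; N-terminal Gln cyclizes
  p <- apply_ptms(frag("QDLDHVFLRFG"))
  expect_equal(render_peptide(p), "pQDLDHVFLRFa")
  # two cysteines pair automatically on a full-length peptide
  p <- apply_ptms(frag("PFCNAFTGCG"))
  expect_equal(render_peptide(p), "PFCNAFTGCa")
  expect_equal(p$disulfides, list(c(2L, 8L)))
  # no trailing glycine: unmodified
  p <- apply_ptms(frag("RYLPT"))
  expect_equal(render_peptide(p), "RYLPT")
  expect_false(p$amidated || p$pyroglu)
  # Gln on a truncated peptide does not cyclize
  p <- apply_ptms(frag("QVFDQAC", followed = FALSE, c_open = TRUE))
  expect_false(p$pyroglu)
  expect_true(p$c_open)
  # trailing G at the precursor C-terminus is kept without a template
  p <- apply_ptms(frag("AAWG", followed = FALSE))
  expect_false(p$amidated)
  expect_equal(p$seq, "AAWG")
})

test_that("templates gate pyroGlu-from-Glu, sulfation and disulfides", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ESFSAWG\tpyroglu_E",
               "EFDEYGHMRF\tpyroglu_E;sulfo:Y4",
               "ACACAC\tss:1-3",
               "AAW\tamide_Cterm"), tmp)
  tpl <- read_ptm_templates(tmp)
  frag <- function(seq, followed = TRUE)
    list(seq = seq, followed_by_site = followed, n_open = FALSE,
         c_open = FALSE)
  p <- apply_ptms(frag("ESFSAWGG"), templates = tpl)
  expect_equal(render_peptide(p), "pESFSAWGa")
  p <- apply_ptms(frag("EFDEYGHMRFG"), templates = tpl)
  expect_equal(render_peptide(p), "pEFDEY(SO3H)GHMRFa")
  expect_equal(p$sulfated, 4L)
  # >2 cysteines need a template; ordinals map to residue positions
  p <- apply_ptms(frag("ACACAC"), templates = tpl)
  expect_equal(p$disulfides, list(c(1L, 5L)))
  p <- apply_ptms(frag("ACACAC"))
  expect_equal(p$disulfides, list())
  # template-granted amidation at the precursor C-terminus
  p <- apply_ptms(frag("AAWG", followed = FALSE), templates = tpl)
  expect_true(p$amidated)
  expect_equal(p$seq, "AAW")
  # sulfation suppressed on open-ended peptides
  po <- apply_ptms(list(seq = "EFDEYGHMRF", followed_by_site = FALSE,
                        n_open = FALSE, c_open = TRUE), templates = tpl)
  expect_equal(po$sulfated, integer(0))
})

test_that("pyroglu_E configuration modes behave as documented", {
  frag <- list(seq = "EAAAA", followed_by_site = TRUE, n_open = FALSE,
               c_open = FALSE)
  expect_false(apply_ptms(frag, ptm_config("never"))$pyroglu)
  expect_false(apply_ptms(frag, ptm_config("template"))$pyroglu)
  expect_true(apply_ptms(frag, ptm_config("always"))$pyroglu)
})

test_that("deduplication keys on sequence plus full modification state", {
  mk <- function(seq, amidated = FALSE, precursor = "a")
    structure(list(seq = seq, amidated = amidated, pyroglu = FALSE,
                   sulfated = integer(0), disulfides = list(),
                   n_open = FALSE, c_open = FALSE, precursor = precursor),
              class = "mature_peptide")
  same <- deduplicate(list(mk("NRNFLRF", TRUE, "p1"), mk("NRNFLRF", TRUE,
                                                         "p2")))
  expect_length(same, 1L)
  diff <- deduplicate(list(mk("NRNFLRF", TRUE), mk("NRNFLRF", FALSE)))
  expect_length(diff, 2L)
  # stable first-occurrence order
  out <- deduplicate(list(mk("B"), mk("A"), mk("B")))
  expect_equal(vapply(out, `[[`, "", "seq"), c("B", "A"))
})

test_that("rendering and parsing of conventional notation are inverse", {
  cases <- c("pQDLDHVFLRFa", "PSFNAW+", "+KPPFNGSIFa", "RYLPT",
             "GGGEY(SO3H)DDY(SO3H)GHLRFa", "+GFN",
             "QVFDQACKGVYDRNLFKKLDRVCEDCYNLYRKPFVATTCR+")
  for (s in cases) {
    expect_equal(render_peptide(parse_peptide(s)), s)
  }
  p <- parse_peptide("GGGEY(SO3H)DDY(SO3H)GHLRFa")
  expect_equal(p$seq, "GGGEYDDYGHLRF")
  expect_equal(p$sulfated, c(4L, 7L))
})

test_that("no excised peptide ends in unamidated glycine before a site", {
  set.seed(77)
  for (i in 1:30) {
    gp <- generate_precursor(sample(2:5, 1))
    prec <- precursor_from_truth(gp)
    peps <- process_precursor(prec)
    sites <- find_cleavage_sites(prec)
    fr <- excise_fragments(prec, sites)
    for (k in seq_len(nrow(fr))) {
      if (fr$followed_by_site[k] && endsWith(fr$seq[k], "G")) {
        expect_true(peps[[k]]$amidated)
      }
    }
  }
})
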