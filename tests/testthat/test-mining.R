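test_that("a query embedded verbatim in a transcript is the top hit", {
  set.seed(71)
  query <- random_protein(40)
  # embed the back-translation in frame +2 among decoys
  embedded <- paste0("G", paste(vapply(strsplit(query, "")[[1]], function(a) {
    cods <- names(which(Biostrings::GENETIC_CODE == a))
    sample(cods, 1)
  }, ""), collapse = ""), "AA")
  tx <- data.frame(id = c(sprintf("decoy_%02d", 1:20), "target"),
                   seq = c(replicate(20, random_dna(300)), embedded),
                   stringsAsFactors = FALSE)
  hits <- translated_search("q", query, tx)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$transcript_id[1], "target")
  expect_equal(hits$frame[1], 2L)
  # the aligned query span covers the full query
  expect_equal(hits$q_start[1], 0L)
  expect_equal(hits$q_end[1], nchar(query))
})

test_that("degenerate searches return empty hit lists", {
  q <- random_protein(30)
  empty <- data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(translated_search("q", q, empty)), 0L)
  set.seed(72)
  tx <- data.frame(id = "t1", seq = random_dna(300), stringsAsFactors = FALSE)
  expect_equal(nrow(translated_search("q", strrep("X", 30), tx)), 0L)
})

test_that("scores ignore database order; E-values grow with database size", {
  set.seed(73)
  gp <- generate_precursor(3, seed = 5)
  sim <- generate_transcriptome(n_true = 4, n_decoy = 10, seed = 5)
  tx <- sim$transcripts
  h1 <- translated_search("q", gp$protein, tx)
  h2 <- translated_search("q", gp$protein, tx[rev(seq_len(nrow(tx))), ])
  expect_equal(h1$score, h2$score)
  expect_equal(h1$transcript_id, h2$transcript_id)
  # doubling the database doubles E for the same raw score
  db1 <- build_search_db(tx)
  db2 <- db1
  db2$db_size <- db1$db_size * 2
  loose <- search_params(evalue_max = Inf)
  e1 <- translated_search("q", gp$protein, params = loose, db = db1)
  e2 <- translated_search("q", gp$protein, params = loose, db = db2)
  expect_equal(e2$evalue, 2 * e1$evalue)
})

test_that("reciprocal best hits are recognized and shuffled queries rejected", {
  set.seed(74)
  member <- random_protein(120)
  panel <- data.frame(id = c("P", "Q"),
                      seq = c(member, random_protein(120)),
                      stringsAsFactors = FALSE)
  back <- data.frame(id = "me", seq = member, stringsAsFactors = FALSE)
  rb <- reciprocal_best_hit("me", member, panel, back)
  expect_equal(rb$best_panel_member, "P")
  expect_true(rb$reciprocal)
  # a protein unrelated to the panel yields no assignment
  expect_null(reciprocal_best_hit(
    "x", paste(rev(strsplit(random_protein(120), "")[[1]]), collapse = ""),
    panel, back, search_params(evalue_max = 1e-6)))
})

test_that("a mutated panel member still finds its origin reciprocally", {
  set.seed(75)
  member <- random_protein(150)
  chars <- strsplit(member, "")[[1]]
  idx <- sample(length(chars), 30)  # 20% of sites
  chars[idx] <- vapply(chars[idx], function(a)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], a), 1), "")
  mutant <- paste(chars, collapse = "")
  panel <- data.frame(id = c("P", "other"),
                      seq = c(member, random_protein(150)),
                      stringsAsFactors = FALSE)
  back <- data.frame(id = c("mut", "noise"),
                     seq = c(mutant, random_protein(150)),
                     stringsAsFactors = FALSE)
  rb <- reciprocal_best_hit("mut", mutant, panel, back)
  expect_equal(rb$best_panel_member, "P")
  expect_true(rb$reciprocal)
})
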