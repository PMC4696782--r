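#' @keywords internal
.body_alphabet <- c("A", "D", "F", "G", "H", "I", "L", "N", "S", "T", "V",
                    "W", "Y")

.rand_body <- function(len) {
  chars <- sample(.body_alphabet, len, replace = TRUE)
  # never end in G (amidation donors are added explicitly)
  while (chars[len] == "G") chars[len] <- sample(.body_alphabet, 1L)
  paste(chars, collapse = "")
}

# Family peptide instantiators; every family here is C-terminally amidated.
# Motifs containing an internal arginine (FLRFamide, pyrokinin) carry an
# N-terminal extension long enough that the arginine sits at block index
# >= 8, so it can never find a basic helper at -4/-6/-8 (the nearest
# upstream basic is the preceding cleavage site) and the monobasic rule
# stays silent on it.
.family_generators <- list(
  `AST-A` = function() paste0(.rand_body(sample(2:3, 1L)),
                              sample(c("Y", "F"), 1L),
                              sample(.body_alphabet, 1L), "FG",
                              sample(c("L", "I"), 1L)),
  FLRFamide = function() paste0(.rand_body(sample(6:8, 1L)),
                                sample(c("F", "Y"), 1L), "LRF"),
  leucokinin = function() paste0(.rand_body(sample(2:4, 1L)), "F",
                                 .rand_body(sample(1:2, 1L)), "W",
                                 sample(c("G", "A"), 1L)),
  pyrokinin = function() paste0(.rand_body(sample(5:7, 1L)), "FSPRL"),
  GSEFLamide = function() paste0(.rand_body(sample(1:2, 1L)), "GSEFL")
)

#' Generate a ground-truthed synthetic precursor
#'
#' Emulates the canonical preprohormone architecture: a signal peptide
#' (Met + two basic residues + an 8-12 residue hydrophobic h-region + an
#' `ASA` cleavage context satisfying the (-3,-1) rule), then alternating
#' peptide and linker blocks separated by cleavage sites drawn from
#' `site_mix`. Amidation donors are encoded as trailing glycines;
#' pyroglutamate as a prepended glutamine. Monobasic sites are built with
#' the required basic residue at relative position -4 inside the preceding
#' block. Deterministic under `seed`.
#'
#' @param n_peptides Number of family peptide blocks (must be >= 1).
#' @param peptide_len,linker_len Length ranges (used for random blocks).
#' @param site_mix Named probabilities over `KR`, `RR`, `mono_R`.
#' @param amidation_prob Probability a random peptide is amidated (family
#'   peptides are always amidated, as their motifs require).
#' @param pyroglu_prob Probability a peptide starts with pyroglutamate.
#' @param families Families to draw peptides from (subset of the shipped
#'   generator families, or `"random"`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `protein`, and `truth` (list: `signal_end`, `sites`
#'   data frame, `fragments` data frame with mature sequences, families and
#'   PTM flags in precursor order).
#' @export
generate_precursor <- function(n_peptides, peptide_len = c(6L, 12L),
                               linker_len = c(4L, 12L),
                               site_mix = c(KR = 0.4, RR = 0.4, mono_R = 0.2),
                               amidation_prob = 0.7, pyroglu_prob = 0.2,
                               families = names(.family_generators),
                               seed = NULL) {
  if (n_peptides < 1L) stop("n_peptides must be >= 1")
  if (peptide_len[1] < 2L || linker_len[1] < 2L) {
    stop("peptide/linker length ranges must allow length >= 2")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stopifnot(all(names(site_mix) %in% c("KR", "RR", "mono_R")))

  signal <- paste0("M", paste(sample(c("K", "R"), 2L, replace = TRUE),
                              collapse = ""),
                   paste(sample(c("L", "I", "F"), sample(8:12, 1L),
                                replace = TRUE), collapse = ""),
                   "ASA")
  signal_end <- nchar(signal)

  n_blocks <- 2L * n_peptides  # peptide, linker, peptide, ..., final linker
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    if (b %% 2L == 1L) {  # peptide block
      fam <- sample(families, 1L)
      if (fam == "random") {
        body <- .rand_body(sample(peptide_len[1]:peptide_len[2], 1L))
        amid <- stats::runif(1) < amidation_prob
      } else {
        body <- .family_generators[[fam]]()
        amid <- TRUE
      }
      pyro <- stats::runif(1) < pyroglu_prob
      if (pyro) body <- paste0("Q", body)
      blocks[[b]] <- list(body = body, family = fam, amidated = amid,
                          pyroglu = pyro)
    } else {
      blocks[[b]] <- list(body = .rand_body(sample(linker_len[1]:
                                                     linker_len[2], 1L)),
                          family = "linker", amidated = FALSE,
                          pyroglu = FALSE)
    }
  }
  site_kinds <- sample(names(site_mix), n_blocks - 1L, replace = TRUE,
                       prob = site_mix)
  # monobasic sites rebuild the preceding block around the -4 helper, which
  # would destroy a family peptide's motif: place them after linkers only
  odd <- seq_along(site_kinds) %% 2L == 1L
  if (any(odd & site_kinds == "mono_R")) {
    site_kinds[odd & site_kinds == "mono_R"] <-
      sample(c("KR", "RR"), sum(odd & site_kinds == "mono_R"), replace = TRUE)
  }
  # monobasic sites need a basic residue at -4: rebuild the preceding block
  # as a 12-mer with K at 0-based index 8 (offsets chosen so that neither the
  # helper K nor the site can fire any other rule)
  for (k in seq_along(site_kinds)) {
    if (site_kinds[k] == "mono_R") {
      bl <- blocks[[k]]
      body <- .rand_body(12L)
      chars <- strsplit(body, "", fixed = TRUE)[[1]]
      chars[9L] <- "K"
      bl$body <- paste(chars, collapse = "")
      bl$amidated <- FALSE  # keep the -4 geometry exact (no donor G)
      bl$pyroglu <- FALSE
      blocks[[k]] <- bl
    }
  }

  protein <- signal
  sites <- .empty_sites()
  fragments <- list()
  for (b in seq_len(n_blocks)) {
    bl <- blocks[[b]]
    followed <- b < n_blocks
    raw <- paste0(bl$body, if (bl$amidated && followed) "G" else "")
    frag_start <- nchar(protein)
    protein <- paste0(protein, raw)
    if (followed) {
      kind <- site_kinds[b]
      site_seq <- switch(kind, KR = "KR", RR = "RR", mono_R = "R")
      sites <- rbind(sites, data.frame(
        pos = nchar(protein), kind = if (kind == "mono_R") "mono_R" else kind,
        width = nchar(site_seq), source = "truth", low_confidence = FALSE,
        stringsAsFactors = FALSE))
      protein <- paste0(protein, site_seq)
    }
    fragments[[b]] <- data.frame(
      seq = bl$body, start = frag_start,
      family = bl$family,
      amidated = bl$amidated && followed,
      pyroglu = bl$pyroglu, n_open = FALSE, c_open = FALSE,
      stringsAsFactors = FALSE)
  }
  list(protein = protein,
       truth = list(signal_end = signal_end, sites = sites,
                    fragments = do.call(rbind, fragments)))
}

#' @keywords internal
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Back-translate a protein with uniform synonymous codons
#' @keywords internal
back_translate <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    cods <- .codon_table[[a]]
    if (is.null(cods)) stop("cannot back-translate residue: ", a)
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

.rand_nt <- function(len, gc = 0.5) {
  if (len == 0L) return("")
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' True transcripts embed back-translated synthetic precursors in random
#' frames and strands; the completeness mix is realized by construction: F
#' transcripts carry bracketing stop codons and UTRs, N transcripts lose the
#' terminal stop and 3' tail, C transcripts lose the 5' end through the
#' start Met, and I transcripts lose both. Decoys are random sequence,
#' length- and GC-matched to the true set. Deterministic under `seed`.
#'
#' @param n_true,n_decoy Transcript counts (>= 0).
#' @param truncation_mix Named probabilities over classes `F`, `N`, `C`, `I`.
#' @param utr_len Range of UTR lengths (nt).
#' @param n_peptides,... Passed to [generate_precursor()].
#' @param seed Integer seed.
#' @return List with `transcripts` (`data.frame`: `id`, `seq`, `length`) and
#'   `truth` (`data.frame`: `transcript_id`, `is_decoy`, `class`, `frame`,
#'   `protein`, plus a `precursors` list of per-precursor truth records
#'   indexed by transcript id).
#' @export
generate_transcriptome <- function(n_true = 10L, n_decoy = 40L,
                                   truncation_mix = c(F = 1),
                                   utr_len = c(30L, 60L),
                                   n_peptides = 4L, seed = NULL, ...) {
  stopifnot(n_true >= 0L, n_decoy >= 0L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  classes <- if (n_true > 0L) {
    sample(names(truncation_mix), n_true, replace = TRUE,
           prob = truncation_mix)
  } else character(0)
  tx <- list()
  truth_rows <- list()
  precursors <- list()
  for (i in seq_len(n_true)) {
    gp <- generate_precursor(n_peptides = n_peptides, ...)
    id <- sprintf("synthetic_true_%03d", i)
    cls <- classes[i]
    protein <- gp$protein
    u5 <- sample(utr_len[1]:utr_len[2], 1L)
    u3 <- sample(utr_len[1]:utr_len[2], 1L)
    if (cls %in% c("C", "I")) {
      # clip through the start: drop signal plus two residues of block 1
      cut <- gp$truth$signal_end + 2L
      protein_vis <- substring(protein, cut + 1L)
      if (cls == "I") {
        protein_vis <- substr(protein_vis, 1L, nchar(protein_vis) - 2L)
      }
      cds <- back_translate(protein_vis)
      seq <- if (cls == "C") paste0(cds, "TAA", .rand_nt(u3)) else cds
      s_orig <- 0L
    } else {
      protein_vis <- protein
      cds <- back_translate(protein_vis)
      seq <- paste0(.rand_nt(u5), "TAA", cds,
                    if (cls == "F") paste0("TAA", .rand_nt(u3)) else "")
      s_orig <- u5 + 3L
    }
    frame <- (s_orig %% 3L) + 1L
    if (stats::runif(1) < 0.5) {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      frame <- -frame
    }
    tx[[length(tx) + 1L]] <- data.frame(id = id, seq = seq,
                                        length = nchar(seq),
                                        stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript_id = id, is_decoy = FALSE, class = cls, frame = frame,
      protein = protein_vis, stringsAsFactors = FALSE)
    precursors[[id]] <- gp
  }
  true_seqs <- vapply(tx, function(t) t$seq, "")
  gc <- if (length(true_seqs)) {
    mean(strsplit(paste(true_seqs, collapse = ""), "",
                  fixed = TRUE)[[1]] %in% c("G", "C"))
  } else 0.5
  len_range <- if (length(true_seqs)) range(nchar(true_seqs)) else c(300L, 900L)
  for (i in seq_len(n_decoy)) {
    id <- sprintf("synthetic_decoy_%03d", i)
    len <- sample(len_range[1]:len_range[2], 1L)
    tx[[length(tx) + 1L]] <- data.frame(id = id, seq = .rand_nt(len, gc),
                                        length = len, stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript_id = id, is_decoy = TRUE, class = NA_character_,
      frame = NA_integer_, protein = NA_character_, stringsAsFactors = FALSE)
  }
  transcripts <- if (length(tx)) do.call(rbind, tx) else
    data.frame(id = character(), seq = character(), length = integer(),
               stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(transcript_id = character(), is_decoy = logical(),
               class = character(), frame = integer(), protein = character(),
               stringsAsFactors = FALSE)
  list(transcripts = transcripts, truth = truth, precursors = precursors)
}

#' Generate a synthetic multi-pass membrane protein
#'
#' Test/demo construction: `n_tm` strongly hydrophobic segments separated by
#' charged loops, with charged N- and C-terminal tails.
#'
#' @param n_tm Number of membrane-spanning segments.
#' @param tm_len Segment length.
#' @param loop_len Loop length between segments.
#' @param tail_len Length of the terminal hydrophilic tails.
#' @return Amino-acid string.
#' @export
generate_receptor_protein <- function(n_tm = 7L, tm_len = 23L,
                                      loop_len = 22L, tail_len = 30L) {
  tm <- function() paste(sample(c("L", "I", "V"), tm_len, TRUE),
                         collapse = "")
  loop <- function(len) paste(sample(c("D", "E", "K", "R", "N", "Q"),
                                     len, TRUE), collapse = "")
  paste0(loop(tail_len),
         paste(vapply(seq_len(n_tm), function(i)
           paste0(tm(), if (i < n_tm) loop(loop_len) else ""), ""),
           collapse = ""),
         loop(tail_len))
}
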