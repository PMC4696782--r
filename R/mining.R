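#' Search parameters for translated homology search
#'
#' Karlin-Altschul scaling constants default to the conventional gapped
#' BLOSUM62 values (lambda = 0.267, K = 0.041). The default E-value cutoff
#' of 5e-3 is a judgment call chosen to admit weak but genuine precursor
#' hits (the weakest credible hits in this problem domain sit around E ~
#' 1e-3) while excluding random matches; it is configurable.
#'
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for bit-score/E-value scaling.
#' @param evalue_max Maximum E-value for a reported hit.
#' @param min_segment_aa Skip stop-free frame segments shorter than this.
#' @return List of class `"search_params"`.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                          lambda = 0.267, K = 0.041, evalue_max = 5e-3,
                          min_segment_aa = 10L) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 evalue_max = evalue_max, min_segment_aa = min_segment_aa),
            class = "search_params")
}

.empty_hits <- function() {
  data.frame(query_id = character(), transcript_id = character(),
             frame = integer(), score = numeric(), bitscore = numeric(),
             evalue = numeric(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), stringsAsFactors = FALSE)
}

#' Build a translated search database from transcripts
#'
#' Translates every transcript in all six frames (vectorized), splits the
#' frame translations at stop codons into stop-free segments, and records
#' frame-local offsets. Building the database once lets many queries reuse
#' it.
#'
#' @param transcripts Data frame with `id` and `seq` (nucleotide) columns.
#' @param min_segment_aa Segments shorter than this are dropped.
#' @return List of class `"search_db"` with `segments` (data frame:
#'   `transcript_id`, `frame`, `offset`, `seq`) and `db_size` (total
#'   translated residues).
#' @export
build_search_db <- function(transcripts, min_segment_aa = 10L) {
  seg_tx <- character(0); seg_fr <- integer(0)
  seg_off <- integer(0); seg_seq <- character(0)
  db_size <- 0
  if (nrow(transcripts) > 0L) {
    dna <- Biostrings::DNAStringSet(gsub("U", "T",
                                         toupper(transcripts$seq)))
    rc <- Biostrings::reverseComplement(dna)
    for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      src <- if (f > 0L) dna else rc
      off <- abs(f) - 1L
      w <- pmax(Biostrings::width(src) - off, 0L)
      w <- w - w %% 3L
      keep <- which(w >= 3L)
      if (length(keep) == 0L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(src[keep], start = off + 1L, width = w[keep]),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      db_size <- db_size + sum(nchar(gsub("*", "", aa, fixed = TRUE)))
      pieces <- strsplit(aa, "*", fixed = TRUE)
      for (k in seq_along(keep)) {
        ps <- pieces[[k]]
        if (length(ps) == 0L) next
        offs <- cumsum(c(0L, nchar(ps) + 1L))[seq_along(ps)]
        sel <- nchar(ps) >= min_segment_aa
        if (!any(sel)) next
        seg_tx <- c(seg_tx, rep(transcripts$id[keep[k]], sum(sel)))
        seg_fr <- c(seg_fr, rep(f, sum(sel)))
        seg_off <- c(seg_off, offs[sel])
        seg_seq <- c(seg_seq, ps[sel])
      }
    }
  }
  structure(list(segments = data.frame(transcript_id = seg_tx,
                                       frame = seg_fr, offset = seg_off,
                                       seq = seg_seq,
                                       stringsAsFactors = FALSE),
                 db_size = db_size),
            class = "search_db")
}

#' Translated local-alignment search of a protein query against transcripts
#'
#' Each transcript is translated in all six frames; stop codons split the
#' frame translations into segments (no alignment crosses a stop), and the
#' query is locally aligned against every segment. The best segment hit per
#' transcript/frame is scored; E-values use Karlin-Altschul scaling with the
#' total translated database size. Hits are ranked by score, ties broken by
#' transcript identifier.
#'
#' @param query_id,query Protein query identifier and sequence.
#' @param transcripts Data frame with `id` and `seq` (nucleotide) columns
#'   (ignored when `db` is supplied).
#' @param params A [search_params()].
#' @param db Optional prebuilt [build_search_db()] database.
#' @return Ranked hit table (0-based half-open spans; `s_*` in frame-local
#'   protein coordinates).
#' @export
translated_search <- function(query_id, query, transcripts = NULL,
                              params = search_params(), db = NULL) {
  if (is.null(db)) {
    if (is.null(transcripts)) stop("supply transcripts or a search db")
    db <- build_search_db(transcripts, params$min_segment_aa)
  }
  segs <- db$segments
  db_size <- db$db_size
  if (nrow(segs) == 0L) return(.empty_hits())
  subj <- Biostrings::AAStringSet(segs$seq)
  pa <- Biostrings::pairwiseAlignment(
    subj, Biostrings::AAString(query), type = "local",
    substitutionMatrix = params$matrix, gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
  scores <- Biostrings::score(pa)
  qr <- Biostrings::subject(pa)  # the query is the fixed 'subject'
  sr <- Biostrings::pattern(pa)
  hits <- data.frame(query_id = query_id, transcript_id = segs$transcript_id,
                     frame = segs$frame, score = scores,
                     q_start = BiocGenerics::start(qr) - 1L,
                     q_end = BiocGenerics::end(qr),
                     s_start = segs$offset + BiocGenerics::start(sr) - 1L,
                     s_end = segs$offset + BiocGenerics::end(sr),
                     stringsAsFactors = FALSE)
  # best segment per transcript/frame
  key <- paste(hits$transcript_id, hits$frame)
  ord <- order(-hits$score, hits$transcript_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  hits$bitscore <- (params$lambda * hits$score - log(params$K)) / log(2)
  hits$evalue <- params$K * nchar(query) * db_size *
    exp(-params$lambda * hits$score)
  hits <- hits[hits$score > 0 & hits$evalue <= params$evalue_max, ,
               drop = FALSE]
  hits <- hits[order(-hits$score, hits$transcript_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "transcript_id", "frame", "score", "bitscore",
           "evalue", "q_start", "q_end", "s_start", "s_end")]
}

#' Protein-vs-protein local search (best hit)
#'
#' @param query Protein string.
#' @param db Data frame with `id` and `seq` columns.
#' @param params A [search_params()].
#' @return Data frame of scored hits sorted by score then id (E-value filter
#'   applied, database size = total db residues).
#' @keywords internal
protein_search <- function(query, db, params = search_params()) {
  if (nrow(db) == 0L) {
    return(data.frame(id = character(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db$seq), Biostrings::AAString(query),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(pa)
  n_db <- sum(nchar(db$seq))
  out <- data.frame(id = db$id, score = sc,
                    evalue = params$K * nchar(query) * n_db *
                      exp(-params$lambda * sc),
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0 & out$evalue <= params$evalue_max, , drop = FALSE]
  out[order(-out$score, out$id), , drop = FALSE]
}

#' Reciprocal-best-hit assignment against a reference panel
#'
#' The query protein's best panel member is found by local alignment; the
#' assignment is flagged reciprocal when that panel member's own best hit
#' back into `back_db` is the query protein. Ties break deterministically by
#' identifier.
#'
#' @param protein_id,protein Query identifier and sequence.
#' @param panel Data frame with `id`, `seq` and optionally `superfamily`.
#' @param back_db Data frame with `id`, `seq` — the database for the return
#'   search (should contain the query protein itself).
#' @param params A [search_params()].
#' @return List with `protein_id`, `best_panel_member`, `reciprocal`,
#'   `score`, or `NULL` when no panel hit passes the threshold.
#' @export
reciprocal_best_hit <- function(protein_id, protein, panel, back_db,
                                params = search_params()) {
  stopifnot(nrow(panel) > 0L)
  fwd <- protein_search(protein, panel, params)
  if (nrow(fwd) == 0L) return(NULL)
  best <- fwd$id[1L]
  back <- protein_search(panel$seq[panel$id == best][1L], back_db, params)
  reciprocal <- nrow(back) > 0L && back$id[1L] == protein_id
  list(protein_id = protein_id, best_panel_member = best,
       reciprocal = reciprocal, score = fwd$score[1L])
}
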