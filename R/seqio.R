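#' Read sequences from a FASTA file
#'
#' Reads nucleotide or protein FASTA into a plain data frame. Sequences are
#' uppercased; in nucleotide mode `U` is mapped to `T` so RNA input is
#' accepted transparently. Record identifiers (the first whitespace-delimited
#' token of each header) must be non-empty and unique within a file.
#'
#' @param path Path to a FASTA file.
#' @param type `"nt"` for nucleotide records, `"aa"` for protein records.
#' @return A `data.frame` with columns `id`, `seq` and `length` (residues).
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- if (type == "nt") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (type == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(ids == "")) {
    stop("FASTA parse error: empty record identifier at record ",
         which(ids == "")[1])
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("FASTA parse error: duplicate identifier(s): ",
         paste(dups, collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    bad <- ids[nchar(seqs) == 0L]
    stop("FASTA parse error: empty sequence for record(s): ",
         paste(bad, collapse = ", "))
  }
  data.frame(id = unname(ids), seq = unname(seqs),
             length = unname(nchar(seqs)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids Character vector of identifiers (or a data frame with `id` and
#'   `seq` columns, in which case `seqs` is ignored).
#' @param seqs Character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, seqs = NULL, path, width = 60L) {
  if (is.data.frame(ids)) {
    seqs <- ids$seq
    ids <- ids$id
  }
  stopifnot(length(ids) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.valid_frames <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code; stop codons are rendered `*`. Negative frames
#' translate the reverse complement. Trailing 1-2 nt that do not complete a
#' codon are ignored. Codons containing an ambiguity (e.g. `N`) translate to
#' `X` unless the ambiguity still resolves to a unique amino acid.
#'
#' @param seq Nucleotide string over the IUPAC alphabet.
#' @param frame One of `+1, +2, +3, -1, -2, -3`.
#' @return Amino-acid string with `*` for stops.
#' @export
translate_frame <- function(seq, frame) {
  if (!frame %in% .valid_frames) stop("invalid frame: ", frame)
  dna <- tryCatch(Biostrings::DNAString(gsub("U", "T", toupper(seq))),
                  error = function(e) stop("non-IUPAC character in sequence: ",
                                           conditionMessage(e)))
  if (frame < 0L) dna <- Biostrings::reverseComplement(dna)
  off <- abs(frame) - 1L
  n <- length(dna) - off
  if (n < 3L) return("")
  n <- n - n %% 3L
  sub <- Biostrings::subseq(dna, start = off + 1L, width = n)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Six-frame translation
#'
#' @param seq Nucleotide string.
#' @return Named list of six amino-acid strings (`"+1"` ... `"-3"`).
#' @export
six_frame <- function(seq) {
  out <- lapply(.valid_frames, function(f) translate_frame(seq, f))
  names(out) <- ifelse(.valid_frames > 0, paste0("+", .valid_frames),
                       as.character(.valid_frames))
  out
}

#' Extract open reading frames from a transcript
#'
#' ORFs are maximal stop-free stretches of each frame translation; start-Met
#' trimming is deliberately left to the precursor stage so that the
#' distinction between an ORF and the protein deduced from it is preserved.
#' Coordinates are 0-based half-open within the frame translation.
#'
#' @param id Transcript identifier.
#' @param seq Transcript nucleotide sequence.
#' @param min_aa Minimum ORF length in amino acids.
#' @return A `data.frame` with one row per ORF: `transcript_id`, `frame`,
#'   `aa_start`, `aa_end`, `protein`, `upstream_stop`, `start_met`,
#'   `terminal_stop`.
#' @export
extract_orfs <- function(id, seq, min_aa = 30L) {
  stopifnot(min_aa >= 1L)
  rows <- list()
  for (f in .valid_frames) {
    aa <- translate_frame(seq, f)
    if (nchar(aa) == 0L) next
    chars <- strsplit(aa, "", fixed = TRUE)[[1]]
    stops <- which(chars == "*")
    bounds <- c(0L, stops, length(chars) + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k] + 1L       # first residue of stretch (1-based)
      e <- bounds[k + 1L] - 1L  # last residue of stretch (1-based)
      if (e - s + 1L < min_aa) next
      prot <- substr(aa, s, e)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id,
        frame = f,
        aa_start = s - 1L,
        aa_end = e,
        protein = prot,
        upstream_stop = bounds[k] > 0L,
        start_met = substr(prot, 1L, 1L) == "M",
        terminal_stop = bounds[k + 1L] <= length(chars),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), frame = integer(),
                      aa_start = integer(), aa_end = integer(),
                      protein = character(), upstream_stop = logical(),
                      start_met = logical(), terminal_stop = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Format a frame label such as "+2" from its integer code
#' @keywords internal
frame_label <- function(frame) {
  ifelse(frame > 0, paste0("+", frame), as.character(frame))
}
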