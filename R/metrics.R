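#' Default Clustal-style conservation groups
#'
#' Strong and weak residue conservation groups in the conventional Clustal
#' sets, shipped as an editable data file.
#'
#' @param path Path to a groups file (`strong`/`weak` TAB group lines).
#' @return List with character vectors `strong` and `weak`.
#' @export
conservation_groups <- function(path = system.file("extdata",
                                                   "conservation_groups.tsv",
                                                   package = "pepmine")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, "", 1L)
  grp <- vapply(parts, `[`, "", 2L)
  list(strong = grp[kind == "strong"], weak = grp[kind == "weak"])
}

#' Optimal global pairwise alignment of two proteins
#'
#' Needleman-Wunsch-style optimal global alignment with affine gap
#' penalties, defaulting to BLOSUM62 with gap open 10 and gap extension 0.5
#' (a gap of length L costs `10 + 0.5 L`).
#'
#' @param a,b Amino-acid strings (standard residues plus `X`).
#' @param matrix Substitution matrix name (passed to the aligner).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param groups Conservation groups for the symbol line.
#' @return List of class `"pairwise_alignment"`: `aligned_a`, `aligned_b`,
#'   `symbols`, `score`, `len_a`, `len_b`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, groups = conservation_groups()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  for (s in c(a, b)) {
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", s)) {
      stop("non-amino-acid character in sequence")
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  aln <- structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                        symbols = NULL, score = Biostrings::score(pa),
                        len_a = nchar(a), len_b = nchar(b)),
                   class = "pairwise_alignment")
  aln$symbols <- conservation_string(aln, groups)
  aln
}

#' Conservation symbol line for an alignment
#'
#' `*` identical residues, `:` both residues within one strong conservation
#' group, `.` both within one weak group, space otherwise (including any
#' gapped column).
#'
#' @param aln A `pairwise_alignment` (or list with `aligned_a`, `aligned_b`).
#' @param groups Conservation groups ([conservation_groups()]).
#' @return Character scalar of the same length as the alignment.
#' @export
conservation_string <- function(aln, groups = conservation_groups()) {
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  sym <- vapply(seq_along(ca), function(i) {
    x <- ca[i]; y <- cb[i]
    if (x == "-" || y == "-") return(" ")
    if (x == y) return("*")
    in_grp <- function(gs) any(vapply(gs, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), NA))
    if (in_grp(groups$strong)) return(":")
    if (in_grp(groups$weak)) return(".")
    " "
  }, "")
  paste(sym, collapse = "")
}

#' Percent identity and similarity of an aligned pair
#'
#' Percent identity is the number of identical residues (`*` columns)
#' divided by the total number of residues in the longest sequence, times
#' 100; percent similarity additionally counts the similar (`:` and `.`)
#' columns. The denominator is the ungapped length of the longer input.
#'
#' @param aln A `pairwise_alignment` from [global_align()].
#' @return List of class `"identity_stats"`: `pct_identity`,
#'   `pct_similarity`, `n_identical`, `n_similar`, `longest_len`.
#' @export
identity_similarity <- function(aln) {
  sym <- strsplit(aln$symbols, "", fixed = TRUE)[[1]]
  n_id <- sum(sym == "*")
  n_sim <- sum(sym %in% c(":", "."))
  longest <- max(aln$len_a, aln$len_b)
  structure(list(pct_identity = 100 * n_id / longest,
                 pct_similarity = 100 * (n_id + n_sim) / longest,
                 n_identical = n_id, n_similar = n_sim,
                 longest_len = longest),
            class = "identity_stats")
}

#' @export
print.identity_stats <- function(x, ...) {
  cat(sprintf("identity %.1f%% / similarity %.1f%% (%d identical, %d similar, longest %d aa)\n",
              x$pct_identity, x$pct_similarity, x$n_identical, x$n_similar,
              x$longest_len))
  invisible(x)
}

#' Format an alignment in Clustal-like blocks
#'
#' Three-line blocks of the given width: sequence, sequence, symbols.
#'
#' @param aln A `pairwise_alignment`.
#' @param width Block width.
#' @param names Two sequence labels.
#' @return Character vector of lines.
#' @export
format_alignment <- function(aln, width = 60L, names = c("seq_a", "seq_b")) {
  n <- nchar(aln$aligned_a)
  lab <- formatC(substr(names, 1L, 12L), width = 13L, flag = "-")
  out <- character(0)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    out <- c(out,
             paste0(lab[1], substr(aln$aligned_a, s, e)),
             paste0(lab[2], substr(aln$aligned_b, s, e)),
             paste0(strrep(" ", 13L), substr(aln$symbols, s, e)),
             "")
  }
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<global alignment> score %.1f, %d columns\n", x$score,
              nchar(x$aligned_a)))
  cat(format_alignment(x), sep = "\n")
  invisible(x)
}
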