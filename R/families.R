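#' Compile a family motif pattern
#'
#' Patterns are a restricted, explicit syntax: literal residues, residue
#' classes `[ABC]`, the wildcard `.` (any standard residue; never matches
#' `X`), and a `{m,n}` repeat on the preceding element. Compilation expands
#' repeats into the set of fixed-length element sequences, which makes
#' partial (truncated-end) matching well defined.
#'
#' @param pattern Pattern string, e.g. `"[FW].{1,2}W[GA]"`.
#' @return List of alternatives; each alternative is a list of character
#'   vectors of allowed residues (`NULL` for the wildcard).
#' @keywords internal
compile_pattern <- function(pattern) {
  tokens <- list()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substring(pattern, i))
      if (j < 0) stop("unterminated class in pattern: ", pattern)
      cls <- strsplit(substr(pattern, i + 1L, i + j - 2L), "", TRUE)[[1]]
      tokens[[length(tokens) + 1L]] <- list(elem = cls, min = 1L, max = 1L)
      i <- i + j
    } else if (ch == ".") {
      tokens[[length(tokens) + 1L]] <- list(elem = NULL, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "{") {
      j <- regexpr("}", substring(pattern, i))
      if (j < 0 || length(tokens) == 0L) {
        stop("misplaced quantifier in pattern: ", pattern)
      }
      mn <- strsplit(substr(pattern, i + 1L, i + j - 2L), ",", TRUE)[[1]]
      tokens[[length(tokens)]]$min <- as.integer(mn[1])
      tokens[[length(tokens)]]$max <-
        as.integer(if (length(mn) > 1L) mn[2] else mn[1])
      i <- i + j
    } else if (grepl("^[A-Z]$", ch)) {
      tokens[[length(tokens) + 1L]] <- list(elem = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else {
      stop("unsupported pattern character '", ch, "' in: ", pattern)
    }
  }
  alts <- list(list())
  for (tok in tokens) {
    new <- list()
    for (alt in alts) {
      for (k in tok$min:tok$max) {
        a <- alt
        # note: a[[n]] <- NULL would delete, so wrap in list()
        if (k > 0L) for (r in seq_len(k)) a[length(a) + 1L] <- list(tok$elem)
        new[[length(new) + 1L]] <- a
      }
    }
    alts <- new
  }
  alts
}

.match_elems <- function(chars, elems) {
  if (length(chars) != length(elems)) return(FALSE)
  for (i in seq_along(elems)) {
    if (chars[i] == "X") return(FALSE)
    if (!is.null(elems[[i]]) && !(chars[i] %in% elems[[i]])) return(FALSE)
  }
  TRUE
}

#' Match a peptide against an anchored family motif
#'
#' Anchors: `Cterm` (motif must match the C-terminal residues), `Nterm`
#' (N-terminal), `full` (whole sequence). For peptides truncated on the side
#' the anchor sits on (`c_open` for `Cterm`, `n_open` for `Nterm`), a partial
#' match of at least `min_match` residues of the motif against the intact
#' portion is accepted, and the amidation requirement is waived (the
#' amidated terminus is the missing one).
#'
#' @param p A `mature_peptide`.
#' @param anchor `"Cterm"`, `"Nterm"` or `"full"`.
#' @param pattern Motif pattern (see [compile_pattern()]).
#' @param requires_amidation Must the peptide be C-terminally amidated?
#' @param min_match Minimum residues matched for truncated peptides.
#' @return `TRUE`/`FALSE`.
#' @export
match_motif <- function(p, anchor, pattern, requires_amidation = FALSE,
                        min_match = 4L) {
  chars <- strsplit(p$seq, "", fixed = TRUE)[[1]]
  alts <- compile_pattern(pattern)
  nc <- length(chars)
  for (alt in alts) {
    L <- length(alt)
    if (anchor == "full") {
      if (!p$n_open && !p$c_open && nc == L &&
          (!requires_amidation || p$amidated) &&
          .match_elems(chars, alt)) return(TRUE)
      next
    }
    if (anchor == "Cterm") {
      if (!p$c_open && nc >= L &&
          (!requires_amidation || p$amidated) &&
          .match_elems(chars[(nc - L + 1L):nc], alt)) return(TRUE)
      if (p$c_open) {
        # the visible C-terminal residues may be a prefix of the motif
        for (k in seq_len(L - 1L)) {
          keep <- L - k
          if (keep < min_match || keep > nc) next
          if (.match_elems(chars[(nc - keep + 1L):nc],
                           alt[seq_len(keep)])) return(TRUE)
        }
      }
      next
    }
    if (anchor == "Nterm") {
      if (!p$n_open && nc >= L && .match_elems(chars[seq_len(L)], alt)) {
        return(TRUE)
      }
      if (p$n_open) {
        # the visible N-terminal residues may be a suffix of the motif
        for (k in seq_len(L - 1L)) {
          keep <- L - k
          if (keep < min_match || keep > nc) next
          if (.match_elems(chars[seq_len(keep)],
                           alt[(k + 1L):L])) return(TRUE)
        }
      }
      next
    }
    stop("unknown anchor: ", anchor)
  }
  FALSE
}

#' Read a family motif library
#'
#' Tab-separated, `#` comments: `family TAB anchor TAB pattern TAB
#' requires_amidation`. Library order is the classification precedence
#' order; full-sequence motifs should precede the C-terminal motifs they
#' would otherwise collide with (e.g. the myosuppressin full motif precedes
#' the FLRFamide C-terminal motif).
#'
#' @param path Path; default is the library shipped with the package.
#' @return `data.frame` with columns `family`, `anchor`, `pattern`,
#'   `requires_amidation`.
#' @export
read_motif_library <- function(path = system.file("extdata",
                                                  "family_motifs.tsv",
                                                  package = "pepmine")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lib <- data.frame(
    family = vapply(parts, `[`, "", 1L),
    anchor = vapply(parts, `[`, "", 2L),
    pattern = vapply(parts, `[`, "", 3L),
    requires_amidation = vapply(parts, `[`, "", 4L) %in%
      c("TRUE", "true", "1", "yes"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(lib$family)) {
    stop("family names must be unique in a motif library")
  }
  lib
}

#' Read an exact-sequence family template table
#'
#' Tab-separated, `#` comments: `structure TAB family`, where `structure`
#' uses the conventional rendering understood by [parse_peptide()]. Used for
#' families whose members are recognized by exact structure rather than a
#' short motif (e.g. the crustacean hyperglycemic hormones).
#'
#' @param path Path; default is the table shipped with the package.
#' @return `data.frame` with columns `key` (sequence + amidation key) and
#'   `family`.
#' @export
read_family_templates <- function(path = system.file("extdata",
                                                     "family_templates.tsv",
                                                     package = "pepmine")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  structs <- vapply(parts, `[`, "", 1L)
  fams <- vapply(parts, `[`, "", 2L)
  keys <- vapply(structs, function(s) {
    p <- parse_peptide(s)
    paste(p$seq, p$amidated, p$n_open, p$c_open, sep = "|")
  }, "")
  data.frame(key = unname(keys), family = fams, stringsAsFactors = FALSE)
}

.template_key <- function(p) {
  paste(p$seq, p$amidated, p$n_open, p$c_open, sep = "|")
}

#' Classify a mature peptide into a family
#'
#' Precedence: (1) exact-sequence template entries; (2) when the precursor's
#' family is known and the peptide matches that family's motif, the
#' precursor's family (disambiguating e.g. a myosuppressin-like
#' ...VFLRFamide from the FLRFamide family); (3) the first matching library
#' motif, in library order; (4) truncated peptides matched on the intact end
#' with at least `min_match` residues; (5) otherwise `"linker"`.
#'
#' @param p A `mature_peptide`.
#' @param lib Motif library ([read_motif_library()]).
#' @param templates Optional exact-template table ([read_family_templates()]).
#' @param precursor_family Optional family of the precursor of origin.
#' @param min_match Minimum matched residues for truncated peptides.
#' @return List with `family`, `matched_motif` (pattern or `NA`),
#'   `via_precursor`, `via_template`.
#' @export
classify_peptide <- function(p, lib = read_motif_library(), templates = NULL,
                             precursor_family = NULL, min_match = 4L) {
  if (!is.null(templates)) {
    hit <- match(.template_key(p), templates$key)
    if (!is.na(hit)) {
      return(list(family = templates$family[hit], matched_motif = NA_character_,
                  via_precursor = FALSE, via_template = TRUE))
    }
  }
  if (!is.null(precursor_family) && precursor_family %in% lib$family) {
    row <- lib[lib$family == precursor_family, ]
    if (match_motif(p, row$anchor, row$pattern, row$requires_amidation,
                    min_match)) {
      return(list(family = precursor_family, matched_motif = row$pattern,
                  via_precursor = TRUE, via_template = FALSE))
    }
  }
  for (i in seq_len(nrow(lib))) {
    if (match_motif(p, lib$anchor[i], lib$pattern[i],
                    lib$requires_amidation[i], min_match)) {
      return(list(family = lib$family[i], matched_motif = lib$pattern[i],
                  via_precursor = FALSE, via_template = FALSE))
    }
  }
  list(family = "linker", matched_motif = NA_character_,
       via_precursor = FALSE, via_template = FALSE)
}

#' Summarize per-family peptide counts
#'
#' @param assignments `data.frame` with columns `family`, `n_open`, `c_open`
#'   (one row per distinct peptide), e.g. from [run_predict()].
#' @return `data.frame` with `family`, `n_distinct`, `n_full`, `n_partial`
#'   plus a `total` row.
#' @export
summarize_counts <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(family = character(), n_distinct = integer(),
                      n_full = integer(), n_partial = integer(),
                      stringsAsFactors = FALSE))
  }
  partial <- assignments$n_open | assignments$c_open
  fams <- sort(unique(assignments$family))
  out <- data.frame(
    family = fams,
    n_distinct = vapply(fams, function(f)
      sum(assignments$family == f), 0L),
    n_full = vapply(fams, function(f)
      sum(assignments$family == f & !partial), 0L),
    n_partial = vapply(fams, function(f)
      sum(assignments$family == f & partial), 0L),
    stringsAsFactors = FALSE)
  rbind(out, data.frame(family = "total", n_distinct = nrow(assignments),
                        n_full = sum(!partial), n_partial = sum(partial),
                        stringsAsFactors = FALSE))
}
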