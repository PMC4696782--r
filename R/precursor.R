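#' Signal peptide prediction
#'
#' A deliberately simple, fully documented stand-in for dedicated predictors:
#' a candidate signal peptide requires a hydrophobic h-region of at least
#' `h_min` consecutive residues from `{A,I,L,F,V,M,W,C}` beginning within the
#' first 35 residues, and the cleavage site is chosen by the classical
#' (-3,-1) small-residue rule (residues at -3 and -1 relative to the mature
#' start must be in `{A,G,S,C,T,V}`), taking the first eligible position
#' whose -1 residue lies at or beyond the end of the h-region. Heuristic
#' calls are constrained to lengths 10-45. Annotation mode returns a supplied
#' span verbatim, so that curated signal peptides can override the heuristic.
#'
#' @param protein Amino-acid string; must begin with `M` in heuristic mode.
#' @param mode `"heuristic"` or `"annotation"`.
#' @param span For annotation mode, integer `c(start, end)` 0-based half-open;
#'   `start` must be 0.
#' @param h_min Minimum h-region length.
#' @return A list with `start`, `end` (0-based half-open) and `source`, or
#'   `NULL` when no signal peptide is predicted.
#' @export
predict_signal_peptide <- function(protein, mode = c("heuristic", "annotation"),
                                   span = NULL, h_min = 7L) {
  mode <- match.arg(mode)
  if (mode == "annotation") {
    if (is.null(span) || length(span) != 2L) {
      stop("annotation mode requires span = c(start, end)")
    }
    if (span[1] != 0L) stop("annotated signal peptide span must start at 0")
    if (span[2] > nchar(protein)) stop("signal span exceeds protein length")
    return(list(start = 0L, end = as.integer(span[2]), source = "annotation"))
  }
  if (substr(protein, 1L, 1L) != "M") {
    stop("heuristic signal prediction requires a protein starting with M")
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  hydro <- c("A", "I", "L", "F", "V", "M", "W", "C")
  small <- c("A", "G", "S", "C", "T", "V")
  is_h <- chars %in% hydro
  # first run of >= h_min hydrophobics starting at index 2..36 (1-based)
  run_start <- NA_integer_
  i <- 2L
  while (i <= min(length(chars), 36L)) {
    if (is_h[i]) {
      j <- i
      while (j < length(chars) && is_h[j + 1L]) j <- j + 1L
      if (j - i + 1L >= h_min) {
        run_start <- i
        run_end <- j
        break
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.na(run_start)) return(NULL)
  # Candidate cleavage positions: cc is the 0-based index of the first mature
  # residue, so the -1 residue is chars[cc] and the -3 residue chars[cc - 2]
  # in 1-based indexing. The -1 residue must lie at or beyond the first
  # position after the h-region (cc >= run_end + 1, run_end 1-based), both
  # -3 and -1 must be small, and the signal length cc must be within 10..45.
  lo <- max(10L, run_end + 1L)
  hi <- min(45L, length(chars) - 1L)
  if (lo <= hi) {
    for (cc in lo:hi) {
      if (chars[cc] %in% small && chars[cc - 2L] %in% small) {
        return(list(start = 0L, end = cc, source = "heuristic"))
      }
    }
  }
  NULL
}

#' Classify precursor completeness
#'
#' Implements the four-way completeness scheme for deduced proteins:
#' \describe{
#'   \item{F}{full-length: stop codons bracket the ORF, a start Met is
#'     present and a signal peptide is predicted. When the upstream stop is
#'     absent but a signal peptide starts at the start Met, the protein is
#'     still classed F with `putative_full = TRUE`.}
#'   \item{N}{amino-terminal partial: start Met + signal peptide but no stop
#'     codon terminates the ORF (the C-terminus is missing).}
#'   \item{C}{carboxyl-terminal partial: no stop before the ORF, no start Met
#'     producing a signal peptide, but a terminal stop (the N-terminus is
#'     missing).}
#'   \item{I}{internal fragment: everything else.}
#' }
#'
#' @param upstream_stop,start_met,terminal_stop Logical ORF flags.
#' @param has_signal Logical; was a signal peptide predicted (from the start
#'   Met)?
#' @return List with `class` (one of `"F","N","C","I"`) and `putative_full`.
#' @export
classify_completeness <- function(upstream_stop, start_met, terminal_stop,
                                  has_signal) {
  stopifnot(is.logical(upstream_stop), is.logical(start_met),
            is.logical(terminal_stop), is.logical(has_signal))
  if (upstream_stop && start_met && terminal_stop && has_signal) {
    list(class = "F", putative_full = FALSE)
  } else if (!upstream_stop && start_met && has_signal && terminal_stop) {
    list(class = "F", putative_full = TRUE)
  } else if (start_met && has_signal && !terminal_stop) {
    list(class = "N", putative_full = FALSE)
  } else if (!upstream_stop && !(start_met && has_signal) && terminal_stop) {
    list(class = "C", putative_full = FALSE)
  } else {
    list(class = "I", putative_full = FALSE)
  }
}

#' Build a precursor from an ORF
#'
#' Trims the ORF protein to its first Met when one is present (the deduced
#' protein starts at the start Met; the raw ORF is a stop-to-stop stretch),
#' predicts or accepts a signal peptide, and attaches the completeness class.
#'
#' @param orf One-row data frame (or list) as returned by [extract_orfs()].
#' @param name Precursor name.
#' @param signal_mode `"heuristic"` or `"annotation"`.
#' @param signal_span For annotation mode, the 0-based half-open span on the
#'   trimmed protein; use `NULL` in annotation mode to assert no signal.
#' @param min_len Minimum precursor length in aa; shorter ORFs return `NULL`.
#' @return An object of class `"precursor"`: list with `name`, `protein`,
#'   `completeness`, `putative_full`, `signal`, `source_orf`; or `NULL`.
#' @export
build_precursor <- function(orf, name, signal_mode = c("heuristic", "annotation"),
                            signal_span = NULL, min_len = 30L) {
  signal_mode <- match.arg(signal_mode)
  orf <- as.list(orf)
  protein <- orf$protein
  met <- regexpr("M", protein, fixed = TRUE)
  start_met <- met > 0L
  if (start_met) protein <- substr(protein, met, nchar(protein))
  if (nchar(protein) < min_len) return(NULL)
  signal <- NULL
  if (start_met) {
    signal <- if (signal_mode == "annotation") {
      if (is.null(signal_span)) NULL else
        predict_signal_peptide(protein, "annotation", span = signal_span)
    } else {
      predict_signal_peptide(protein, "heuristic")
    }
  } else if (signal_mode == "annotation" && !is.null(signal_span)) {
    stop("annotated signal peptide on a protein without a start Met: ", name)
  }
  if (!is.null(signal) && signal$end > nchar(protein)) {
    stop("signal span exceeds protein length for ", name)
  }
  comp <- classify_completeness(isTRUE(orf$upstream_stop), start_met,
                                isTRUE(orf$terminal_stop), !is.null(signal))
  structure(list(name = name, protein = protein,
                 completeness = comp$class, putative_full = comp$putative_full,
                 signal = signal, source_orf = orf),
            class = "precursor")
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor> %s  [%s%s]  %d aa\n", x$name, x$completeness,
              if (isTRUE(x$putative_full)) "*" else "", nchar(x$protein)))
  if (!is.null(x$signal)) {
    cat(sprintf("  signal peptide: [0,%d) (%s)\n", x$signal$end,
                x$signal$source))
  }
  cat("  ", x$protein, "\n", sep = "")
  invisible(x)
}

#' Select the candidate ORF of a transcript
#'
#' When a transcript contains several ORFs, the candidate is the ORF
#' overlapping the best homology hit (same frame, overlapping protein
#' coordinates); without a hit, the longest ORF. Length selection alone is
#' unreliable on real data because the antisense frame of a coding region
#' is itself depleted of stop codons.
#'
#' @param orfs Data frame from [extract_orfs()] (one transcript).
#' @param hit Optional one-row hit (list/data frame with `frame`, `s_start`,
#'   `s_end`) from [translated_search()].
#' @return The selected ORF row, or `NULL` when `orfs` is empty.
#' @export
select_orf <- function(orfs, hit = NULL) {
  if (nrow(orfs) == 0L) return(NULL)
  if (!is.null(hit)) {
    hit <- as.list(hit)
    cand <- orfs[orfs$frame == hit$frame & orfs$aa_start < hit$s_end &
                   orfs$aa_end > hit$s_start, , drop = FALSE]
    if (nrow(cand) > 0L) {
      return(cand[which.max(nchar(cand$protein)), , drop = FALSE])
    }
  }
  orfs[which.max(nchar(orfs$protein)), , drop = FALSE]
}

#' Read a precursor annotation sidecar file
#'
#' Plain-text, `#`-comment lines allowed. Each line:
#' `name TAB signal_end TAB cleavage_positions` where `cleavage_positions` is
#' a comma-separated list of 0-based positions of the first basic residue of
#' each cleavage site (may be empty). `signal_end` of 0 means no signal
#' peptide.
#'
#' @param path Path to the sidecar file.
#' @return Named list; each element has `signal_end` and `cleavage_pos`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed annotation line: ", ln)
    pos <- integer(0)
    if (length(parts) >= 3L && nzchar(parts[3])) {
      pos <- as.integer(strsplit(parts[3], ",", fixed = TRUE)[[1]])
    }
    out[[parts[1]]] <- list(signal_end = as.integer(parts[2]),
                            cleavage_pos = pos)
  }
  out
}
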