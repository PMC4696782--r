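#' Cleavage ruleset configuration
#'
#' Defaults reflect the standard prohormone-convertase conventions used for
#' arthropod precursors: all KR and RR dibasics cleave; KK and RK dibasics
#' cleave when enabled (enabled by default, flagged low-confidence);
#' monobasic K or R cleaves only when another basic residue lies at relative
#' position -4, -6 or -8 and the residue following the site is not proline.
#' No site may fall inside the signal peptide. Overlapping dibasics are
#' resolved leftmost-first; a residue belongs to at most one site.
#'
#' @param dibasic_secondary Cleave KK/RK dibasics?
#' @param monobasic Allow monobasic sites (with the -4/-6/-8 rule)?
#' @return A list of class `"cleavage_rules"`.
#' @export
cleavage_rules <- function(dibasic_secondary = TRUE, monobasic = TRUE) {
  structure(list(dibasic_secondary = dibasic_secondary,
                 monobasic = monobasic),
            class = "cleavage_rules")
}

.empty_sites <- function() {
  data.frame(pos = integer(), kind = character(), width = integer(),
             source = character(), low_confidence = logical(),
             stringsAsFactors = FALSE)
}

#' Find prohormone-convertase cleavage sites
#'
#' @param prec A [build_precursor()] object, or an amino-acid string (in
#'   which case `signal_end` gives the first position eligible for sites).
#' @param ruleset A [cleavage_rules()] object (rule mode), or `"annotation"`
#'   to use `annotation_pos`.
#' @param signal_end 0-based end of the signal peptide (0 when absent).
#' @param annotation_pos Integer vector of 0-based positions of the first
#'   basic residue of each site (annotation mode).
#' @return A `data.frame`: `pos` (0-based first basic residue), `kind`
#'   (`KR`, `RR`, `KK`, `RK`, `mono_R`, `mono_K`), `width` (1 or 2),
#'   `source`, `low_confidence`.
#' @export
find_cleavage_sites <- function(prec, ruleset = cleavage_rules(),
                                signal_end = NULL, annotation_pos = NULL) {
  if (inherits(prec, "precursor")) {
    protein <- prec$protein
    if (is.null(signal_end)) {
      signal_end <- if (is.null(prec$signal)) 0L else prec$signal$end
    }
    name <- prec$name
  } else {
    protein <- prec
    if (is.null(signal_end)) signal_end <- 0L
    name <- "<protein>"
  }
  if (nchar(protein) == 0L) stop("precursor protein is empty")
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  basic <- chars %in% c("K", "R")

  if (identical(ruleset, "annotation")) {
    if (is.null(annotation_pos)) annotation_pos <- integer(0)
    annotation_pos <- sort(as.integer(annotation_pos))
    rows <- list()
    taken <- rep(FALSE, length(chars))
    for (p in annotation_pos) {
      i <- p + 1L
      if (i < 1L || i > length(chars) || !basic[i]) {
        stop(sprintf("annotated cleavage position %d of %s is not K/R", p,
                     name))
      }
      width <- if (i < length(chars) && basic[i + 1L] &&
                   !((p + 1L) %in% annotation_pos) && !taken[i + 1L]) 2L else 1L
      kind <- if (width == 2L) paste0(chars[i], chars[i + 1L]) else
        paste0("mono_", chars[i])
      taken[i:(i + width - 1L)] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, kind = kind, width = width, source = "annotation",
        low_confidence = FALSE, stringsAsFactors = FALSE)
    }
    sites <- if (length(rows)) do.call(rbind, rows) else .empty_sites()
    return(sites[order(sites$pos), , drop = FALSE])
  }

  stopifnot(inherits(ruleset, "cleavage_rules"))
  primary <- c("KR", "RR")
  secondary <- c("KK", "RK")
  rows <- list()
  i <- signal_end + 1L  # 1-based scan start (first residue after the signal)
  while (i <= length(chars)) {
    if (!basic[i]) {
      i <- i + 1L
      next
    }
    pair <- if (i < length(chars)) paste0(chars[i], chars[i + 1L]) else ""
    if (pair %in% primary ||
        (ruleset$dibasic_secondary && pair %in% secondary)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pos = i - 1L, kind = pair, width = 2L, source = "rule",
        low_confidence = pair %in% secondary, stringsAsFactors = FALSE)
      i <- i + 2L
      next
    }
    if (ruleset$monobasic) {
      upstream <- i - c(4L, 6L, 8L)
      upstream <- upstream[upstream >= 1L]
      has_helper <- any(basic[upstream])
      not_pro <- i == length(chars) || chars[i + 1L] != "P"
      if (has_helper && not_pro) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = i - 1L, kind = paste0("mono_", chars[i]), width = 1L,
          source = "rule", low_confidence = FALSE, stringsAsFactors = FALSE)
      }
    }
    i <- i + 1L
  }
  if (length(rows)) do.call(rbind, rows) else .empty_sites()
}

#' Excise raw peptide fragments from a precursor
#'
#' Fragments are the maximal stretches between the signal-peptide end and
#' successive cleavage sites; the basic residues of each site belong to
#' neither flanking fragment. Empty fragments are dropped. Boundary flags
#' mark truncation at a partial-precursor boundary: the first fragment of a
#' C- or I-type precursor is `n_open` (its true N-terminus is missing), and
#' the last fragment of an N- or I-type precursor is `c_open`.
#'
#' @param prec A precursor object (or amino-acid string plus `signal_end` and
#'   `completeness`).
#' @param sites Data frame from [find_cleavage_sites()].
#' @param signal_end,completeness Used when `prec` is a bare string.
#' @return `data.frame`: `seq`, `start` (0-based position in the precursor),
#'   `n_open`, `c_open`, `followed_by_site`, `removed` (basic residues of the
#'   following site, `""` for the last fragment).
#' @export
excise_fragments <- function(prec, sites, signal_end = NULL,
                             completeness = NULL) {
  if (inherits(prec, "precursor")) {
    protein <- prec$protein
    if (is.null(signal_end)) {
      signal_end <- if (is.null(prec$signal)) 0L else prec$signal$end
    }
    if (is.null(completeness)) completeness <- prec$completeness
  } else {
    protein <- prec
    if (is.null(signal_end)) signal_end <- 0L
    if (is.null(completeness)) completeness <- "F"
  }
  sites <- sites[order(sites$pos), , drop = FALSE]
  n <- nchar(protein)
  starts <- c(signal_end, sites$pos + sites$width)
  ends <- c(sites$pos, n)  # 0-based half-open fragment spans
  frag <- data.frame(
    seq = substring(protein, starts + 1L, ends),
    start = starts,
    removed = c(substring(protein, sites$pos + 1L, sites$pos + sites$width),
                ""),
    followed_by_site = c(rep(TRUE, nrow(sites)), FALSE),
    stringsAsFactors = FALSE)
  frag <- frag[nchar(frag$seq) > 0L, , drop = FALSE]
  rownames(frag) <- NULL
  frag$n_open <- FALSE
  frag$c_open <- FALSE
  if (nrow(frag) > 0L) {
    if (completeness %in% c("C", "I")) frag$n_open[1L] <- TRUE
    if (completeness %in% c("N", "I")) frag$c_open[nrow(frag)] <- TRUE
  }
  frag
}

#' PTM prediction configuration
#'
#' @param pyroglu_E One of `"never"`, `"template"`, `"always"`: whether an
#'   N-terminal glutamic acid cyclizes to pyroglutamate (glutamine always
#'   cyclizes on closed-ended peptides).
#' @param cterm_amidation_via_template Allow amidation of a precursor's own
#'   C-terminal fragment only when a template lists the peptide.
#' @return List of class `"ptm_config"`.
#' @export
ptm_config <- function(pyroglu_E = c("template", "never", "always"),
                       cterm_amidation_via_template = TRUE) {
  pyroglu_E <- match.arg(pyroglu_E)
  structure(list(pyroglu_E = pyroglu_E,
                 cterm_amidation_via_template = cterm_amidation_via_template),
            class = "ptm_config")
}

#' Apply post-translational modifications to an excised fragment
#'
#' Rules: a fragment ending in glycine that was followed by a cleavage site
#' loses the glycine and becomes C-terminally amidated (amidation at the
#' precursor's own C-terminus needs a template listing); an N-terminal
#' glutamine cyclizes to pyroglutamate on peptides with both ends intact
#' (glutamic acid cyclization is template-gated by default); tyrosine
#' sulfation comes only from templates; disulfides are assigned automatically
#' for exactly-two-cysteine peptides, by template when more cysteines are
#' present, and only for full-length peptides.
#'
#' @param fragment One row of [excise_fragments()] output (or a list with the
#'   same fields).
#' @param config A [ptm_config()].
#' @param templates Optional template table from [read_ptm_templates()].
#' @param precursor Name of the precursor of origin.
#' @return An object of class `"mature_peptide"`.
#' @export
apply_ptms <- function(fragment, config = ptm_config(), templates = NULL,
                       precursor = NA_character_) {
  fragment <- as.list(fragment)
  seq <- fragment$seq
  if (nchar(seq) == 0L) stop("empty fragment")
  n_open <- isTRUE(fragment$n_open)
  c_open <- isTRUE(fragment$c_open)
  followed <- isTRUE(fragment$followed_by_site)

  tpl <- NULL
  amidated <- FALSE
  # amidation: trailing G consumed when a site followed, or when a template
  # grants amidation at the precursor C-terminus
  if (!c_open && endsWith(seq, "G")) {
    core <- substr(seq, 1L, nchar(seq) - 1L)
    if (followed) {
      amidated <- TRUE
      seq <- core
    } else if (isTRUE(config$cterm_amidation_via_template) &&
               !is.null(templates) && core %in% templates$seq &&
               "amide_Cterm" %in% .tpl_directives(templates, core)) {
      amidated <- TRUE
      seq <- core
    }
  }
  if (is.null(tpl) && !is.null(templates) && seq %in% templates$seq) {
    tpl <- .tpl_directives(templates, seq)
  }

  pyroglu <- FALSE
  first <- substr(seq, 1L, 1L)
  if (!n_open && !c_open) {
    if (first == "Q") {
      pyroglu <- TRUE
    } else if (first == "E") {
      pyroglu <- switch(config$pyroglu_E,
                        always = TRUE,
                        template = !is.null(tpl) && "pyroglu_E" %in% tpl,
                        never = FALSE)
    }
  }

  sulfated <- integer(0)
  disulfides <- list()
  full_length <- !n_open && !c_open
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (full_length) {
    if (!is.null(tpl)) {
      for (d in tpl) {
        if (startsWith(d, "sulfo:")) {
          pos <- as.integer(sub("^sulfo:Y", "", d))
          if (is.na(pos) || pos + 1L > length(chars) ||
              chars[pos + 1L] != "Y") {
            stop("sulfation template references a non-Tyr residue in ", seq)
          }
          sulfated <- c(sulfated, pos)
        }
        if (startsWith(d, "ss:")) {
          cys <- which(chars == "C")
          pairs <- strsplit(sub("^ss:", "", d), ",", fixed = TRUE)[[1]]
          for (pr in pairs) {
            ij <- as.integer(strsplit(pr, "-", fixed = TRUE)[[1]])
            if (any(is.na(ij)) || any(ij > length(cys)) || ij[1] == ij[2]) {
              stop("disulfide template references absent cysteines in ", seq)
            }
            disulfides[[length(disulfides) + 1L]] <- cys[ij] - 1L
          }
        }
      }
    }
    if (length(disulfides) == 0L) {
      cys <- which(chars == "C")
      if (length(cys) == 2L) disulfides <- list(cys - 1L)
      # > 2 cysteines without a template: left unassigned
    }
  }

  structure(list(seq = seq, amidated = amidated, pyroglu = pyroglu,
                 sulfated = sort(unique(sulfated)), disulfides = disulfides,
                 n_open = n_open, c_open = c_open,
                 precursor = precursor),
            class = "mature_peptide")
}

.tpl_directives <- function(templates, seq) {
  d <- templates$directives[match(seq, templates$seq)]
  if (is.na(d) || !nzchar(d)) character(0) else
    strsplit(d, ";", fixed = TRUE)[[1]]
}

#' Read a PTM template file
#'
#' Plain text, `#` comments; lines are `seq TAB ptm_directives`, e.g.
#' `sulfo:Y5;ss:1-3,2-7;pyroglu_E;amide_Cterm`. Sulfation positions are
#' 0-based residue indices on the mature (glycine-trimmed) peptide;
#' disulfide pairs are 1-based cysteine ordinals.
#'
#' @param path Path to the template file.
#' @return `data.frame` with columns `seq`, `directives`.
#' @export
read_ptm_templates <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(seq = character(), directives = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(seq = vapply(parts, `[`, "", 1L),
             directives = vapply(parts, function(p)
               if (length(p) >= 2L) p[2] else "", ""),
             stringsAsFactors = FALSE)
}

#' Process a precursor into mature peptides
#'
#' Convenience wrapper: cleavage-site identification, excision and PTM
#' decoration in one call.
#'
#' @param prec A precursor object.
#' @param ruleset A [cleavage_rules()] object or `"annotation"`.
#' @param annotation_pos Annotated 0-based site positions (annotation mode).
#' @param config A [ptm_config()].
#' @param templates Optional PTM template table.
#' @return List of `mature_peptide` objects.
#' @export
process_precursor <- function(prec, ruleset = cleavage_rules(),
                              annotation_pos = NULL, config = ptm_config(),
                              templates = NULL) {
  sites <- find_cleavage_sites(prec, ruleset, annotation_pos = annotation_pos)
  frags <- excise_fragments(prec, sites)
  lapply(seq_len(nrow(frags)), function(i)
    apply_ptms(frags[i, ], config, templates, precursor = prec$name))
}

#' Distinctness key for a mature peptide
#' @keywords internal
peptide_key <- function(p) {
  paste(p$seq, p$amidated, p$pyroglu,
        paste(p$sulfated, collapse = ","),
        paste(vapply(p$disulfides, paste, "", collapse = "-"),
              collapse = ","),
        p$n_open, p$c_open, sep = "|")
}

#' Deduplicate mature peptides
#'
#' Distinctness covers the sequence and the full PTM/truncation state
#' (`seq`, `amidated`, `pyroglu`, `sulfated`, `disulfides`, `n_open`,
#' `c_open`); the precursor of origin is not part of the key, so identical
#' peptides arising from different precursors collapse. First-occurrence
#' order is preserved.
#'
#' @param peptides List of `mature_peptide` objects.
#' @return List of distinct `mature_peptide` objects.
#' @export
deduplicate <- function(peptides) {
  keys <- vapply(peptides, peptide_key, "")
  peptides[!duplicated(keys)]
}

#' Render a mature peptide in conventional notation
#'
#' `pQ`/`pE` marks an N-terminal pyroglutamate, a trailing `a` marks a
#' C-terminal amide, `Y(SO3H)` a sulfated tyrosine, and `+` an open
#' (truncated) terminus. Disulfides are not rendered inline.
#'
#' @param p A `mature_peptide`.
#' @return Character scalar.
#' @export
render_peptide <- function(p) {
  chars <- strsplit(p$seq, "", fixed = TRUE)[[1]]
  if (length(p$sulfated)) {
    chars[p$sulfated + 1L] <- paste0(chars[p$sulfated + 1L], "(SO3H)")
  }
  body <- paste(chars, collapse = "")
  if (p$pyroglu) body <- paste0("p", body)
  paste0(if (p$n_open) "+" else "", body,
         if (p$amidated) "a" else "",
         if (p$c_open) "+" else "")
}

#' Parse conventional peptide notation into a mature peptide
#'
#' Inverse of [render_peptide()] (disulfides, which the notation does not
#' carry inline, are restored as empty).
#'
#' @param structure Character scalar, e.g. `"pQDLDHVFLRFa"` or `"PSFNAW+"`.
#' @param precursor Optional precursor-of-origin name.
#' @return A `mature_peptide`.
#' @export
parse_peptide <- function(structure, precursor = NA_character_) {
  s <- structure
  n_open <- startsWith(s, "+")
  if (n_open) s <- substring(s, 2L)
  c_open <- endsWith(s, "+")
  if (c_open) s <- substring(s, 1L, nchar(s) - 1L)
  pyroglu <- grepl("^p[QE]", s)
  if (pyroglu) s <- substring(s, 2L)
  amidated <- FALSE
  if (endsWith(s, "a")) {
    amidated <- TRUE
    s <- substring(s, 1L, nchar(s) - 1L)
  }
  sulfated <- integer(0)
  while (grepl("(SO3H)", s, fixed = TRUE)) {
    at <- regexpr("(SO3H)", s, fixed = TRUE)
    sulfated <- c(sulfated, at - 2L)  # 0-based index of the Y before the tag
    s <- paste0(substr(s, 1L, at - 1L),
                substring(s, at + attr(at, "match.length")))
  }
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", s)) {
    stop("unparseable peptide structure: ", structure)
  }
  structure(list(seq = s, amidated = amidated, pyroglu = pyroglu,
                 sulfated = sulfated, disulfides = list(),
                 n_open = n_open, c_open = c_open, precursor = precursor),
            class = "mature_peptide")
}

#' @export
print.mature_peptide <- function(x, ...) {
  mods <- c(if (x$amidated) "amidated", if (x$pyroglu) "pyroGlu",
            if (length(x$sulfated)) paste0("sulfoY@",
                                           paste(x$sulfated, collapse = ",")),
            if (length(x$disulfides)) paste0(length(x$disulfides),
                                             " disulfide(s)"))
  cat(sprintf("<peptide> %s%s\n", render_peptide(x),
              if (length(mods)) paste0("  [", paste(mods, collapse = "; "),
                                       "]") else ""))
  invisible(x)
}
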