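#' Kyte-Doolittle hydropathy values
#' @keywords internal
.kd_scale <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9,
               A = 1.8, G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3,
               P = -1.6, H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5,
               K = -3.9, R = -4.5, X = 0)

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of the standard Kyte-Doolittle residue values;
#' positions near the ends use truncated windows so the profile has one
#' value per residue. Unknown residues (`X`) contribute 0.
#'
#' @param protein Amino-acid string.
#' @param window Odd window width (the canonical transmembrane setting is 19).
#' @return Numeric vector, `length == nchar(protein)`.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  vals <- unname(.kd_scale[chars])
  if (anyNA(vals)) {
    stop("unknown residue(s): ",
         paste(unique(chars[is.na(vals)]), collapse = ", "))
  }
  half <- (window - 1L) %/% 2L
  n <- length(vals)
  # the scale is in tenths: integer window sums are exact, so profiles are
  # reproducible under translation and threshold comparisons never depend
  # on accumulated floating-point error
  cs <- cumsum(c(0L, as.integer(round(vals * 10))))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (10 * (hi - lo + 1L))
}

#' Detect transmembrane segments from a hydropathy profile
#'
#' Maximal runs of windowed hydropathy at or above `threshold` of length at
#' least `min_len`; runs separated by fewer than `min_gap` positions are
#' merged first.
#'
#' @param profile Numeric vector from [hydropathy_profile()].
#' @param threshold Hydropathy threshold.
#' @param min_len Minimum segment length (residues).
#' @param min_gap Runs closer than this are merged.
#' @return `data.frame` with 0-based half-open `start`, `end` columns.
#' @export
detect_tm_segments <- function(profile, threshold = 1.6, min_len = 15L,
                               min_gap = 3L) {
  above <- profile >= threshold
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by small gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, , drop = FALSE]
  data.frame(start = merged$start - 1L, end = merged$end)
}

#' Characterize a receptor protein
#'
#' Superfamily assignment is by homology: the reciprocal-best-hit panel
#' member's superfamily label wins. The transmembrane count from the
#' hydropathy profile corroborates the call (7 +/- 1 segments is considered
#' consistent with a GPCR); a discordant count is reported but never
#' overrides the label, and partial proteins never fail the check. With no
#' panel hit the superfamily is `"unknown"`.
#'
#' @param protein_id,protein Identifier and amino-acid sequence.
#' @param panel Reference panel `data.frame` with `id`, `seq`, `superfamily`.
#' @param back_db Database for the reciprocal search (see
#'   [reciprocal_best_hit()]); defaults to the query alone.
#' @param completeness Completeness class of the protein (`F/N/C/I`).
#' @param params A [search_params()].
#' @param window,threshold,min_len,min_gap Hydropathy/TM parameters.
#' @return List of class `"receptor_annotation"`: `protein_id`,
#'   `tm_segments`, `tm_count`, `superfamily`, `panel_assignment`,
#'   `tm_consistent`, `completeness`.
#' @export
classify_receptor <- function(protein_id, protein, panel, back_db = NULL,
                              completeness = "F", params = search_params(),
                              window = 19L, threshold = 1.6, min_len = 15L,
                              min_gap = 3L) {
  prof <- hydropathy_profile(protein, window)
  tm <- detect_tm_segments(prof, threshold, min_len, min_gap)
  if (is.null(back_db)) {
    back_db <- data.frame(id = protein_id, seq = protein,
                          stringsAsFactors = FALSE)
  }
  pa <- if (nrow(panel) > 0L) {
    reciprocal_best_hit(protein_id, protein, panel, back_db, params)
  } else NULL
  superfamily <- "unknown"
  if (!is.null(pa) && "superfamily" %in% names(panel)) {
    superfamily <- panel$superfamily[panel$id == pa$best_panel_member][1L]
  }
  gpcr <- superfamily %in% c("rhodopsin_like_GPCR", "secretin_like_GPCR")
  tm_consistent <- if (completeness != "F") {
    NA  # partial proteins never fail the TM check
  } else if (gpcr) {
    abs(nrow(tm) - 7L) <= 1L
  } else {
    NA
  }
  structure(list(protein_id = protein_id, tm_segments = tm,
                 tm_count = nrow(tm), superfamily = superfamily,
                 panel_assignment = pa, tm_consistent = tm_consistent,
                 completeness = completeness),
            class = "receptor_annotation")
}

#' @export
print.receptor_annotation <- function(x, ...) {
  cat(sprintf("<receptor> %s  %s  %d TM segment(s)  [%s]%s\n",
              x$protein_id, x$superfamily, x$tm_count, x$completeness,
              if (isFALSE(x$tm_consistent)) "  (TM count discordant)" else ""))
  invisible(x)
}
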