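# Independent oracles used by the tests. These deliberately avoid the code
# paths (and, where feasible, the libraries) they are checking.

# -- minimal standard-code translator (independent of Biostrings) -----------
.oracle_codons <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(bases, bases, paste0)))
  codons <- as.vector(vapply(bases, function(b1)
    paste0(b1, codons[1:16]), character(16)))
  stats::setNames(aa, codons)
})

oracle_translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  cod <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  aa <- .oracle_codons[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# brute-force stop-free stretch scan for one frame translation
oracle_stretches <- function(aa, min_aa) {
  chars <- strsplit(aa, "")[[1]]
  out <- list()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "*") { i <- i + 1; next }
    j <- i
    while (j < length(chars) && chars[j + 1] != "*") j <- j + 1
    if (j - i + 1 >= min_aa) {
      out[[length(out) + 1]] <- list(
        start = i - 1, end = j,
        protein = paste(chars[i:j], collapse = ""),
        upstream_stop = i > 1,
        start_met = chars[i] == "M",
        terminal_stop = j < length(chars))
    }
    i <- j + 1
  }
  out
}

# -- BLOSUM62 lookup (the matrix itself is data, shared with the package) ---
.b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# -- exhaustive enumeration of all global alignments with affine gaps -------
# gap of length L costs gap_open + gap_extend * L
oracle_enum_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, .b62[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- gap_extend + if (state == "B") 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, "B"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- gap_extend + if (state == "A") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, "A"))
    }
    best
  }
  rec(1, 1, "M")
}

# -- independent affine-gap DP (Gotoh), plain R -----------------------------
oracle_gotoh_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + gap_extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + gap_extend * (j - 1))
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1) {
        M[i, j] <- .b62[ca[i - 1], cb[j - 1]] +
          max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      }
      if (i > 1) {
        X[i, j] <- max(X[i, j],
                       M[i - 1, j] - gap_open - gap_extend,
                       X[i - 1, j] - gap_extend,
                       Y[i - 1, j] - gap_open - gap_extend)
      }
      if (j > 1) {
        Y[i, j] <- max(Y[i, j],
                       M[i, j - 1] - gap_open - gap_extend,
                       X[i, j - 1] - gap_open - gap_extend,
                       Y[i, j - 1] - gap_extend)
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein <- function(len,
                           alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# build a precursor object directly from a generator result
precursor_from_truth <- function(gp, name = "syn", completeness = "F") {
  structure(list(name = name, protein = gp$protein,
                 completeness = completeness, putative_full = FALSE,
                 signal = list(start = 0L, end = gp$truth$signal_end,
                               source = "annotation"),
                 source_orf = NULL),
            class = "precursor")
}

fixture_path <- function(name) system.file("extdata", name,
                                           package = "pepmine")
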