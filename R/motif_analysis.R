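## Breakpoint-anchored motif summaries: right-justified stacking of
## candidate sequences, position frequency matrix, per-column information
## content (logo heights in bits), terminal composition and occurrence
## scanning.

#' Breakpoint-anchored alignment
#'
#' Candidates are reported 5' to 3' with the breakpoint at the 3' terminus,
#' so they are already registered at their last base: stacking is
#' right-justified, with shorter sequences contributing nothing to leading
#' columns. No gaps are introduced.
#'
#' @param candidates character vector of candidate sequences (or a
#'   candidate `data.frame` with a `sequence` column)
#' @return an `AnchoredAlignment`: list with `matrix` (rows = sequences,
#'   columns = positions, `NA` where a sequence does not reach) and `depth`
#' @export
anchor_align <- function(candidates) {
  if (is.data.frame(candidates)) candidates <- candidates$sequence
  candidates <- toupper(as.character(candidates))
  if (length(candidates) == 0L) stop("no candidate sequences")
  check_dna(candidates)
  depth <- max(nchar(candidates))
  mat <- matrix(NA_character_, nrow = length(candidates), ncol = depth)
  for (i in seq_along(candidates)) {
    x <- strsplit(candidates[i], "", fixed = TRUE)[[1L]]
    mat[i, (depth - length(x) + 1L):depth] <- x
  }
  structure(list(matrix = mat, depth = depth), class = "AnchoredAlignment")
}

#' Position frequency matrix
#'
#' Per-column base counts over A/C/G/T (`N` is ignored, i.e. does not
#' contribute to `n_effective`). Probabilities are
#' `(count + pseudocount) / (n_effective + 4 * pseudocount)`.
#'
#' @param alignment an [anchor_align()] result
#' @param pseudocount non-negative pseudocount (default 0)
#' @return a `PositionFrequencyMatrix`: list with `counts` (4 x depth),
#'   `n_effective` (per column), `probs` (4 x depth), `pseudocount`
#' @export
build_pfm <- function(alignment, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  bases <- c("A", "C", "G", "T")
  depth <- alignment$depth
  counts <- matrix(0L, 4L, depth, dimnames = list(bases, NULL))
  for (j in seq_len(depth)) {
    col <- alignment$matrix[, j]
    col <- col[!is.na(col) & col != "N"]
    counts[, j] <- tabulate(match(col, bases), 4L)
  }
  n_eff <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2L, n_eff + 4 * pseudocount, "/")
  probs[, n_eff + 4 * pseudocount == 0] <- NA_real_
  structure(list(counts = counts, n_effective = n_eff, probs = probs,
                 pseudocount = pseudocount),
            class = "PositionFrequencyMatrix")
}

#' Per-column information content in bits
#'
#' `IC_j = 2 + sum_b p_b log2 p_b` with `0 * log 0 = 0`; 2 bits for an
#' invariant column, 0 for a uniform one. Columns with no contributing
#' sequences are `NA`.
#'
#' @param pfm a [build_pfm()] result
#' @return numeric vector of length `depth`, values in `[0, 2]`
#' @export
information_content <- function(pfm) {
  apply(pfm$probs, 2L, function(p) {
    if (anyNA(p)) return(NA_real_)
    nz <- p[p > 0]
    2 + sum(nz * log2(nz))
  })
}

#' Terminal composition of candidate sequences
#'
#' Counts the breakpoint-proximal terminal k-mers (the last `k` bases of
#' each reporting-oriented candidate), the fraction ending in `GGG`, and the
#' thymine fraction over all bases of all candidates. Candidates shorter
#' than `k` are excluded with a message.
#'
#' @param candidates character vector or candidate `data.frame`
#' @param k terminal k-mer length (default 3)
#' @return list with `terminal_counts` (named integer vector),
#'   `ggg_fraction`, `t_fraction`, `n_used`
#' @export
terminal_composition <- function(candidates, k = 3L) {
  if (is.data.frame(candidates)) candidates <- candidates$sequence
  candidates <- toupper(as.character(candidates))
  short <- nchar(candidates) < k
  if (any(short))
    message(sum(short), " candidate(s) shorter than k = ", k, " excluded")
  used <- candidates[!short]
  kmers <- substr(used, nchar(used) - k + 1L, nchar(used))
  tc <- sort(table(kmers), decreasing = TRUE)
  allb <- paste(candidates, collapse = "")
  tf <- if (nchar(allb)) {
    sum(strsplit(allb, "", fixed = TRUE)[[1L]] == "T") / nchar(allb)
  } else NA_real_
  list(
    terminal_counts = setNames(as.integer(tc), names(tc)),
    ggg_fraction = if (length(used)) mean(kmers == strrep("G", k)) else NA_real_,
    t_fraction = tf,
    n_used = length(used)
  )
}

#' Count motif occurrences in a sequence
#'
#' Slides the consensus along both strands of `sequence`, counting every
#' (possibly overlapping) window with at most `max_mismatches` mismatches.
#' Matches on the two strands are counted separately, so a palindromic
#' consensus at one site counts twice. `N` never matches.
#'
#' @param consensus motif string
#' @param sequence subject DNA string
#' @param max_mismatches allowed mismatches per window (default 0)
#' @return integer occurrence count
#' @export
scan_occurrences <- function(consensus, sequence, max_mismatches = 0L) {
  consensus <- toupper(consensus); sequence <- toupper(sequence)
  check_dna(consensus); check_dna(sequence)
  k <- nchar(consensus); n <- nchar(sequence)
  if (k > n) stop("consensus longer than sequence")
  count_one <- function(pat) {
    p <- strsplit(pat, "", fixed = TRUE)[[1L]]
    s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    hits <- 0L
    for (i in 1:(n - k + 1L)) {
      w <- s[i:(i + k - 1L)]
      mm <- sum(w != p | w == "N" | p == "N")
      if (mm <= max_mismatches) hits <- hits + 1L
    }
    hits
  }
  count_one(consensus) + count_one(reverse_complement(consensus))
}

#' Logo table: per-column base heights in bits
#'
#' Numeric serialisation of a sequence logo: each base's height is
#' `p_b * IC_j`, so column heights sum to the information content.
#'
#' @param pfm a [build_pfm()] result
#' @return `data.frame` with columns `column`, `A`, `C`, `G`, `T`,
#'   `information_bits`, `n_effective`
#' @export
logo_table <- function(pfm) {
  ic <- information_content(pfm)
  h <- sweep(pfm$probs, 2L, ic, "*")
  data.frame(column = seq_len(ncol(h)),
             A = h["A", ], C = h["C", ], G = h["G", ], T = h["T", ],
             information_bits = ic, n_effective = pfm$n_effective,
             row.names = NULL)
}
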