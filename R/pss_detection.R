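## Signal-sequence detection at SV breakpoints: inverted-orientation flank
## alignment (criterion i), short-repeat exclusion (criterion ii) and
## control-cohort subtraction (criterion iii).

#' Detection configuration
#'
#' @param flank_window flank length in bases extracted at each breakpoint
#'   (default 20)
#' @param min_identity minimum inverted-alignment identity (default 0.50,
#'   "at least 50 percent identity")
#' @param max_offset maximum alignment start offset from the breakpoint, in
#'   bases (default 3: strictly less than 4 bp from the breakpoint)
#' @param min_aligned_len minimum ungapped aligned length (default 10)
#' @param max_repeat_len homopolymer / tandem tract length above which a
#'   candidate is disqualified (default 5)
#' @param control_identity identity at or above which a candidate matching a
#'   passing control alignment is removed (default 0.80)
#' @param identity_denominator `"aligned"` (identity over the aligned
#'   segment, the default) or `"window"` (over the full flank window)
#' @param control_mode `"sequence"` (default: remove candidates similar to a
#'   passing control alignment) or `"cohort"` (any passing control pair
#'   empties the candidate set)
#' @param flank_mode `"inner"` (default: flanks read into the rearranged
#'   segment) or `"outer"` (flanks read away from it)
#' @return a `PssConfig` list
#' @export
pss_config <- function(flank_window = 20L, min_identity = 0.50,
                       max_offset = 3L, min_aligned_len = 10L,
                       max_repeat_len = 5L, control_identity = 0.80,
                       identity_denominator = c("aligned", "window"),
                       control_mode = c("sequence", "cohort"),
                       flank_mode = c("inner", "outer")) {
  cfg <- list(flank_window = as.integer(flank_window),
              min_identity = min_identity,
              max_offset = as.integer(max_offset),
              min_aligned_len = as.integer(min_aligned_len),
              max_repeat_len = as.integer(max_repeat_len),
              control_identity = control_identity,
              identity_denominator = match.arg(identity_denominator),
              control_mode = match.arg(control_mode),
              flank_mode = match.arg(flank_mode))
  if (cfg$min_identity <= 0 || cfg$min_identity > 1)
    stop("min_identity must lie in (0,1]")
  if (cfg$max_offset < 0L) stop("max_offset must be >= 0")
  if (cfg$min_aligned_len > cfg$flank_window - cfg$max_offset)
    stop("min_aligned_len must be <= flank_window - max_offset")
  class(cfg) <- "PssConfig"
  cfg
}

contig_seq <- function(locus, contig) {
  if (contig == "" || contig == locus$name) return(locus$sequence)
  s <- locus$extra_contigs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  s
}

#' Extract the breakpoint flank pair of one SV
#'
#' Both flanks are returned in *inward* orientation — read from the
#' breakpoint into the rearranged segment, 5' to 3': the left flank is the
#' plus-strand window starting at `left_bp`, the right flank the reverse
#' complement of the plus-strand window ending at `right_bp`. In this frame
#' an inverted terminal repeat appears as a plain forward match between the
#' two flanks. `flank_mode = "outer"` reads away from the segment instead.
#' For TRA each anchor contributes its inward window on its own contig.
#'
#' @param sv one-row structural-variant `data.frame`
#' @param locus a [locus_reference()]
#' @param config a [pss_config()]
#' @return a `FlankPair` list (`sv_id`, `flank_left`, `flank_right`), or
#'   `NULL` with a message when a breakpoint sits too close to a contig end
#'   (the candidate is skipped, not fatal)
#' @export
extract_flanks <- function(sv, locus, config) {
  W <- config$flank_window
  lseq <- locus$sequence
  rseq <- tryCatch(contig_seq(locus, sv$partner_contig), error = function(e) NULL)
  if (is.null(rseq)) {
    message("skipping ", sv$id, ": partner contig '", sv$partner_contig,
            "' not available")
    return(NULL)
  }
  lb <- sv$left_bp; rb <- sv$right_bp
  if (config$flank_mode == "inner") {
    ok <- lb + W <= nchar(lseq) && rb - W >= 0L && lb >= 0L && rb <= nchar(rseq)
    if (!ok) {
      message("skipping ", sv$id, ": breakpoint within ", W, " bp of a contig end")
      return(NULL)
    }
    fl <- subseq0(lseq, lb, lb + W)
    fr <- reverse_complement(subseq0(rseq, rb - W, rb))
  } else {
    ok <- lb - W >= 0L && rb + W <= nchar(rseq)
    if (!ok) {
      message("skipping ", sv$id, ": breakpoint within ", W, " bp of a contig end")
      return(NULL)
    }
    fl <- reverse_complement(subseq0(lseq, lb - W, lb))
    fr <- subseq0(rseq, rb, rb + W)
  }
  structure(list(sv_id = sv$id, flank_left = fl, flank_right = fr),
            class = "FlankPair")
}

#' Best ungapped inverted-orientation alignment of a flank pair
#'
#' Exhaustive search over start offsets `offset_left`, `offset_right` in
#' `[0, max_offset]` and aligned lengths in
#' `[min_aligned_len, flank_window - max(offsets)]`. Because flanks are held
#' inward-oriented, inverted-orientation identity is a plain forward base
#' comparison; `N` never counts as a match. The maximiser of identity is
#' returned, ties broken by larger aligned length, then smaller offset sum,
#' then smaller left offset. `passed` is identity `>= min_identity`.
#'
#' @param pair a `FlankPair` from [extract_flanks()]
#' @param config a [pss_config()]
#' @return an `InvertedAlignmentResult` list: `offset_left`, `offset_right`,
#'   `aligned_len`, `matches`, `identity`, `passed`
#' @export
best_inverted_alignment <- function(pair, config) {
  a <- strsplit(pair$flank_left, "", fixed = TRUE)[[1L]]
  b <- strsplit(pair$flank_right, "", fixed = TRUE)[[1L]]
  W <- config$flank_window
  stopifnot(length(a) == W, length(b) == W)
  best <- NULL
  for (ol in 0:config$max_offset) {
    for (or in 0:config$max_offset) {
      maxlen <- W - max(ol, or)
      if (maxlen < config$min_aligned_len) next
      ia <- a[(ol + 1L):(ol + maxlen)]
      ib <- b[(or + 1L):(or + maxlen)]
      eq <- cumsum(ia == ib & ia != "N" & ib != "N")
      for (len in config$min_aligned_len:maxlen) {
        m <- eq[len]
        den <- if (config$identity_denominator == "aligned") len else W
        cand <- list(offset_left = ol, offset_right = or, aligned_len = len,
                     matches = m, identity = m / den)
        if (is.null(best) || better_alignment(cand, best)) best <- cand
      }
    }
  }
  best$passed <- best$identity >= config$min_identity
  class(best) <- "InvertedAlignmentResult"
  best
}

better_alignment <- function(x, y) {
  if (x$identity != y$identity) return(x$identity > y$identity)
  if (x$aligned_len != y$aligned_len) return(x$aligned_len > y$aligned_len)
  sx <- x$offset_left + x$offset_right
  sy <- y$offset_left + y$offset_right
  if (sx != sy) return(sx < sy)
  x$offset_left < y$offset_left
}

#' Short-repeat disqualification (criterion ii)
#'
#' `TRUE` iff the sequence contains a homopolymer run longer than
#' `max_repeat_len`, or a tandem tract (period 2-5, at least two full
#' consecutive unit copies, partial trailing copy included in the tract)
#' whose total length exceeds `max_repeat_len`. Orientation-invariant.
#'
#' @param seq DNA string
#' @param max_repeat_len tract length threshold (default 5)
#' @return logical flag
#' @export
has_disqualifying_repeat <- function(seq, max_repeat_len = 5L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  if (n == 0L) stop("empty sequence")
  for (p in 1:5) {
    if (n <= p) break
    run <- p  # current periodic tract length ending at position i
    for (i in (p + 1L):n) {
      if (x[i] == x[i - p]) run <- run + 1L else run <- p
      if (run > max_repeat_len && run >= 2L * p) return(TRUE)
    }
  }
  FALSE
}

aligned_segments <- function(pair, aln) {
  list(
    left = substr(pair$flank_left, aln$offset_left + 1L,
                  aln$offset_left + aln$aligned_len),
    right = substr(pair$flank_right, aln$offset_right + 1L,
                   aln$offset_right + aln$aligned_len)
  )
}

## ungapped identity between two sequences, best over relative shifts
## within +/- max_shift; denominator is the overlap length
shifted_identity <- function(s1, s2, max_shift, min_overlap = 1L) {
  a <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b <- strsplit(s2, "", fixed = TRUE)[[1L]]
  best <- 0
  for (sh in (-max_shift):max_shift) {
    i1 <- max(1L, 1L - sh); i2 <- max(1L, 1L + sh)
    ov <- min(length(a) - i1, length(b) - i2) + 1L
    if (ov < min_overlap) next
    ia <- a[i1:(i1 + ov - 1L)]; ib <- b[i2:(i2 + ov - 1L)]
    id <- sum(ia == ib & ia != "N" & ib != "N") / ov
    if (id > best) best <- id
  }
  best
}

#' Control-cohort subtraction (criterion iii)
#'
#' Removes every candidate whose sequence matches, at identity
#' `>= control_identity` (best over shifts up to `max_offset`), the aligned
#' left-flank segment of any *passing* control flank pair. With
#' `control_mode = "cohort"`, any passing control pair removes all
#' candidates. Removals are recorded in the `"removed"` attribute of the
#' returned table.
#'
#' @param candidates candidate `data.frame` from [detect_pss()]
#' @param control_pairs list of control `FlankPair`s
#' @param config a [pss_config()]
#' @return filtered candidate `data.frame`
#' @export
subtract_control <- function(candidates, control_pairs, config) {
  removed <- data.frame(sv_id = character(), side = character(),
                        control_id = character(), identity = numeric(),
                        stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L || length(control_pairs) == 0L) {
    attr(candidates, "removed") <- removed
    return(candidates)
  }
  ctrl <- list()
  for (cp in control_pairs) {
    aln <- best_inverted_alignment(cp, config)
    if (aln$passed)   # reporting orientation, to match candidate sequences
      ctrl[[length(ctrl) + 1L]] <-
        list(id = cp$sv_id,
             seq = reverse_complement(aligned_segments(cp, aln)$left))
  }
  if (length(ctrl) == 0L) {
    attr(candidates, "removed") <- removed
    return(candidates)
  }
  if (config$control_mode == "cohort") {
    removed <- data.frame(sv_id = candidates$sv_id, side = candidates$side,
                          control_id = ctrl[[1L]]$id, identity = NA_real_,
                          stringsAsFactors = FALSE)
    out <- candidates[0L, , drop = FALSE]
    attr(out, "removed") <- removed
    return(out)
  }
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    for (ct in ctrl) {
      id <- shifted_identity(candidates$sequence[i], ct$seq,
                             config$max_offset,
                             min_overlap = config$min_aligned_len)
      if (id >= config$control_identity) {
        keep[i] <- FALSE
        removed <- rbind(removed, data.frame(
          sv_id = candidates$sv_id[i], side = candidates$side[i],
          control_id = ct$id, identity = id, stringsAsFactors = FALSE))
        break
      }
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

candidate_row <- function(pair, aln, side, config) {
  off <- if (side == "left") aln$offset_left else aln$offset_right
  flank <- if (side == "left") pair$flank_left else pair$flank_right
  len <- min(off + aln$aligned_len, config$flank_window)
  inward <- substr(flank, 1L, len)
  data.frame(
    sv_id = pair$sv_id, side = side,
    sequence = reverse_complement(inward),  # 5'->3', breakpoint at the 3' end
    offset_left = aln$offset_left, offset_right = aln$offset_right,
    aligned_len = aln$aligned_len, identity = aln$identity,
    control_hit = FALSE, stringsAsFactors = FALSE
  )
}

#' Detect signal-sequence candidates at breakpoints
#'
#' Full criteria pipeline: flank extraction, best inverted-orientation
#' alignment (criterion i), short-repeat exclusion on both aligned segments
#' (criterion ii), control-cohort subtraction (criterion iii). Each passing
#' SV yields two candidates (left and right breakpoint), each reported
#' 5' to 3' with the breakpoint at the 3' terminus.
#'
#' @param case_svs,control_svs structural-variant `data.frame`s (control may
#'   have zero rows, which disables criterion iii)
#' @param locus a [locus_reference()]
#' @param config a [pss_config()]
#' @return candidate `data.frame` with columns `sv_id`, `side`, `sequence`,
#'   `offset_left`, `offset_right`, `aligned_len`, `identity`,
#'   `control_hit`; attributes `"skipped"` (sv_id + reason) and `"removed"`
#'   (criterion-iii log)
#' @export
detect_pss <- function(case_svs, control_svs, locus, config = pss_config()) {
  skipped <- data.frame(sv_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  empty <- data.frame(sv_id = character(), side = character(),
                      sequence = character(), offset_left = integer(),
                      offset_right = integer(), aligned_len = integer(),
                      identity = numeric(), control_hit = logical(),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(case_svs))) {
    sv <- case_svs[i, , drop = FALSE]
    pair <- suppressMessages(extract_flanks(sv, locus, config))
    if (is.null(pair)) {
      skipped <- rbind(skipped, data.frame(sv_id = sv$id, reason = "flank_out_of_range"))
      next
    }
    aln <- best_inverted_alignment(pair, config)
    if (!aln$passed) {
      skipped <- rbind(skipped, data.frame(sv_id = sv$id, reason = "identity_below_threshold"))
      next
    }
    segs <- aligned_segments(pair, aln)
    if (has_disqualifying_repeat(segs$left, config$max_repeat_len) ||
        has_disqualifying_repeat(segs$right, config$max_repeat_len)) {
      skipped <- rbind(skipped, data.frame(sv_id = sv$id, reason = "disqualifying_repeat"))
      next
    }
    rows[[length(rows) + 1L]] <- candidate_row(pair, aln, "left", config)
    rows[[length(rows) + 1L]] <- candidate_row(pair, aln, "right", config)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else empty
  control_pairs <- list()
  for (i in seq_len(nrow(control_svs))) {
    cp <- suppressMessages(extract_flanks(control_svs[i, , drop = FALSE], locus, config))
    if (!is.null(cp)) control_pairs[[length(control_pairs) + 1L]] <- cp
  }
  candidates <- subtract_control(candidates, control_pairs, config)
  rownames(candidates) <- NULL
  attr(candidates, "skipped") <- skipped
  candidates
}

#' Classify an SV as inactivating
#'
#' A rearrangement is inactivating when it disrupts exonic sequence:
#' DEL/DUP whose segment overlaps an exon; INV whose segment overlaps an
#' exon while a breakpoint falls inside the gene body; TRA with an anchor
#' inside an exon. Purely intronic segments are not inactivating.
#'
#' @param sv one-row structural-variant `data.frame`
#' @param exons sorted, disjoint exon intervals
#' @return logical flag
#' @export
classify_inactivating <- function(sv, exons) {
  if (nrow(exons) == 0L) return(FALSE)
  overlaps_exon <- function(s, e) any(exons$start < e & exons$end > s)
  in_exon <- function(p) any(exons$start <= p & p < exons$end)
  gene_lo <- min(exons$start); gene_hi <- max(exons$end)
  in_body <- function(p) p > gene_lo && p < gene_hi
  switch(sv$svtype,
    DEL = ,
    DUP = overlaps_exon(sv$left_bp, sv$right_bp),
    INV = (in_body(sv$left_bp) || in_body(sv$right_bp)) &&
      overlaps_exon(sv$left_bp, sv$right_bp),
    TRA = in_exon(sv$left_bp) ||
      (sv$partner_contig == "" && in_exon(sv$right_bp - 1L)),
    FALSE
  )
}

#' Cohort summary of inactivating / total variants
#'
#' @param svs structural-variant `data.frame` (one cohort)
#' @param exons exon intervals
#' @return list with `inactivating` and `total` counts
#' @export
summarize_cohort <- function(svs, exons) {
  inact <- 0L
  for (i in seq_len(nrow(svs)))
    inact <- inact + classify_inactivating(svs[i, , drop = FALSE], exons)
  list(inactivating = as.integer(inact), total = nrow(svs))
}
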