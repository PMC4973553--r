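## Synthetic forward-genetic-screen generator: an HPRT1-like single-gene
## locus, two SV cohorts (case with planted inverted-terminal-repeat
## elements, motif-free control), and windowed small-variant counts.

#' Simulation configuration
#'
#' Defaults describe the screen this package emulates: a ~43 kb single-gene
#' locus with nine exons at 0.41 GC, 13-bp signal elements with a GGG
#' breakpoint-proximal terminus and no thymines (in reporting orientation),
#' and per-40-bp-window small-variant rates with an exonic excess under
#' selection.
#'
#' @param seed integer seed; all generators are deterministic given it
#' @param locus_len locus length in bases (default 43000)
#' @param n_exons number of exons (default 9)
#' @param gc target GC fraction (default 0.41)
#' @param n_sv_case,n_sv_control cohort sizes
#' @param sv_type_weights named probabilities over DEL/INV/DUP/TRA (sum 1)
#' @param planted_fraction fraction of case SVs receiving a planted element
#' @param motif_len element length in bases (default 13)
#' @param motif_terminal breakpoint-proximal terminal trinucleotide of the
#'   reporting-oriented element (default `"GGG"`)
#' @param motif_t_free if `TRUE`, reporting-oriented elements contain no T
#' @param motif_noise per-base substitution probability applied
#'   independently to each planted copy
#' @param flank_window breakpoint flank window in bases (default 20)
#' @param snv_rate_exon,snv_rate_intron per-40-bp-window small-variant event
#'   rates for exonic / intronic windows
#' @param exon_boost multiplier applied to the exonic rate under selection
#'   (default 5)
#' @param read_depth reads covering each window (default 1000)
#' @param mean_support mean supporting reads per small-variant event
#' @param sv_len_min,sv_len_max rearranged-segment length bounds in bases
#' @param tra_contig_len length of the simulated translocation partner contig
#' @return a `SimulationConfig` list
#' @export
sim_config <- function(seed,
                       locus_len = 43000L, n_exons = 9L, gc = 0.41,
                       n_sv_case = 50L, n_sv_control = 50L,
                       sv_type_weights = c(DEL = 0.4, INV = 0.35, DUP = 0.15, TRA = 0.1),
                       planted_fraction = 1, motif_len = 13L,
                       motif_terminal = "GGG", motif_t_free = TRUE,
                       motif_noise = 0, flank_window = 20L,
                       snv_rate_exon = 0.2, snv_rate_intron = 0.2,
                       exon_boost = 5, read_depth = 1000L, mean_support = 5,
                       sv_len_min = 500L, sv_len_max = 10000L,
                       tra_contig_len = 5000L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), locus_len = as.integer(locus_len),
              n_exons = as.integer(n_exons), gc = gc,
              n_sv_case = as.integer(n_sv_case),
              n_sv_control = as.integer(n_sv_control),
              sv_type_weights = sv_type_weights,
              planted_fraction = planted_fraction,
              motif_len = as.integer(motif_len),
              motif_terminal = toupper(motif_terminal),
              motif_t_free = isTRUE(motif_t_free),
              motif_noise = motif_noise,
              flank_window = as.integer(flank_window),
              snv_rate_exon = snv_rate_exon, snv_rate_intron = snv_rate_intron,
              exon_boost = exon_boost, read_depth = as.integer(read_depth),
              mean_support = mean_support,
              sv_len_min = as.integer(sv_len_min),
              sv_len_max = as.integer(sv_len_max),
              tra_contig_len = as.integer(tra_contig_len))
  probs <- c(cfg$planted_fraction, cfg$motif_noise, cfg$gc)
  if (any(probs < 0 | probs > 1)) stop("fractions must lie in [0,1]")
  if (abs(sum(cfg$sv_type_weights) - 1) > 1e-8)
    stop("sv_type_weights must sum to 1")
  if (!all(names(cfg$sv_type_weights) %in% SV_TYPES))
    stop("sv_type_weights names must be DEL/INV/DUP/TRA")
  if (cfg$motif_len >= cfg$flank_window)
    stop("motif_len must be smaller than flank_window")
  if (cfg$motif_len < 6L) stop("motif_len must be >= 6")
  class(cfg) <- "SimulationConfig"
  cfg
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate the locus reference
#'
#' Draws an i.i.d. sequence at the target GC and places `n_exons`
#' non-overlapping exons of 60-300 bp, each at least 500 bp from its
#' neighbours and from the locus ends. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()]
#' @return a [locus_reference()] named `"locus"`
#' @export
simulate_locus <- function(config) {
  withr::with_seed(config$seed, {
    seq <- random_dna(config$locus_len, config$gc)
    exons <- place_exons(config$locus_len, config$n_exons)
    locus_reference("locus", seq, exons = exons)
  })
}

place_exons <- function(L, n, len_min = 60L, len_max = 300L,
                        gap = 500L, margin = 500L) {
  for (try in seq_len(200L)) {
    lens <- sample(len_min:len_max, n, replace = TRUE)
    slack <- L - 2L * margin - sum(lens) - (n - 1L) * gap
    if (slack < 0L) next
    # distribute the slack over the n+1 gaps uniformly at random
    cuts <- sort(sample.int(slack + n, n))
    extra <- diff(c(0L, cuts)) - 1L
    starts <- integer(n); pos <- margin
    for (i in seq_len(n)) {
      pos <- pos + extra[i]
      starts[i] <- pos
      pos <- pos + lens[i] + gap
    }
    return(genomic_intervals("locus", starts, starts + lens, "+",
                             sprintf("exon_%d", seq_len(n))))
  }
  stop("cannot place ", n, " exons in a ", L, " bp locus")
}

#' Draw one signal-sequence element
#'
#' Returns the element in *inward* orientation (read from the breakpoint
#' into the rearranged segment): the reporting-oriented sequence (breakpoint
#' at the 3' terminus) is its reverse complement, so the inward string
#' starts with `reverse_complement(motif_terminal)` and, when
#' `motif_t_free`, contains no A (no T after reporting conversion). Elements
#' containing a disqualifying short repeat are redrawn; consumes the current
#' RNG stream.
#'
#' @param config a [sim_config()]
#' @return inward-oriented DNA string of length `motif_len`
#' @export
make_pss_element <- function(config) {
  prefix <- reverse_complement(config$motif_terminal)
  alphabet <- if (config$motif_t_free) c("C", "G", "T") else c("A", "C", "G", "T")
  n_rest <- config$motif_len - nchar(prefix)
  if (n_rest < 0L) stop("motif_len shorter than terminal motif")
  for (try in seq_len(1000L)) {
    m <- paste0(prefix, paste(sample(alphabet, n_rest, replace = TRUE),
                              collapse = ""))
    if (!has_disqualifying_repeat(m)) return(m)
  }
  stop("cannot draw a repeat-free element after 1000 tries")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     "", USE.NAMES = FALSE)
  }
  paste(x, collapse = "")
}

#' Plant structural variants and signal elements
#'
#' Draws case and control cohorts of DEL/INV/DUP/TRA calls and, for a
#' `planted_fraction` of case SVs, overwrites the locus with an element copy
#' inward at the left breakpoint and its reverse complement inward at the
#' right breakpoint, then applies `motif_noise` substitutions independently
#' per copy. Breakpoint flank windows (one `flank_window` each side of every
#' breakpoint) are mutually disjoint across all SVs and kept clear of exons;
#' whole rearranged segments may overlap, since each SV models an
#' independent cell and only the flanks feed the downstream analysis.
#'
#' @param locus a [simulate_locus()] result
#' @param config a [sim_config()]
#' @return a list with elements `locus` (modified reference, including the
#'   TRA partner contig when present), `svs` (case + control SV table) and
#'   `truth` (per-case-SV planted truth table)
#' @export
plant_structural_variants <- function(locus, config) {
  withr::with_seed(config$seed + 1L, {
    W <- config$flank_window
    ml <- config$motif_len
    L <- nchar(locus$sequence)
    guard <- W  # half-width of the exclusion window around a breakpoint
    exon_lo <- locus$exons$start - guard
    exon_hi <- locus$exons$end + guard
    occupied_lo <- exon_lo; occupied_hi <- exon_hi

    partner <- random_dna(config$tra_contig_len, config$gc)
    partner_occ_lo <- integer(); partner_occ_hi <- integer()

    n_case <- config$n_sv_case; n_ctrl <- config$n_sv_control
    n <- n_case + n_ctrl
    types <- sample(names(config$sv_type_weights), n, replace = TRUE,
                    prob = config$sv_type_weights)
    cohort <- rep(c("case", "control"), c(n_case, n_ctrl))
    ids <- sprintf("sv_%s_%03d", cohort, c(seq_len(n_case), seq_len(n_ctrl)))

    free_at <- function(bp, lo, hi) all(bp + guard <= lo | bp - guard >= hi)
    claim <- function(bp) {
      occupied_lo <<- c(occupied_lo, bp - guard)
      occupied_hi <<- c(occupied_hi, bp + guard)
    }

    left_bp <- integer(n); right_bp <- integer(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        if (types[i] == "TRA") {
          lb <- sample.int(L - 2L * W, 1L) + W - 1L
          rb <- sample.int(config$tra_contig_len - 2L * W, 1L) + W
          ok <- free_at(lb, occupied_lo, occupied_hi) &&
            free_at(rb, partner_occ_lo, partner_occ_hi)
          if (ok) {
            claim(lb)
            partner_occ_lo <- c(partner_occ_lo, rb - guard)
            partner_occ_hi <- c(partner_occ_hi, rb + guard)
            left_bp[i] <- lb; right_bp[i] <- rb; placed <- TRUE
          }
        } else {
          len <- sample(config$sv_len_min:config$sv_len_max, 1L)
          if (L - 2L * W - len <= 0L) next
          lb <- sample.int(L - 2L * W - len, 1L) + W - 1L
          rb <- lb + len
          if (free_at(lb, occupied_lo, occupied_hi) &&
              free_at(rb, occupied_lo, occupied_hi) &&
              abs(rb - lb) > 2L * guard) {
            claim(lb); claim(rb)
            left_bp[i] <- lb; right_bp[i] <- rb; placed <- TRUE
          }
        }
        if (placed) break
      }
      if (!placed) stop("cannot place SV ", i, " without window collisions")
    }

    svs <- structural_variants(ids, types, left_bp, right_bp,
                               partner_contig = ifelse(types == "TRA", "partner", ""),
                               cohort = cohort)

    seq <- locus$sequence
    case_idx <- which(cohort == "case")
    planted <- rep(FALSE, n)
    planted[case_idx] <- runif(length(case_idx)) < config$planted_fraction
    motif_seq <- rep(NA_character_, n)

    overwrite <- function(s, at0, piece) {   # at0: 0-based start
      paste0(substr(s, 1L, at0), piece, substr(s, at0 + nchar(piece) + 1L, nchar(s)))
    }

    ## a planted SV must carry a *valid* signal sequence in its realized
    ## (noise-free) context: the flank bases beyond the element can extend
    ## the inverted alignment by chance and create a disqualifying short
    ## repeat, so elements are redrawn until the noiseless flanks pass
    ## criteria i and ii under the default detection config
    det_cfg <- pss_config(flank_window = W)
    plantable <- function(m, i) {
      lf <- paste0(m, subseq0(seq, left_bp[i] + ml, left_bp[i] + W))
      tailseq <- if (types[i] == "TRA") {
        reverse_complement(subseq0(partner, right_bp[i] - W, right_bp[i] - ml))
      } else {
        reverse_complement(subseq0(seq, right_bp[i] - W, right_bp[i] - ml))
      }
      rf <- paste0(m, tailseq)
      pair <- structure(list(sv_id = "tmp", flank_left = lf, flank_right = rf),
                        class = "FlankPair")
      aln <- best_inverted_alignment(pair, det_cfg)
      segs <- aligned_segments(pair, aln)
      aln$passed &&
        !has_disqualifying_repeat(segs$left, det_cfg$max_repeat_len) &&
        !has_disqualifying_repeat(segs$right, det_cfg$max_repeat_len)
    }

    for (i in which(planted)) {
      m <- NULL
      for (try in seq_len(100L)) {
        cand <- make_pss_element(config)
        if (plantable(cand, i)) { m <- cand; break }
      }
      if (is.null(m)) stop("cannot plant a valid element at SV ", i)
      motif_seq[i] <- m
      left_copy <- mutate_seq(m, config$motif_noise)
      right_copy <- mutate_seq(m, config$motif_noise)
      # left breakpoint, inward = plus strand forward from left_bp
      seq <- overwrite(seq, left_bp[i], left_copy)
      # right breakpoint, inward = revcomp of plus-strand window ending at right_bp
      if (types[i] == "TRA") {
        partner <- overwrite(partner, right_bp[i] - ml, reverse_complement(right_copy))
      } else {
        seq <- overwrite(seq, right_bp[i] - ml, reverse_complement(right_copy))
      }
    }

    truth <- data.frame(
      sv_id = ids[cohort == "case"],
      planted = planted[cohort == "case"],
      motif_seq = motif_seq[cohort == "case"],
      left_copy_start = ifelse(planted[cohort == "case"], left_bp[cohort == "case"], NA_integer_),
      left_copy_end = ifelse(planted[cohort == "case"], left_bp[cohort == "case"] + ml, NA_integer_),
      right_copy_start = ifelse(planted[cohort == "case"], right_bp[cohort == "case"] - ml, NA_integer_),
      right_copy_end = ifelse(planted[cohort == "case"], right_bp[cohort == "case"], NA_integer_),
      stringsAsFactors = FALSE
    )

    # partner contig is always generated and attached so the output file
    # set (and manifest) is the same whatever the TRA draw
    extra <- c(partner = partner)
    out_locus <- locus_reference(locus$name, seq, exons = locus$exons,
                                 amplicons = locus$amplicons,
                                 annotations = locus$annotations,
                                 extra_contigs = extra)
    list(locus = out_locus, svs = svs, truth = truth)
  })
}

#' Simulate windowed small-variant counts
#'
#' Per non-overlapping 40-bp window, the number of small-variant events is
#' Poisson with rate `snv_rate_exon` (windows overlapping an exon) or
#' `snv_rate_intron`; under `condition = "selected"` the exonic rate is
#' multiplied by `exon_boost`, emulating selection for inactivating exonic
#' variants. Each event gets a uniform position within its window, a random
#' alternate allele and `1 + Poisson(mean_support - 1)` supporting reads out
#' of `read_depth`. Deterministic given `config$seed` and `condition`.
#'
#' @param locus a [locus_reference()]
#' @param config a [sim_config()]
#' @param condition `"unselected"` or `"selected"`
#' @return a small-variant `data.frame`
#' @export
simulate_small_variants <- function(locus, config,
                                    condition = c("unselected", "selected")) {
  condition <- match.arg(condition)
  seed <- config$seed + 2L + (condition == "selected")
  withr::with_seed(seed, {
    L <- nchar(locus$sequence)
    starts <- seq.int(0L, L - 1L, by = 40L)
    ends <- pmin(starts + 40L, L)
    exonic <- vapply(seq_along(starts), function(i)
      any(locus$exons$start < ends[i] & locus$exons$end > starts[i]), logical(1L))
    rate <- ifelse(exonic, config$snv_rate_exon, config$snv_rate_intron)
    if (condition == "selected") rate[exonic] <- rate[exonic] * config$exon_boost
    k <- rpois(length(starts), rate)
    if (sum(k) == 0L)
      return(small_variants(integer(), character(), character(), integer(), integer()))
    widx <- rep(seq_along(starts), k)
    pos <- starts[widx] + vapply(widx, function(i)
      sample.int(ends[i] - starts[i], 1L) - 1L, integer(1L))
    ref <- substring(locus$sequence, pos + 1L, pos + 1L)
    vclass <- sample(c("SNV", "INS", "DEL"), length(pos), replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
    alt <- vapply(seq_along(pos), function(i) {
      switch(vclass[i],
             SNV = sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L),
             INS = paste0(ref[i], sample(c("A", "C", "G", "T"), 1L)),
             DEL = ref[i])
    }, "")
    # DEL: ref spans two bases, alt keeps the first (VCF-style left anchor)
    del <- vclass == "DEL"
    ref[del] <- substring(locus$sequence, pos[del] + 1L, pos[del] + 2L)
    supp <- 1L + rpois(length(pos), max(config$mean_support - 1, 0))
    supp <- pmin(supp, config$read_depth)
    small_variants(pos, ref, alt, supp, config$read_depth, vclass)
  })
}
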