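# Independent oracles, deliberately written as plain enumerations on
# different code paths from the package implementation.

# brute-force best inverted alignment: enumerate every
# (offset_left, offset_right, aligned_len), count matches positionally,
# order by the stated tie-break
oracle_best_alignment <- function(flank_left, flank_right, cfg) {
  a <- strsplit(flank_left, "")[[1]]
  b <- strsplit(flank_right, "")[[1]]
  W <- cfg$flank_window
  rows <- list()
  for (ol in 0:cfg$max_offset) for (or in 0:cfg$max_offset) {
    for (len in seq_len(W)) {
      if (len < cfg$min_aligned_len) next
      if (ol + len > W || or + len > W) next
      m <- 0L
      for (k in 1:len) {
        ca <- a[ol + k]; cb <- b[or + k]
        if (ca == cb && ca != "N") m <- m + 1L
      }
      den <- if (cfg$identity_denominator == "aligned") len else W
      rows[[length(rows) + 1]] <-
        data.frame(ol = ol, or = or, len = len, matches = m, identity = m / den)
    }
  }
  d <- do.call(rbind, rows)
  d <- d[order(-d$identity, -d$len, d$ol + d$or, d$ol), ]
  d[1, ]
}

# substring-enumeration repeat oracle: any substring of length > maxlen
# with period p in 1..5 and at least two full unit copies
oracle_has_repeat <- function(seq, maxlen = 5L) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  for (i in 1:n) for (j in i:n) {
    t <- j - i + 1L
    if (t <= maxlen) next
    for (p in 1:5) {
      if (t < 2L * p) next
      periodic <- TRUE
      for (k in (i + p):j) if (x[k] != x[k - p]) { periodic <- FALSE; break }
      if (periodic) return(TRUE)
    }
  }
  FALSE
}

# own binomial point probability (log-choose arithmetic, no dbinom)
oracle_point_prob <- function(k, n, p) {
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

# minlike two-sided p for the conditional rate-ratio test, equal tie rule
oracle_rate_ratio_p <- function(c1, c2, t1 = 1, t2 = 1) {
  n <- c1 + c2
  pi0 <- t1 / (t1 + t2)
  probs <- vapply(0:n, oracle_point_prob, numeric(1), n = n, p = pi0)
  obs <- probs[c1 + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Clopper-Pearson by root-finding on the binomial tail
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  low <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}

random_flank <- function(W = 20) {
  paste(sample(c("A", "C", "G", "T"), W, replace = TRUE), collapse = "")
}

# tiny deterministic locus with two exons, for interval logic tests
toy_locus <- function(len = 400, seed = 42) {
  withr::with_seed(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    locus_reference("locus", seq,
                    exons = genomic_intervals("locus", c(100, 250), c(160, 300),
                                              "+", c("exon_1", "exon_2")))
  })
}
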