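#' @importFrom data.table fread fwrite data.table as.data.table
#' @importFrom stats dbinom pbinom qbeta rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
SV_TYPES <- c("DEL", "INV", "DUP", "TRA")

## ---- interval and variant containers ---------------------------------------

#' Genomic intervals (0-based, half-open)
#'
#' Builds the package's interval container: a plain `data.frame` with columns
#' `contig`, `start`, `end`, `strand`, `label`. All coordinates in this
#' package are 0-based, half-open (`[start, end)`), matching BED on disk.
#'
#' @param contig contig identifier(s)
#' @param start 0-based start offset(s)
#' @param end end offset(s), exclusive
#' @param strand `"+"` or `"-"` (recycled)
#' @param label free-text label(s) (recycled)
#' @return a `data.frame` of intervals
#' @export
genomic_intervals <- function(contig, start, end, strand = "+", label = "") {
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(start)),
    label = rep_len(as.character(label), length(start)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("contig", "start", "end", "strand", "label") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval must satisfy start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

#' Locus reference
#'
#' A single-contig reference carrying the locus sequence and its exon,
#' amplicon and free annotation intervals. Translocation partner contigs
#' (small accessory sequences) live in `extra_contigs`, a named character
#' vector.
#'
#' @param name contig name
#' @param sequence uppercase DNA string over A/C/G/T/N
#' @param exons,amplicons,annotations interval `data.frame`s
#'   (see [genomic_intervals()]); exons must be sorted and non-overlapping
#' @param extra_contigs named character vector of partner contig sequences
#' @return an object of class `LocusReference`
#' @export
locus_reference <- function(name, sequence,
                            exons = genomic_intervals(character(), integer(), integer()),
                            amplicons = genomic_intervals(character(), integer(), integer()),
                            annotations = genomic_intervals(character(), integer(), integer()),
                            extra_contigs = character()) {
  sequence <- toupper(sequence)
  check_dna(sequence)
  L <- nchar(sequence)
  validate_intervals(exons)
  if (nrow(exons)) {
    if (any(exons$end > L)) stop("exon intervals must lie within the locus")
    o <- order(exons$start)
    exons <- exons[o, , drop = FALSE]
    if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
      stop("exons must be non-overlapping")
    rownames(exons) <- NULL
  }
  structure(
    list(name = as.character(name), sequence = sequence, exons = exons,
         amplicons = amplicons, annotations = annotations,
         extra_contigs = extra_contigs),
    class = "LocusReference"
  )
}

#' @export
print.LocusReference <- function(x, ...) {
  cat(sprintf("LocusReference '%s': %d bp, %d exons, %d amplicons, %d extra contigs\n",
              x$name, nchar(x$sequence), nrow(x$exons), nrow(x$amplicons),
              length(x$extra_contigs)))
  invisible(x)
}

#' @export
length.LocusReference <- function(x) nchar(x$sequence)

check_dna <- function(seq) {
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nchar(bad) > 0L))
    stop("sequence contains characters outside {A,C,G,T,N}: '",
         substr(bad[nchar(bad) > 0L][1L], 1L, 10L), "'")
  invisible(seq)
}

#' Structural variant table
#'
#' One row per rearrangement call. `left_bp` is the 0-based offset of the
#' first rearranged base; `right_bp` is one past the last rearranged base
#' (half-open). For translocations (`TRA`) the right breakpoint lives on
#' `partner_contig` and the `left_bp < right_bp` ordering is not required.
#'
#' @param id variant identifiers
#' @param svtype one of `"DEL"`, `"INV"`, `"DUP"`, `"TRA"`
#' @param left_bp,right_bp breakpoint offsets (0-based; right exclusive)
#' @param partner_contig partner contig name, `""` except for TRA
#' @param cohort cohort label
#' @return a `data.frame` of structural variants
#' @export
structural_variants <- function(id, svtype, left_bp, right_bp,
                                partner_contig = "", cohort = "") {
  df <- data.frame(
    id = as.character(id),
    svtype = as.character(svtype),
    left_bp = as.integer(left_bp),
    right_bp = as.integer(right_bp),
    partner_contig = rep_len(as.character(partner_contig), length(id)),
    cohort = rep_len(as.character(cohort), length(id)),
    stringsAsFactors = FALSE
  )
  validate_svs(df)
  df
}

validate_svs <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- setdiff(unique(df$svtype), SV_TYPES)
  if (length(bad)) stop("unknown svtype: ", paste(bad, collapse = ", "))
  intra <- df$svtype != "TRA"
  if (any(intra & df$left_bp >= df$right_bp))
    stop("left_bp must be < right_bp for DEL/INV/DUP")
  invisible(df)
}

#' Small variant table
#'
#' @param pos 0-based offsets
#' @param ref,alt reference and alternate alleles (`ref != alt`)
#' @param supporting_reads,total_reads read support (`0 <= supp <= total`)
#' @param vclass `"SNV"`, `"INS"` or `"DEL"`
#' @return a `data.frame` of small variants
#' @export
small_variants <- function(pos, ref, alt, supporting_reads, total_reads,
                           vclass = "SNV") {
  df <- data.frame(
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    supporting_reads = as.integer(supporting_reads),
    total_reads = as.integer(total_reads),
    vclass = rep_len(as.character(vclass), length(pos)),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$supporting_reads < 0L | df$supporting_reads > df$total_reads))
      stop("need 0 <= supporting_reads <= total_reads")
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    if (!all(df$vclass %in% c("SNV", "INS", "DEL")))
      stop("vclass must be SNV, INS or DEL")
  }
  df
}

## ---- FASTA -----------------------------------------------------------------

#' Read / write a single-record locus FASTA
#'
#' `read_fasta()` reads exactly one record (a multi-record file is an
#' ambiguous locus and an error), uppercases it and rejects characters
#' outside A/C/G/T/N. `write_fasta()` writes the locus sequence (plus any
#' extra contigs) deterministically at 70 columns.
#'
#' @param path file path
#' @return `read_fasta`: a [locus_reference()] carrying the sequence only.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # BString keeps arbitrary letters so the alphabet check is ours
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  if (length(set) > 1L)
    stop("ambiguous locus: FASTA has ", length(set), " records")
  seq <- toupper(as.character(set[[1L]]))
  check_dna(seq)
  locus_reference(names(set)[1L], seq)
}

#' @param locus a [locus_reference()]
#' @rdname read_fasta
#' @export
write_fasta <- function(locus, path) {
  seqs <- c(setNames(locus$sequence, locus$name), locus$extra_contigs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

## ---- BED -------------------------------------------------------------------

#' Read / write BED intervals
#'
#' Standard 0-based half-open BED; columns 4 (name), 5 (score, ignored) and
#' 6 (strand) are optional on read and always written. Round-trips
#' `(contig, start, end, label, strand)` losslessly.
#'
#' @param path file path
#' @return `read_bed`: an interval `data.frame` (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(genomic_intervals(character(), integer(), integer()))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1L))
  if (nrow(dt) == 0L) return(genomic_intervals(character(), integer(), integer()))
  if (ncol(dt) < 3L) stop("BED needs >= 3 columns: ", path)
  if (any(dt[[2L]] < 0)) stop("negative BED coordinate in ", path)
  if (any(dt[[2L]] >= dt[[3L]])) stop("BED start >= end in ", path)
  genomic_intervals(
    contig = dt[[1L]],
    start = dt[[2L]],
    end = dt[[3L]],
    strand = if (ncol(dt) >= 6L) ifelse(dt[[6L]] %in% c("+", "-"), dt[[6L]], "+") else "+",
    label = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else ""
  )
}

#' @param intervals interval `data.frame`
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  dt <- data.table(
    intervals$contig, intervals$start, intervals$end,
    ifelse(nzchar(intervals$label), intervals$label, "."),
    0L, intervals$strand
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- BEDPE -----------------------------------------------------------------

#' Read / write structural variants as BEDPE
#'
#' Anchors occupy columns 1-6, the name column 7; columns 8-10 are score and
#' strands (written as placeholders); svtype and cohort are carried in
#' columns 11-12. Anchors are single-base intervals at the first (left) and
#' last (right) rearranged base, so `left_bp = start1` and
#' `right_bp = start2 + 1 = end2`. See `inst/extdata/convention.bedpe` for a
#' worked line.
#'
#' @param path file path
#' @return `read_bedpe`: a structural-variant `data.frame`
#'   (see [structural_variants()]).
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(structural_variants(character(), character(), integer(), integer()))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = c(1L, 4L)))
  if (nrow(dt) == 0L)
    return(structural_variants(character(), character(), integer(), integer()))
  if (ncol(dt) < 11L) stop("BEDPE needs svtype in column 11: ", path)
  chrom1 <- dt[[1L]]; chrom2 <- dt[[4L]]
  svtype <- as.character(dt[[11L]])
  cohort <- if (ncol(dt) >= 12L) as.character(dt[[12L]]) else ""
  tra <- svtype == "TRA"
  if (any(!tra & chrom1 != chrom2))
    stop("non-TRA anchors on different contigs in ", path)
  svs <- structural_variants(
    id = as.character(dt[[7L]]),
    svtype = svtype,
    left_bp = dt[[2L]],
    right_bp = dt[[5L]] + 1L,
    partner_contig = ifelse(tra, chrom2, ""),
    cohort = cohort
  )
  svs
}

#' @param svs structural-variant `data.frame`
#' @param contig contig name written for intra-locus anchors
#' @rdname read_bedpe
#' @export
write_bedpe <- function(svs, path, contig = "locus") {
  validate_svs(svs)
  tra <- svs$svtype == "TRA"
  chrom2 <- ifelse(tra, svs$partner_contig, contig)
  dt <- data.table(
    contig, svs$left_bp, svs$left_bp + 1L,
    chrom2, svs$right_bp - 1L, svs$right_bp,
    svs$id, 0L, "+", "-", svs$svtype, svs$cohort
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- small variants (TSV / minimal VCF) ------------------------------------

#' Read / write small-variant tables
#'
#' Native format is a TSV with header
#' `pos ref alt supporting_reads total_reads vclass` (`pos` 0-based).
#' `read_small_variants()` also accepts a minimal VCF 4.2 body (`##` headers,
#' `#CHROM` line, `AD` in FORMAT giving ref,alt depths); VCF `POS` is 1-based
#' and converted to the internal 0-based frame.
#'
#' @param path file path
#' @return `read_small_variants`: a small-variant `data.frame`.
#' @export
read_small_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) return(read_minimal_vcf(path))
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("pos", "ref", "alt", "supporting_reads", "total_reads", "vclass")
  if (!all(need %in% names(dt)))
    stop("small-variant TSV must have columns: ", paste(need, collapse = ", "))
  small_variants(dt$pos, dt$ref, dt$alt, dt$supporting_reads, dt$total_reads,
                 dt$vclass)
}

read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L)
    return(small_variants(integer(), character(), character(), integer(), integer()))
  f <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols < 10L)) stop("VCF body needs FORMAT + one sample column")
  pos1 <- as.integer(vapply(f, `[`, "", 2L))
  ref <- vapply(f, `[`, "", 4L)
  alt <- vapply(f, `[`, "", 5L)
  fmt <- strsplit(vapply(f, `[`, "", 9L), ":", fixed = TRUE)
  smp <- strsplit(vapply(f, `[`, "", 10L), ":", fixed = TRUE)
  ad <- mapply(function(k, v) {
    i <- match("AD", k)
    if (is.na(i)) stop("VCF FORMAT lacks AD")
    as.integer(strsplit(v[i], ",", fixed = TRUE)[[1L]])
  }, fmt, smp, SIMPLIFY = FALSE)
  supp <- vapply(ad, function(x) x[2L], integer(1L))
  tot <- vapply(ad, sum, integer(1L))
  vclass <- ifelse(nchar(ref) == nchar(alt), "SNV",
                   ifelse(nchar(ref) < nchar(alt), "INS", "DEL"))
  small_variants(pos1 - 1L, ref, alt, supp, tot, vclass)
}

#' @param variants small-variant `data.frame`
#' @rdname read_small_variants
#' @export
write_small_variants <- function(variants, path) {
  fwrite(as.data.table(variants), path, sep = "\t", quote = FALSE)
  invisible(path)
}

## ---- sequence utilities ----------------------------------------------------

#' Reverse complement
#'
#' Vectorised over input strings; alphabet restricted to A/C/G/T/N
#' (N maps to N). An involution: `reverse_complement(reverse_complement(s))`
#' is `s`.
#'
#' @param seq character vector of DNA strings
#' @return character vector of reverse complements
#' @export
reverse_complement <- function(seq) {
  check_dna(toupper(seq))
  comp <- chartr("ACGTN", "TGCAN", toupper(seq))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), "")
}

subseq0 <- function(seq, start, end) {
  # 0-based half-open extraction from a plain character scalar
  substr(seq, start + 1L, end)
}

## ---- amplicon tiling -------------------------------------------------------

#' Tile a locus with overlapping amplicons
#'
#' Emulates long-range PCR panel design: amplicons of span up to `max_span`
#' stepping so that adjacent amplicons overlap by `overlap` bases; every base
#' of the locus is covered. Each span lies in `[min_span, max_span]` except
#' possibly the last, which is truncated at the locus end.
#'
#' @param locus a [locus_reference()]
#' @param min_span,max_span allowed amplicon spans in bases
#' @param overlap overlap between adjacent amplicons (default 200)
#' @return interval `data.frame` of amplicons
#' @export
tile_amplicons <- function(locus, min_span, max_span, overlap = 200L) {
  L <- nchar(locus$sequence)
  if (min_span <= 0L || min_span > max_span) stop("need 0 < min_span <= max_span")
  if (min_span > L) stop("locus shorter than min_span")
  if (overlap >= min_span) stop("overlap must be smaller than min_span")
  starts <- integer(); ends <- integer()
  pos <- 0L
  repeat {
    e <- min(pos + max_span, L)
    starts <- c(starts, pos); ends <- c(ends, e)
    if (e >= L) break
    pos <- e - as.integer(overlap)
  }
  genomic_intervals(locus$name, starts, ends, "+",
                    sprintf("amplicon_%02d", seq_along(starts)))
}
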