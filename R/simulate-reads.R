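#' Simulate alignment evidence for one SV in one accession
#'
#' Emits idealized read alignments, on both reference coordinate systems,
#' consistent with a chosen genotype.  Reads are drawn from the accession's
#' two local haplotypes (Poisson coverage, uniform starts).  A read whose
#' haplotype crosses a junction absent from a reference is emitted as a
#' clipped primary alignment plus, when both sides are long enough, an
#' SA-tagged supplementary alignment (the supplementary-alignment
#' convention for split reads).  A read falling entirely inside a segment
#' the reference lacks is unmapped there and omitted.  Homozygotes for the
#' segment-lacking allele therefore show near-zero depth inside the segment
#' on the carrier genome; heterozygotes show both split and spanning reads.
#'
#' @param genomes list with `genome_a`, `genome_b` as returned by
#'   [simulate_genome_pair()].
#' @param sv single SV record (one row of the truth `svs` table).
#' @param genotype one of `"A_HOM"`, `"B_HOM"`, `"HET"`.
#' @param config a [sim_config()] object (`read_depth`, `read_length`).
#' @param accession accession label, used for read naming and to decorrelate
#'   the RNG stream between accessions.
#' @return list with `aln_a` and `aln_b`: data.frames of alignment records
#'   (columns qname, flag, rname, pos (1-based), mapq, cigar, seq, sa).
#' @export
simulate_read_evidence <- function(genomes, sv, genotype, config,
                                   accession = "acc") {
  if (!genotype %in% c("A_HOM", "HET", "B_HOM"))
    stop("genotype must be A_HOM, HET or B_HOM")
  sv <- as.list(sv)
  set.seed((stage_seed(config, "reads") +
              sum(utf8ToInt(paste0(sv$id, accession)))) %% .Machine$integer.max)
  if (config$read_depth <= 0) {
    warning("read depth 0 requested; returning empty record set")
    return(list(aln_a = empty_aln(), aln_b = empty_aln()))
  }

  rl <- config$read_length
  pad <- as.integer(sv$size + 2L * rl)
  haps <- switch(genotype, A_HOM = c("A", "A"), B_HOM = c("B", "B"),
                 HET = c("A", "B"))
  depth_hap <- config$read_depth / 2

  reads_a <- list(); reads_b <- list()
  for (h in seq_along(haps)) {
    allele <- haps[h]
    reg <- hap_region(genomes, sv, allele, pad)
    if (reg$len < rl) next
    n_reads <- stats::rpois(1L, depth_hap * reg$len / rl)
    if (n_reads == 0) next
    starts <- sort(sample.int(reg$len - rl + 1L, n_reads, replace = TRUE)) - 1L
    for (i in seq_len(n_reads)) {
      qname <- sprintf("%s_%s_h%d_r%04d", accession, sv$id, h, i)
      seq <- substring(reg$seq, starts[i] + 1L, starts[i] + rl)
      # genomic (0-based) coordinates of the read on its own reference
      g0 <- reg$start + starts[i]
      reads_self <- data.frame(qname = qname, flag = 0L, rname = sv$chrom_a,
                               pos = g0 + 1L, mapq = 60L,
                               cigar = paste0(rl, "M"), seq = seq,
                               sa = NA_character_, stringsAsFactors = FALSE)
      cross <- project_read(sv, allele, g0, rl, qname, seq)
      if (allele == "A") {
        reads_a[[length(reads_a) + 1L]] <- reads_self
        reads_b[[length(reads_b) + 1L]] <- cross
      } else {
        reads_b[[length(reads_b) + 1L]] <- reads_self
        reads_a[[length(reads_a) + 1L]] <- cross
      }
    }
  }
  list(aln_a = bind_aln(reads_a), aln_b = bind_aln(reads_b))
}

empty_aln <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), sa = character(), stringsAsFactors = FALSE)
}

bind_aln <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(empty_aln())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Local haplotype region around the SV for one allele.
# Returns seq, its genomic start (0-based) on that allele's own reference,
# and length.  The A haplotype locally equals genome A, the B haplotype
# genome B; "own reference" coordinates are genome A/B coordinates.
hap_region <- function(genomes, sv, allele, pad) {
  if (allele == "A") {
    chrom_seq <- genomes$genome_a[[sv$chrom_a]]
    s <- max(0L, sv$start_a - pad)
    e <- min(nchar(chrom_seq), sv$end_a + pad)
  } else {
    chrom_seq <- genomes$genome_b[[sv$chrom_b]]
    s <- max(0L, sv$start_b - pad)
    e <- min(nchar(chrom_seq), sv$end_b + pad)
  }
  list(seq = substring(chrom_seq, s + 1L, e), start = s, len = e - s)
}

MIN_CLIP <- 20L

# Project a read from one allele's haplotype onto the other reference.
# g0 = 0-based start of the read on its own reference; returns an alignment
# data.frame (possibly two rows: primary + SA-tagged supplementary), or NULL
# if the read cannot be placed on the other reference.
project_read <- function(sv, allele, g0, rl, qname, seq) {
  type <- sv$sv_type
  r0 <- g0; r1 <- g0 + rl
  if (type == "inversion") {
    own <- if (allele == "A") c(sv$start_a, sv$end_a) else
      c(sv$start_b, sv$end_b)
    oth <- if (allele == "A") c(sv$start_b, sv$end_b) else
      c(sv$start_a, sv$end_a)
    chrom <- if (allele == "A") sv$chrom_b else sv$chrom_a
    shift <- oth[1] - own[1]
    if (r1 <= own[1] || r0 >= own[2])        # fully outside: plain shift
      return(aln_row(qname, 0L, chrom, r0 + shift, paste0(rl, "M"), seq))
    if (r0 >= own[1] && r1 <= own[2]) {      # fully inside: reverse strand
      pos <- oth[1] + (own[2] - r1)
      return(aln_row(qname, 16L, chrom, pos, paste0(rl, "M"), seq))
    }
    if (r0 < own[1] && r1 > own[2]) return(NULL)  # spans whole inversion
    # crosses one breakpoint: split into forward + reverse pieces.
    # CIGARs are reference-oriented: for a reverse-strand piece the clip
    # where the read continues swaps sides.
    bp_own <- if (r0 < own[1]) own[1] else own[2]
    left <- bp_own - r0; right <- rl - left
    if (left < MIN_CLIP && right < MIN_CLIP) return(NULL)
    rows <- list()
    if (r0 < own[1]) {        # crossing the left breakpoint of own ref
      if (left >= MIN_CLIP)   # outside piece, forward, junction at oth[1]
        rows$p <- aln_row(qname, 0L, chrom, r0 + shift,
                          paste0(left, "M", right, "S"), seq)
      if (right >= MIN_CLIP)  # inside piece, reverse, junction at oth[2]
        rows$s <- aln_row(qname, 16L + 2048L, chrom,
                          oth[1] + (own[2] - r1),
                          paste0(right, "M", left, "S"), seq)
    } else {                  # crossing the right breakpoint of own ref
      if (left >= MIN_CLIP)   # inside piece, reverse, junction at oth[1]
        rows$p <- aln_row(qname, 16L, chrom, oth[1],
                          paste0(right, "S", left, "M"), seq)
      if (right >= MIN_CLIP)  # outside piece, forward, junction at oth[2]
        rows$s <- aln_row(qname, 2048L, chrom,
                          oth[2] + (bp_own - own[2]),
                          paste0(left, "S", right, "M"), seq)
    }
    return(link_sa(rows))
  }

  # indel: determine whether this allele carries the segment
  carrier_allele <- if (type == "deletion") "A" else "B"
  if (allele == carrier_allele) {
    # own reference has the segment; other reference has a junction
    own <- if (allele == "A") c(sv$start_a, sv$end_a) else
      c(sv$start_b, sv$end_b)
    junc <- if (allele == "A") sv$start_b else sv$start_a
    chrom <- if (allele == "A") sv$chrom_b else sv$chrom_a
    off_l <- junc - own[1]; off_r <- junc - own[2]
    if (r1 <= own[1])
      return(aln_row(qname, 0L, chrom, r0 + off_l, paste0(rl, "M"), seq))
    if (r0 >= own[2])
      return(aln_row(qname, 0L, chrom, r0 + off_r, paste0(rl, "M"), seq))
    left <- max(0L, own[1] - r0)
    right <- max(0L, r1 - own[2])
    if (left < MIN_CLIP && right < MIN_CLIP) return(NULL)
    rows <- list()
    if (left >= MIN_CLIP)
      rows$p <- aln_row(qname, 0L, chrom, r0 + off_l,
                        paste0(left, "M", rl - left, "S"), seq)
    if (right >= MIN_CLIP)
      rows$s <- aln_row(qname, if (left >= MIN_CLIP) 2048L else 0L,
                        chrom, junc,
                        paste0(rl - right, "S", right, "M"), seq)
    return(link_sa(rows))
  }
  # this allele lacks the segment; other reference carries it
  junc_own <- if (allele == "A") sv$start_a else sv$start_b
  seg <- if (allele == "A") c(sv$start_b, sv$end_b) else
    c(sv$start_a, sv$end_a)
  chrom <- if (allele == "A") sv$chrom_b else sv$chrom_a
  if (r1 <= junc_own)
    return(aln_row(qname, 0L, chrom, r0 + (seg[1] - junc_own),
                   paste0(rl, "M"), seq))
  if (r0 >= junc_own)
    return(aln_row(qname, 0L, chrom, r0 + (seg[2] - junc_own),
                   paste0(rl, "M"), seq))
  left <- junc_own - r0; right <- rl - left
  if (left < MIN_CLIP && right < MIN_CLIP) return(NULL)
  rows <- list()
  if (left >= MIN_CLIP)
    rows$p <- aln_row(qname, 0L, chrom, r0 + (seg[1] - junc_own),
                      paste0(left, "M", right, "S"), seq)
  if (right >= MIN_CLIP)
    rows$s <- aln_row(qname, if (left >= MIN_CLIP) 2048L else 0L,
                      chrom, seg[2],
                      paste0(left, "S", right, "M"), seq)
  link_sa(rows)
}

aln_row <- function(qname, flag, rname, pos0, cigar, seq) {
  data.frame(qname = qname, flag = flag, rname = rname,
             pos = as.integer(pos0) + 1L, mapq = 60L, cigar = cigar,
             seq = seq, sa = NA_character_, stringsAsFactors = FALSE)
}

# Cross-reference SA tags between a primary and supplementary pair.
link_sa <- function(rows) {
  if (!length(rows)) return(NULL)
  if (length(rows) == 2) {
    sa_of <- function(r) {
      strand <- if (bitwAnd(r$flag, 16L) > 0) "-" else "+"
      sprintf("%s,%d,%s,%s,%d,0;", r$rname, r$pos, strand, r$cigar, r$mapq)
    }
    rows$p$sa <- sa_of(rows$s)
    rows$s$sa <- sa_of(rows$p)
  }
  bind_aln(rows)
}
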