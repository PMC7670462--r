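#' Consolidate duplicated read pairs
#'
#' Sequencing duplicates are collapsed by prefix identity: two pairs are
#' duplicates when both mates share identical bases over the first 90 bp
#' (100-bp reads) or 100 bp (150-bp reads).  One representative per
#' equivalence class is retained, in input order.
#'
#' @param pairs data.frame with columns `left_seq` and `right_seq`.
#' @param read_length read length in bp (100 or 150; other lengths fall back
#'   to `min(read_length, 100)` with a warning).
#' @return the de-duplicated subset of `pairs`.
#' @export
dedup_read_pairs <- function(pairs, read_length) {
  n <- if (read_length == 100) 90L
  else if (read_length == 150) 100L
  else {
    warning("unsupported read length ", read_length,
            "; using prefix min(read_length, 100)")
    min(as.integer(read_length), 100L)
  }
  key <- paste(substr(pairs$left_seq, 1L, n),
               substr(pairs$right_seq, 1L, n), sep = "|")
  pairs[!duplicated(key), , drop = FALSE]
}

# ---- evidence collection ---------------------------------------------------

parse_cigar_spans <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  t(vapply(ops, function(o) {
    len <- as.integer(sub("[A-Z=]", "", o))
    op <- sub("\\d+", "", o)
    lead <- 0L; trail <- 0L
    i <- 1L
    while (i <= length(op) && op[i] %in% c("S", "H")) {
      lead <- lead + len[i]; i <- i + 1L
    }
    j <- length(op)
    while (j >= i && op[j] %in% c("S", "H")) {
      trail <- trail + len[j]; j <- j - 1L
    }
    span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    c(lead = lead, trail = trail, span = span)
  }, c(lead = 0L, trail = 0L, span = 0L)))
}

aln_features <- function(aln) {
  if (!nrow(aln))
    return(data.frame(qname = character(), start0 = integer(),
                      end0 = integer(), lead = integer(), trail = integer()))
  cg <- parse_cigar_spans(aln$cigar)
  data.frame(qname = aln$qname, start0 = aln$pos - 1L,
             end0 = aln$pos - 1L + cg[, "span"],
             lead = cg[, "lead"], trail = cg[, "trail"],
             stringsAsFactors = FALSE)
}

count_split_at <- function(feat, bp, tol = 10L, min_clip = 20L) {
  hit <- (feat$lead >= min_clip & abs(feat$start0 - bp) <= tol) |
    (feat$trail >= min_clip & abs(feat$end0 - bp) <= tol)
  length(unique(feat$qname[hit]))
}

count_span_at <- function(feat, bp, margin = 20L) {
  hit <- feat$lead < 5L & feat$trail < 5L &
    feat$start0 <= bp - margin & feat$end0 >= bp + margin
  length(unique(feat$qname[hit]))
}

coverage_profile <- function(feat, from, to) {
  len <- to - from
  cov <- integer(len)
  if (len <= 0 || !nrow(feat)) return(cov)
  for (i in seq_len(nrow(feat))) {
    s <- max(feat$start0[i], from); e <- min(feat$end0[i], to)
    if (e > s) cov[(s - from + 1L):(e - from)] <-
        cov[(s - from + 1L):(e - from)] + 1L
  }
  cov
}

#' Collect per-SV, per-accession genotype evidence from alignments
#'
#' Summarizes split-read and depth evidence for one SV from one accession's
#' alignments against the two reference genomes.  Split reads are clipped
#' alignments (clip >= 20 bp) whose clip boundary falls within `tol` bp of a
#' breakpoint; they support the allele whose haplotype carries a junction at
#' that point.  Spanning reads are essentially unclipped alignments covering
#' a breakpoint with at least 20 bp on each side.  For indels, per-base
#' depth over the deleted/inserted segment on the carrier genome yields the
#' fraction of the segment covered at >= 2x and the coverage fractions of
#' the two equal-length flanks.
#'
#' @param aln_a,aln_b alignment data.frames (as from
#'   [simulate_read_evidence()] or [read_sam()]) against genomes A and B.
#' @param sv one SV record (row of the truth/validated SV table).
#' @param accession accession label recorded in the summary.
#' @param tol breakpoint matching tolerance in bp.
#' @param ref_lengths optional named list with `a` and `b` chromosome-length
#'   vectors, used to reject SVs outside the reference.
#' @return one-row data.frame of class evidence summary with split counts
#'   per allele and breakpoint, spanning counts, and depth fractions.
#' @export
collect_evidence <- function(aln_a, aln_b, sv, accession = "acc",
                             tol = 10L, ref_lengths = NULL) {
  sv <- as.list(sv)
  if (!is.null(ref_lengths)) {
    la <- ref_lengths$a[[sv$chrom_a]]; lb <- ref_lengths$b[[sv$chrom_b]]
    if (is.null(la) || sv$end_a > la || is.null(lb) || sv$end_b > lb)
      stop("SV ", sv$id, " lies outside the reference")
  }
  fa <- aln_features(aln_a)
  fb <- aln_features(aln_b)

  if (sv$sv_type == "inversion") {
    out <- data.frame(
      sv_id = sv$id, accession = accession, sv_type = sv$sv_type,
      present_allele = "A",
      split_present_bp1 = count_split_at(fb, sv$start_b, tol),
      split_present_bp2 = count_split_at(fb, sv$end_b, tol),
      split_absent_bp1 = count_split_at(fa, sv$start_a, tol),
      split_absent_bp2 = count_split_at(fa, sv$end_a, tol),
      span_present = min(count_span_at(fa, sv$start_a),
                         count_span_at(fa, sv$end_a)),
      span_absent = min(count_span_at(fb, sv$start_b),
                        count_span_at(fb, sv$end_b)),
      covered_frac_2x = NA_real_, left_flank_frac = NA_real_,
      right_flank_frac = NA_real_, stringsAsFactors = FALSE)
    return(out)
  }

  if (sv$sv_type == "deletion") {
    fc <- fa; fo <- fb
    cbp <- c(sv$start_a, sv$end_a); jo <- sv$start_b
    present <- "A"
  } else if (sv$sv_type == "insertion") {
    fc <- fb; fo <- fa
    cbp <- c(sv$start_b, sv$end_b); jo <- sv$start_a
    present <- "B"
  } else stop("unsupported sv_type: ", sv$sv_type)

  seg_len <- cbp[2] - cbp[1]
  from <- max(0L, cbp[1] - seg_len)
  cov <- coverage_profile(fc, from, cbp[2] + seg_len)
  idx_seg <- (cbp[1] - from + 1L):(cbp[2] - from)
  idx_lf <- seq_len(cbp[1] - from)
  idx_rf <- (cbp[2] - from + 1L):length(cov)
  split_pres <- count_split_at(fo, jo, tol)

  data.frame(
    sv_id = sv$id, accession = accession, sv_type = sv$sv_type,
    present_allele = present,
    split_present_bp1 = split_pres, split_present_bp2 = split_pres,
    split_absent_bp1 = count_split_at(fc, cbp[1], tol),
    split_absent_bp2 = count_split_at(fc, cbp[2], tol),
    span_present = min(count_span_at(fc, cbp[1]),
                       count_span_at(fc, cbp[2])),
    span_absent = count_span_at(fo, jo),
    covered_frac_2x = mean(cov[idx_seg] >= 2L),
    left_flank_frac = if (length(idx_lf)) mean(cov[idx_lf] >= 1L) else 0,
    right_flank_frac = if (length(idx_rf)) mean(cov[idx_rf] >= 1L) else 0,
    stringsAsFactors = FALSE)
}

#' Call an SV genotype from an evidence summary
#'
#' Decision rules: an inversion allele is supported only when every
#' breakpoint has at least 3 split reads.  An indel allele is supported by
#' at least 3 split reads at a breakpoint; the segment-absent allele is
#' alternatively supported by the depth rule (< 50% of the segment covered
#' at 2x while > 50% of at least one equal-length flank is covered), and the
#' segment-present allele by at least 3 spanning reads with > 50% of the
#' segment covered at 2x.  Both alleles supported gives a heterozygote, one
#' the corresponding homozygote, neither a missing call.  The function is
#' pure: identical summaries always give identical calls.
#'
#' @param ev one-row evidence summary from [collect_evidence()].
#' @param min_split minimum split reads per breakpoint.
#' @return one of `"A_HOM"`, `"B_HOM"`, `"HET"`, `"MISSING"`.
#' @export
call_genotype <- function(ev, min_split = 3L) {
  ev <- as.list(ev)
  if (ev$sv_type == "inversion") {
    sup_present <- ev$split_present_bp1 >= min_split &&
      ev$split_present_bp2 >= min_split
    sup_absent <- ev$split_absent_bp1 >= min_split &&
      ev$split_absent_bp2 >= min_split
  } else {
    sup_present <- max(ev$split_present_bp1, ev$split_present_bp2) >=
      min_split ||
      (ev$span_present >= min_split && isTRUE(ev$covered_frac_2x > 0.5))
    sup_absent <- max(ev$split_absent_bp1, ev$split_absent_bp2) >=
      min_split ||
      (isTRUE(ev$covered_frac_2x < 0.5) &&
         isTRUE(max(ev$left_flank_frac, ev$right_flank_frac) > 0.5))
  }
  pres <- ev$present_allele
  abs_allele <- if (pres == "A") "B" else "A"
  if (sup_present && sup_absent) return("HET")
  if (sup_present) return(paste0(pres, "_HOM"))
  if (sup_absent) return(paste0(abs_allele, "_HOM"))
  "MISSING"
}

#' Assemble a population genotype matrix from evidence summaries
#'
#' Calls every (SV, accession) evidence row with [call_genotype()] and
#' pivots the calls into a [genotype_matrix()].  Accessions with fewer than
#' `min_genotyped` of SVs genotyped (non-missing) are excluded; an accession
#' at the threshold exactly is retained.  Individual calls are never
#' altered, only columns dropped.
#'
#' @param evidence data.frame of stacked [collect_evidence()] rows.
#' @param sites optional per-SV site table (`sv_id`, `chrom`, `pos`, ...).
#' @param groups optional named group labels per accession (default
#'   `"other"`).
#' @param min_genotyped minimum genotyped fraction per accession.
#' @return a [genotype_matrix()]; the dropped accessions are recorded in the
#'   `dropped` element.
#' @export
build_genotype_matrix <- function(evidence, sites = NULL, groups = NULL,
                                  min_genotyped = 0.40) {
  if (is.null(evidence) || !nrow(evidence))
    stop("evidence collection is empty")
  if (anyDuplicated(paste(evidence$sv_id, evidence$accession)))
    stop("duplicated (sv, accession) evidence rows")
  calls <- vapply(seq_len(nrow(evidence)),
                  function(i) call_genotype(evidence[i, ]), character(1))
  dos <- call_to_dosage(calls)
  sv_ids <- unique(evidence$sv_id)
  acc <- unique(evidence$accession)
  m <- matrix(NA_integer_, length(sv_ids), length(acc),
              dimnames = list(sv_ids, acc))
  m[cbind(match(evidence$sv_id, sv_ids), match(evidence$accession, acc))] <-
    dos
  called_frac <- colMeans(!is.na(m))
  keep <- called_frac >= min_genotyped
  dropped <- acc[!keep]
  m <- m[, keep, drop = FALSE]
  acc <- acc[keep]
  if (is.null(groups)) {
    groups <- rep("other", length(acc)); names(groups) <- acc
  } else groups <- groups[acc]
  if (is.null(sites))
    sites <- data.frame(sv_id = sv_ids, chrom = NA_character_,
                        pos = NA_real_, sv_type = evidence$sv_type[
                          match(sv_ids, evidence$sv_id)],
                        stringsAsFactors = FALSE)
  else sites <- sites[match(sv_ids, sites$sv_id), , drop = FALSE]
  gm <- genotype_matrix(m, sites, groups)
  gm$dropped <- dropped
  gm
}

#' Genotype concordance between two call matrices
#'
#' Fraction of shared, mutually non-missing (SV, accession) cells with
#' identical calls, e.g. short-read calls versus an independent long-read
#' validation set.
#'
#' @param calls1,calls2 [genotype_matrix()] objects.
#' @return a single fraction in \[0, 1\].
#' @export
concordance <- function(calls1, calls2) {
  svs <- intersect(rownames(calls1$dosage), rownames(calls2$dosage))
  acc <- intersect(colnames(calls1$dosage), colnames(calls2$dosage))
  if (!length(svs) || !length(acc))
    stop("matrices share no (sv, accession) cells")
  d1 <- calls1$dosage[svs, acc, drop = FALSE]
  d2 <- calls2$dosage[svs, acc, drop = FALSE]
  both <- !is.na(d1) & !is.na(d2)
  if (!any(both)) stop("no shared non-missing cells")
  mean(d1[both] == d2[both])
}
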