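#' SV record tables
#'
#' SV sets are plain data.frames with columns `id`, `sv_type` (one of
#' insertion, deletion, inversion, repeat_contraction, repeat_expansion,
#' tandem_contraction, tandem_expansion), `chrom_a`, `start_a`, `end_a`,
#' `chrom_b`, `start_b`, `end_b` (0-based half-open; insertion intervals are
#' degenerate on the genome lacking the segment), `size` (bp, >= 10),
#' `sources` (comma-separated subset of `genome_alignment`,
#' `read_mapping_caller1`, `read_mapping_caller2`) and `validated`.
#' `check_sv_table()` enforces the invariants.
#'
#' @param svs data.frame of SV records.
#' @return `svs`, invisibly, after validation.
#' @export
check_sv_table <- function(svs) {
  need <- c("id", "sv_type", "chrom_a", "start_a", "end_a", "size")
  miss <- setdiff(need, names(svs))
  if (length(miss)) stop("missing SV columns: ", paste(miss, collapse = ", "))
  if (any(svs$size < 10)) stop("SV size below the 10-bp floor")
  if (any(svs$start_a > svs$end_a)) stop("start_a > end_a")
  inv <- svs$sv_type == "inversion"
  if (any(inv) && !is.null(svs$start_b)) {
    ok <- (svs$end_a - svs$start_a)[inv] == (svs$end_b - svs$start_b)[inv]
    if (any(!ok, na.rm = TRUE)) stop("inversion sizes differ between genomes")
  }
  invisible(svs)
}

interval_gap_distance <- function(s, e, gaps) {
  if (is.null(gaps) || !nrow(gaps)) return(Inf)
  d <- ifelse(gaps$start >= e, gaps$start - e,
              ifelse(gaps$end <= s, s - gaps$end, 0))
  min(d)
}

#' Remove SVs spanning or close to assembly gaps
#'
#' An SV is retained only if, on both genomes, its interval overlaps no gap
#' and lies at least `min_dist` bp from every gap.  Output preserves the
#' input order and is always a subset of the input.
#'
#' @param svs SV table (see [check_sv_table()]).
#' @param gaps_a,gaps_b gap tracks: data.frames with `chrom`, `start`, `end`
#'   (0-based half-open, sorted, non-overlapping); NULL means no gaps.
#' @param min_dist minimum distance to a gap in bp.
#' @return the retained subset of `svs`.
#' @export
filter_gap_proximity <- function(svs, gaps_a = NULL, gaps_b = NULL,
                                 min_dist = 50) {
  if (!nrow(svs)) return(svs)
  keep <- vapply(seq_len(nrow(svs)), function(i) {
    r <- svs[i, ]
    ga <- if (is.null(gaps_a)) NULL else
      gaps_a[gaps_a$chrom == r$chrom_a, , drop = FALSE]
    da <- interval_gap_distance(r$start_a, r$end_a, ga)
    db <- Inf
    if (!is.null(r$chrom_b) && !is.na(r$chrom_b) && !is.null(gaps_b)) {
      gb <- gaps_b[gaps_b$chrom == r$chrom_b, , drop = FALSE]
      db <- interval_gap_distance(r$start_b, r$end_b, gb)
    }
    min(da, db) >= min_dist
  }, logical(1))
  svs[keep, , drop = FALSE]
}

#' Validate an indel by flank-sequence anchoring
#'
#' The two 5-kb flanks of an indel, aligned against the query genome, must
#' each have a qualifying hit (alignment length > 50 bp, identity > 90%,
#' e-value < 1e-10) in the expected query region, and the geometry between
#' the two best hits must match the SV: for insertions the distance between
#' the hits must differ from the read-based size estimate by less than 20%
#' of that estimate; for deletions the gap or overlap between the hits must
#' be smaller than 3 bp.
#'
#' The expected region is centred on the record's projected position on the
#' query genome with a half-width of `2 * read_size_estimate + 10 kb`; rows
#' with no projected position skip the region check.
#'
#' @param sv one indel SV record.
#' @param hits data.frame of flank hits: `flank` ("left"/"right"),
#'   `hit_chrom`, `hit_start`, `hit_end`, `align_length`, `identity`
#'   (percent), `evalue`.
#' @param read_size_estimate SV size estimated from read mapping (bp).
#' @return TRUE or FALSE.
#' @export
validate_indel_flanks <- function(sv, hits, read_size_estimate) {
  sv <- as.list(sv)
  if (sv$sv_type == "inversion")
    stop("inversions are validated by validate_inversion()")
  if (is.null(hits) || !nrow(hits)) return(FALSE)
  ok <- hits$align_length > 50 & hits$identity > 90 & hits$evalue < 1e-10
  if (!is.null(sv$start_b) && !is.na(sv$start_b)) {
    half <- 2 * read_size_estimate + 10000
    ok <- ok & hits$hit_chrom == sv$chrom_b &
      hits$hit_start >= sv$start_b - half & hits$hit_end <= sv$end_b + half
  }
  hits <- hits[ok, , drop = FALSE]
  left <- hits[hits$flank == "left", , drop = FALSE]
  right <- hits[hits$flank == "right", , drop = FALSE]
  if (!nrow(left) || !nrow(right)) return(FALSE)
  left <- left[which.min(left$evalue), ]
  right <- right[which.min(right$evalue), ]
  between <- right$hit_start - left$hit_end
  if (sv$sv_type == "insertion")
    abs(between - read_size_estimate) < 0.2 * read_size_estimate
  else
    abs(between) < 3
}

READ_CALLERS <- c("read_mapping_caller1", "read_mapping_caller2")

#' Validate an inversion from breakpoint split reads or dual-caller support
#'
#' TRUE when more than 90% of the reads spanning every breakpoint are split
#' reads, or when the inversion was detected by both read-mapping callers.
#' A breakpoint with zero total reads makes the split-read criterion fail
#' (insufficient evidence) rather than raising an error.
#'
#' @param sv one inversion SV record (unused beyond its type; kept for a
#'   uniform operation signature).
#' @param breakpoint_reads data.frame with one row per breakpoint and
#'   columns `split_count` and `spanning_total` (total reads spanning the
#'   breakpoint, split reads included).
#' @param caller_support character vector of supporting sources.
#' @return TRUE or FALSE.
#' @export
validate_inversion <- function(sv, breakpoint_reads, caller_support) {
  if (any(breakpoint_reads$split_count < 0 |
            breakpoint_reads$spanning_total < 0))
    stop("read counts must be >= 0")
  both <- all(READ_CALLERS %in% caller_support)
  split_ok <- all(breakpoint_reads$spanning_total > 0) &&
    all(breakpoint_reads$split_count / breakpoint_reads$spanning_total > 0.9)
  split_ok || both
}

REPEAT_TYPES <- c("repeat_contraction", "repeat_expansion",
                  "tandem_contraction", "tandem_expansion")

#' Convert repeat/tandem expansion-contraction calls into simple indels
#'
#' Genome-alignment callers report repeat-length changes as fuzzy
#' expansion/contraction intervals.  Each such record that contains at least
#' one precise read-mapping indel within its genome-A interval is replaced
#' by those indel record(s); records without a precise match are dropped.
#' Simple indel and inversion records pass through unchanged.
#'
#' @param assemblytics_style SV table possibly containing repeat/tandem
#'   types (genome-A coordinates).
#' @param precise_breakpoints SV table of precise read-mapping indels on the
#'   same coordinates.
#' @return SV table with only simple types.
#' @export
normalize_repeat_svs <- function(assemblytics_style, precise_breakpoints) {
  out <- list()
  for (i in seq_len(nrow(assemblytics_style))) {
    r <- assemblytics_style[i, ]
    if (!r$sv_type %in% REPEAT_TYPES) {
      out[[length(out) + 1L]] <- r
      next
    }
    hit <- precise_breakpoints$chrom_a == r$chrom_a &
      precise_breakpoints$start_a >= r$start_a &
      precise_breakpoints$end_a <= r$end_a &
      precise_breakpoints$sv_type %in% c("insertion", "deletion")
    if (!any(hit)) next  # no precise breakpoints: dropped
    rep_rows <- precise_breakpoints[hit, , drop = FALSE]
    rep_rows$sources <- vapply(rep_rows$sources, function(s)
      merge_sources(s, r$sources), character(1))
    out[[length(out) + 1L]] <- rep_rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- assemblytics_style[0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

merge_sources <- function(a, b) {
  paste(sort(unique(c(strsplit(a %||% "", ",")[[1]],
                      strsplit(b %||% "", ",")[[1]]))), collapse = ",")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / pmax(e1 - s1, 1e-9), ov / pmax(e2 - s2, 1e-9))
}

#' Merge two SV sets by reciprocal overlap
#'
#' Two same-type records are combined when their genome-A intervals overlap
#' by more than `reciprocal` of both lengths.  Insertions, whose genome-A
#' interval is degenerate, are instead combined when their breakpoints lie
#' within `ins_bp_dist` bp and their size ratio exceeds `reciprocal`.
#' A combined record keeps the set-1 coordinates and the union of sources.
#' When a record overlaps several partners the pair with the larger
#' reciprocal overlap wins; remaining ties break by leftmost start, making
#' the output deterministic.  Merging a set with itself returns one record
#' per input record.
#'
#' @param set1,set2 SV tables on the same coordinate system.
#' @param reciprocal required overlap fraction of both records.
#' @param ins_bp_dist breakpoint tolerance for insertion pairing (bp).
#' @return merged SV table (set-1 records possibly augmented with set-2
#'   sources, plus unmatched records of both sets), sorted by position.
#' @export
merge_sv_sets <- function(set1, set2, reciprocal = 0.5, ins_bp_dist = 100) {
  if (!nrow(set1) && !nrow(set2)) return(set1)
  cand <- list()
  for (i in seq_len(nrow(set1))) {
    r <- set1[i, ]
    same <- which(set2$sv_type == r$sv_type & set2$chrom_a == r$chrom_a)
    if (!length(same)) next
    s2 <- set2[same, , drop = FALSE]
    if (r$sv_type == "insertion") {
      score <- ifelse(abs(s2$start_a - r$start_a) <= ins_bp_dist,
                      pmin(s2$size, r$size) / pmax(s2$size, r$size), 0)
    } else {
      score <- reciprocal_overlap(r$start_a, r$end_a, s2$start_a, s2$end_a)
    }
    sel <- score > reciprocal
    if (any(sel))
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = same[sel], score = score[sel],
        start = r$start_a, stringsAsFactors = FALSE)
  }
  used1 <- logical(nrow(set1)); used2 <- logical(nrow(set2))
  merged <- list()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, cand$start, cand$i, cand$j), ,
                 drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used1[i] || used2[j]) next
      used1[i] <- TRUE; used2[j] <- TRUE
      r <- set1[i, ]
      r$sources <- merge_sources(r$sources, set2$sources[j])
      merged[[length(merged) + 1L]] <- r
    }
  }
  out <- rbind(do.call(rbind, merged),
               set1[!used1, , drop = FALSE],
               set2[!used2, , drop = FALSE])
  out <- out[order(out$chrom_a, out$start_a, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full reference-SV validation pipeline
#'
#' Chains the validation operations the way the reference SV set is built:
#' gap-proximity filtering of both call sets, inversion validation by
#' breakpoint split-read fraction or dual-caller support, indel validation
#' by flank anchoring, conversion of repeat/tandem records into precise
#' indels, and reciprocal-overlap merging of the genome-alignment and
#' read-mapping sets.
#'
#' @param assemblytics genome-alignment SV table (may contain repeat types).
#' @param read_calls read-mapping SV table.
#' @param flank_hits named list (by SV id) of flank-hit tables for indels in
#'   `assemblytics`.
#' @param inversion_evidence named list (by SV id) with elements
#'   `breakpoint_reads` and `caller_support`.
#' @param gaps_a,gaps_b gap tracks (see [filter_gap_proximity()]).
#' @param min_gap_dist,reciprocal tuning parameters.
#' @return validated, merged SV table with `validated = TRUE`.
#' @export
build_reference_sv_set <- function(assemblytics, read_calls,
                                   flank_hits = list(),
                                   inversion_evidence = list(),
                                   gaps_a = NULL, gaps_b = NULL,
                                   min_gap_dist = 50, reciprocal = 0.5) {
  assemblytics <- filter_gap_proximity(assemblytics, gaps_a, gaps_b,
                                       min_gap_dist)
  read_calls <- filter_gap_proximity(read_calls, gaps_a, gaps_b,
                                     min_gap_dist)
  keep <- vapply(seq_len(nrow(assemblytics)), function(i) {
    r <- assemblytics[i, ]
    if (r$sv_type == "inversion") {
      ev <- inversion_evidence[[r$id]]
      if (is.null(ev)) return(FALSE)
      validate_inversion(r, ev$breakpoint_reads, ev$caller_support)
    } else if (r$sv_type %in% c("insertion", "deletion")) {
      hits <- flank_hits[[r$id]]
      validate_indel_flanks(r, hits, r$size)
    } else TRUE  # repeat records are resolved by normalize_repeat_svs
  }, logical(1))
  assemblytics <- assemblytics[keep, , drop = FALSE]
  assemblytics <- normalize_repeat_svs(assemblytics, read_calls)
  out <- merge_sv_sets(assemblytics, read_calls, reciprocal)
  out <- out[!duplicated(paste(out$sv_type, out$chrom_a, out$start_a,
                               out$end_a, out$size)), , drop = FALSE]
  out$validated <- TRUE
  rownames(out) <- NULL
  out
}
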