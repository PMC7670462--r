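#' Derive caller-style SV record sets from a simulated truth set
#'
#' Emulates the raw inputs of the reference-SV validation stage: a
#' genome-alignment call set (in which a fraction of indels is reported as
#' fuzzy repeat/tandem expansion-contraction intervals), a read-mapping call
#' set with small breakpoint jitter, flank-hit tables consistent with each
#' true indel, and per-inversion breakpoint read support.  With
#' `decoys = TRUE`, known-bad records are added — an indel next to an
#' assembly gap, an indel whose flank hit fails the identity criterion, and
#' an inversion with weak split-read support from a single caller — along
#' with gap tracks; a correct validation pipeline removes all of them.
#'
#' @param truth truth set from [simulate_genome_pair()].
#' @param config a [sim_config()] object.
#' @param repeat_frac fraction of indels reported as repeat-typed records by
#'   the genome-alignment caller.
#' @param jitter_sd SD (bp) of read-mapping breakpoint jitter.
#' @param decoys add known-false records and gap tracks.
#' @return list with `assemblytics`, `read_calls`, `flank_hits`,
#'   `inversion_evidence`, `gaps_a`, `gaps_b`.
#' @export
simulate_sv_callsets <- function(truth, config, repeat_frac = 0.3,
                                 jitter_sd = 2, decoys = TRUE) {
  set.seed(stage_seed(config, "callsets"))
  svs <- truth$svs
  svs$sources <- "genome_alignment"
  svs$validated <- FALSE

  indel <- svs$sv_type %in% c("insertion", "deletion")
  asm <- svs
  as_repeat <- which(indel & stats::runif(nrow(svs)) < repeat_frac)
  for (i in as_repeat) {
    pad <- 30L + sample.int(40L, 1L)
    asm$sv_type[i] <- if (svs$sv_type[i] == "deletion")
      "repeat_contraction" else "tandem_expansion"
    asm$start_a[i] <- max(0L, asm$start_a[i] - pad)
    asm$end_a[i] <- asm$end_a[i] + pad
  }

  rc <- svs[indel, , drop = FALSE]
  if (nrow(rc)) {
    shift <- as.integer(round(stats::rnorm(nrow(rc), 0, jitter_sd)))
    rc$start_a <- pmax(0L, rc$start_a + shift)
    rc$end_a <- ifelse(rc$sv_type == "insertion", rc$start_a,
                       rc$start_a + rc$size)
    rc$id <- paste0(rc$id, "_rm")
    rc$sources <- ifelse(stats::runif(nrow(rc)) < 0.7,
                         paste(READ_CALLERS, collapse = ","),
                         READ_CALLERS[1])
  }

  flank_hits <- list()
  for (i in which(asm$sv_type %in% c("insertion", "deletion"))) {
    r <- asm[i, ]
    flank_hits[[r$id]] <- data.frame(
      flank = c("left", "right"), hit_chrom = r$chrom_b,
      hit_start = c(r$start_b - 5000, r$end_b),
      hit_end = c(r$start_b, r$end_b + 5000),
      align_length = 5000, identity = 99.5, evalue = 1e-60,
      stringsAsFactors = FALSE)
  }

  inversion_evidence <- list()
  for (i in which(asm$sv_type == "inversion")) {
    tot <- pmax(10L, stats::rpois(2L, 25))
    spl <- round(tot * stats::runif(2L, 0.93, 1.0))
    inversion_evidence[[asm$id[i]]] <- list(
      breakpoint_reads = data.frame(split_count = spl,
                                    spanning_total = tot),
      caller_support = READ_CALLERS)
  }

  gaps_a <- gaps_b <- data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), stringsAsFactors = FALSE)
  if (decoys) {
    ch <- svs$chrom_a[1]
    far <- max(svs$end_a[svs$chrom_a == ch]) + 20000
    gaps_a <- data.frame(chrom = ch, start = far + 120, end = far + 400)
    decoy_gap <- data.frame(
      id = "DECOY_GAP", sv_type = "deletion", chrom_a = ch,
      start_a = far, end_a = far + 80, chrom_b = ch,
      start_b = far, end_b = far, size = 80,
      sources = "genome_alignment", validated = FALSE,
      stringsAsFactors = FALSE)
    decoy_flank <- decoy_gap
    decoy_flank$id <- "DECOY_FLANK"
    decoy_flank$start_a <- far + 5000
    decoy_flank$end_a <- far + 5080
    decoy_flank$start_b <- decoy_flank$end_b <- far + 5000
    flank_hits[["DECOY_FLANK"]] <- data.frame(
      flank = c("left", "right"), hit_chrom = ch,
      hit_start = c(far, far + 5000), hit_end = c(far + 5000, far + 10000),
      align_length = 5000, identity = 85, evalue = 1e-60,
      stringsAsFactors = FALSE)
    decoy_inv <- decoy_gap
    decoy_inv$id <- "DECOY_INV"
    decoy_inv$sv_type <- "inversion"
    decoy_inv$start_a <- far + 11000; decoy_inv$end_a <- far + 11500
    decoy_inv$start_b <- far + 11000; decoy_inv$end_b <- far + 11500
    decoy_inv$size <- 500
    inversion_evidence[["DECOY_INV"]] <- list(
      breakpoint_reads = data.frame(split_count = c(8, 9),
                                    spanning_total = c(10, 10)),
      caller_support = READ_CALLERS[1])
    asm <- rbind(asm, decoy_gap, decoy_flank, decoy_inv)
  }

  list(assemblytics = asm, read_calls = rc, flank_hits = flank_hits,
       inversion_evidence = inversion_evidence,
       gaps_a = gaps_a, gaps_b = gaps_b)
}
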