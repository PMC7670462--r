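#' Simulate a pair of reference genomes differing by planted SVs and SNPs
#'
#' Generates a random genome A (wild-reference-like) and derives genome B
#' (cultivar-reference-like) from it by applying planted deletions (segment
#' present in A, absent in B), insertions (the reverse), inversions, and
#' SNPs.  The truth set records every variant with breakpoints on both
#' coordinate systems.  Planted SVs never overlap: each chromosome is
#' partitioned into equal slots and one SV is placed per slot with generous
#' margins, so local read-evidence windows of different SVs stay disjoint.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genome_a`, `genome_b` (named character
#'   vectors of chromosome sequences) and `truth` (class `"sv_truth"`: list
#'   with data.frames `svs` and `snps`).
#' @export
simulate_genome_pair <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "genome"))
  n_chrom <- config$n_chromosomes
  len <- as.integer(config$chrom_length)
  chroms <- paste0("chr", seq_len(n_chrom))

  acgt <- utf8ToInt("ACGT")
  genome_a <- vapply(chroms, function(ch) {
    intToUtf8(acgt[sample.int(4L, len, replace = TRUE)])
  }, character(1))

  types <- c(rep("deletion", config$n_deletions),
             rep("insertion", config$n_insertions),
             rep("inversion", config$n_inversions))
  n_sv <- length(types)
  svs <- empty_sv_plan()
  if (n_sv > 0) {
    types <- sample(types)
    chrom_of <- sort(rep_len(seq_len(n_chrom), n_sv))
    margin <- max(1000L, 3L * config$read_length)
    edge <- margin
    max_size <- config$sv_size_range[2]
    plan <- vector("list", n_sv)
    k <- 0L
    for (ci in seq_len(n_chrom)) {
      idx <- which(chrom_of == ci)
      if (!length(idx)) next
      usable <- len - 2L * edge
      slot <- floor(usable / length(idx))
      if (slot < max_size + 2 * margin)
        stop("SV plan exceeds capacity of chromosome ", chroms[ci])
      for (j in seq_along(idx)) {
        k <- k + 1L
        size <- as.integer(config$sv_size_range[1]) +
          sample.int(as.integer(max_size - config$sv_size_range[1]) + 1L,
                     1L) - 1L
        slack <- slot - size - 2L * margin
        start <- edge + (j - 1L) * slot + margin +
          sample.int(slack + 1L, 1L) - 1L
        plan[[k]] <- data.frame(chrom = chroms[ci], start = start,
                                size = size, sv_type = types[k],
                                stringsAsFactors = FALSE)
      }
    }
    svs <- do.call(rbind, plan)
    svs <- svs[order(svs$chrom, svs$start), , drop = FALSE]
    svs$id <- sprintf("SV%05d", seq_len(n_sv))
  }

  # SNPs outside SV neighbourhoods
  snps <- lapply(chroms, function(ch) {
    n_snp <- stats::rbinom(1L, len, config$snp_rate)
    if (n_snp == 0) return(NULL)
    pos <- sort(sample.int(len, n_snp) - 1L)
    if (nrow(svs)) {
      sv_c <- svs[svs$chrom == ch, , drop = FALSE]
      if (nrow(sv_c)) {
        near <- vapply(pos, function(p) {
          any(p >= sv_c$start - 100 &
                p < sv_c$start + ifelse(sv_c$sv_type == "insertion",
                                        0, sv_c$size) + 100)
        }, logical(1))
        pos <- pos[!near]
      }
    }
    if (!length(pos)) return(NULL)
    ref <- substring(genome_a[[ch]], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), character(1))
    data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snps)
  if (is.null(snps))
    snps <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character())
  rownames(snps) <- NULL

  built <- apply_edits(genome_a, svs, snps)

  truth <- structure(list(svs = built$svs, snps = snps,
                          seed = config$seed),
                     class = "sv_truth")
  list(genome_a = genome_a, genome_b = built$genome_b, truth = truth)
}

empty_sv_plan <- function() {
  data.frame(chrom = character(), start = integer(), size = integer(),
             sv_type = character(), id = character(),
             stringsAsFactors = FALSE)
}

# Apply SNP substitutions and SV edits to genome A, tracking B coordinates.
apply_edits <- function(genome_a, svs, snps) {
  genome_b <- genome_a
  # SNPs first (they sit outside SV neighbourhoods, so coordinates on A)
  for (ch in names(genome_b)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    seqc <- genome_b[[ch]]
    for (i in seq_len(nrow(s)))
      substr(seqc, s$pos[i] + 1L, s$pos[i] + 1L) <- s$alt[i]
    genome_b[[ch]] <- seqc
  }

  cols <- c("id", "sv_type", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b", "size")
  if (!nrow(svs)) {
    out <- data.frame(id = character(), sv_type = character(),
                      chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      size = integer(), stringsAsFactors = FALSE)
    return(list(genome_b = genome_b, svs = out))
  }
  out <- svs
  out$start_a <- out$start
  out$end_a <- ifelse(out$sv_type == "insertion", out$start,
                      out$start + out$size)
  out$start <- NULL
  out$chrom_a <- out$chrom
  out$chrom_b <- out$chrom
  out$chrom <- NULL
  out$start_b <- NA_integer_
  out$end_b <- NA_integer_

  for (ch in names(genome_b)) {
    idx <- which(out$chrom_a == ch)
    seqc <- genome_b[[ch]]
    if (!length(idx)) next
    pieces <- character(0)
    cursor <- 0L   # 0-based position on (SNP-substituted) A
    delta <- 0L    # current B-minus-A offset
    for (i in idx) {
      s <- out$start_a[i]; e <- out$end_a[i]
      pieces <- c(pieces, substring(seqc, cursor + 1L, s))
      tp <- out$sv_type[i]
      if (tp == "deletion") {
        out$start_b[i] <- s + delta
        out$end_b[i] <- s + delta
        delta <- delta - out$size[i]
      } else if (tp == "insertion") {
        ins <- paste(sample(c("A", "C", "G", "T"), out$size[i],
                            replace = TRUE), collapse = "")
        pieces <- c(pieces, ins)
        out$start_b[i] <- s + delta
        out$end_b[i] <- s + delta + out$size[i]
        delta <- delta + out$size[i]
      } else if (tp == "inversion") {
        seg <- substring(seqc, s + 1L, e)
        pieces <- c(pieces, revcomp(seg))
        out$start_b[i] <- s + delta
        out$end_b[i] <- e + delta
      } else stop("unknown sv_type: ", tp)
      cursor <- e
    }
    pieces <- c(pieces, substring(seqc, cursor + 1L, nchar(seqc)))
    genome_b[[ch]] <- paste(pieces, collapse = "")
  }

  cols <- c("id", "sv_type", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b", "size")
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  list(genome_b = genome_b, svs = out)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' @export
print.sv_truth <- function(x, ...) {
  cat("SV truth set: ", nrow(x$svs), " SVs, ", nrow(x$snps), " SNPs\n",
      sep = "")
  if (nrow(x$svs))
    print(table(x$svs$sv_type))
  invisible(x)
}
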