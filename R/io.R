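#' Read and write FASTA genomes
#'
#' Thin wrappers over Biostrings keeping genomes as named character vectors
#' internally.
#'
#' @param seqs named character vector of chromosome sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("empty FASTA: ", path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write and read alignment records as SAM text
#'
#' Emits a coordinate-sorted SAM file with `@SQ` lines for the given
#' references; split reads carry their partner in the `SA` tag
#' (supplementary-alignment convention).  The reader accepts any SAM text
#' file and keeps the fields this package consumes (qname, flag, rname,
#' pos, mapq, cigar, seq, SA tag).
#'
#' @param aln alignment data.frame (see [simulate_read_evidence()]).
#' @param ref_lengths named vector of reference lengths for the header.
#' @param path file path.
#' @return `read_sam()` returns an alignment data.frame.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  aln <- aln[order(aln$rname, aln$pos), , drop = FALSE]
  body <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    r <- aln[i, ]
    fields <- c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                "*", 0, 0, r$seq, strrep("I", nchar(r$seq)))
    if (!is.na(r$sa)) fields <- c(fields, paste0("SA:Z:", r$sa))
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_aln())
  out <- empty_aln()[rep(1L, 0), ]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("malformed SAM record in ", path, " at line ", i)
    sa <- NA_character_
    if (length(f) > 11) {
      tag <- grep("^SA:Z:", f[12:length(f)], value = TRUE)
      if (length(tag)) sa <- sub("^SA:Z:", "", tag[1])
    }
    rows[[i]] <- data.frame(qname = f[1], flag = as.integer(f[2]),
                            rname = f[3], pos = as.integer(f[4]),
                            mapq = as.integer(f[5]), cigar = f[6],
                            seq = f[10], sa = sa, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$pos)) stop("malformed SAM positions in ", path)
  out
}

#' Write an SV set as a symbolic-ALT VCF
#'
#' One record per SV with `<DEL>`, `<INS>` or `<INV>` alleles and `SVTYPE`,
#' `END`, `SVLEN` INFO keys; coordinates are emitted 1-based on genome A
#' (the internal 0-based half-open interval `[start, end)` becomes
#' `POS = start` anchored one base before the event, `END = end`, per the
#' symbolic-SV convention).  The B-genome interval is carried in
#' `CHR2/START2/END2` so records round-trip.
#'
#' @param svs SV table (see [check_sv_table()]).
#' @param path file path.
#' @return `read_sv_vcf()` returns an SV table.
#' @export
write_sv_vcf <- function(svs, path) {
  alt_of <- c(deletion = "<DEL>", insertion = "<INS>", inversion = "<INV>")
  hdr <- c("##fileformat=VCFv4.3",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"B chrom\">",
           "##INFO=<ID=START2,Number=1,Type=Integer,Description=\"B start (0-based)\">",
           "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"B end (0-based)\">",
           "##INFO=<ID=SOURCES,Number=1,Type=String,Description=\"Callers\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  svlen <- ifelse(svs$sv_type == "deletion", -svs$size, svs$size)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;CHR2=%s;START2=%d;END2=%d;SOURCES=%s",
                  toupper(substr(sub("_.*", "", svs$sv_type), 1, 3)),
                  as.integer(svs$end_a), as.integer(svlen),
                  svs$chrom_b, as.integer(svs$start_b),
                  as.integer(svs$end_b),
                  if (!is.null(svs$sources)) svs$sources else ".")
  body <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s",
                  svs$chrom_a, pmax(1L, as.integer(svs$start_a)), svs$id,
                  alt_of[svs$sv_type], info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  ifelse(lengths(regmatches(info, gregexpr(paste0(key, "="), info))) > 0,
         sub(paste0(".*", key, "="), "", m), NA)
}

#' @rdname write_sv_vcf
#' @export
read_sv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single record drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  type_of <- c(DEL = "deletion", INS = "insertion", INV = "inversion")
  data.frame(
    id = fix$ID,
    sv_type = unname(type_of[info_field(info, "SVTYPE")]),
    chrom_a = fix$CHROM,
    start_a = as.integer(fix$POS),
    end_a = as.integer(info_field(info, "END")),
    chrom_b = info_field(info, "CHR2"),
    start_b = as.integer(info_field(info, "START2")),
    end_b = as.integer(info_field(info, "END2")),
    size = abs(as.integer(info_field(info, "SVLEN"))),
    sources = info_field(info, "SOURCES"),
    validated = TRUE, stringsAsFactors = FALSE)
}

#' Write and read a population genotype matrix
#'
#' The TSV layout is one row per SV and one column per accession, calls
#' coded `0/1/2/NA` for B-homozygote, heterozygote, A-homozygote and
#' missing (documented in the file header).  The VCF flavour uses `GT`
#' with the B allele as REF: `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @return readers return a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(gm, path) {
  hdr <- c("# SV genotype matrix",
           "# coding: 0=B_HOM 1=HET 2=A_HOM NA=MISSING (dosage of the A/wild allele)",
           paste0("# groups: ",
                  paste(names(gm$groups), gm$groups, sep = "=",
                        collapse = ",")))
  df <- cbind(gm$sites[, c("sv_id", "chrom", "pos", "sv_type")],
              as.data.frame(gm$dosage))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path, n = 20)
  gl <- grep("^# groups:", lines, value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("sv_id", "chrom", "pos", "sv_type")
  acc <- setdiff(names(df), meta)
  groups <- rep("other", length(acc))
  names(groups) <- acc
  if (length(gl)) {
    kv <- strsplit(strsplit(sub("^# groups: ", "", gl[1]), ",")[[1]], "=")
    g <- vapply(kv, `[`, character(1), 2)
    names(g) <- vapply(kv, `[`, character(1), 1)
    groups[names(g)[names(g) %in% acc]] <- g[names(g) %in% acc]
  }
  genotype_matrix(as.matrix(df[, acc, drop = FALSE]),
                  df[, meta, drop = FALSE], groups)
}

#' @rdname write_genotype_tsv
#' @export
write_genotype_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.3",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gm$dosage)), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(gm$dosage)), function(i) {
    d <- gm$dosage[i, ]
    gt <- ifelse(is.na(d), "./.", gt_of[d + 1L])
    s <- gm$sites[i, ]
    paste(c(s$chrom, max(1L, as.integer(s$pos)), s$sv_id, "B", "A", ".",
            "PASS",
            sprintf("SVTYPE=%s;END=%d", s$sv_type,
                    as.integer(if (!is.null(s$end) && !is.na(s$end)) s$end
                               else s$pos + 1L)),
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param groups named group labels for the accession columns (defaults to
#'   `"other"`).
#' @export
read_genotype_vcf <- function(path, groups = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt == "0/1" | gt == "1/0"] <- 1L
  dos[gt == "1/1"] <- 2L
  info <- vcfR::getINFO(v)
  sites <- data.frame(sv_id = fix$ID, chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      end = as.integer(info_field(info, "END")),
                      sv_type = info_field(info, "SVTYPE"),
                      stringsAsFactors = FALSE)
  if (is.null(groups)) {
    groups <- rep("other", ncol(dos)); names(groups) <- colnames(dos)
  }
  genotype_matrix(dos, sites, groups[colnames(dos)])
}

#' Accession group labels
#'
#' Two-column TSV (`accession`, `group`).
#'
#' @param groups named character vector of group labels.
#' @param path file path.
#' @return `read_group_tsv()` returns a named character vector.
#' @export
write_group_tsv <- function(groups, path) {
  utils::write.table(data.frame(accession = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_tsv
#' @export
read_group_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$group, df$accession)
}

#' Gene models from GFF3
#'
#' Imports gene features and derives transcription start/stop sites by
#' strand (minus-strand genes: TSS = feature end, TES = feature start).
#' Coordinates are returned 0-based.
#'
#' @param path GFF3 file.
#' @return data.frame `gene_id`, `chrom`, `tss`, `tes`, `strand`.
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[gr$type == "gene", , drop = FALSE]
  if (!nrow(gr)) stop("no gene feature in ", path)
  st <- as.character(gr$strand)
  start0 <- gr$start - 1L
  end0 <- gr$end - 1L
  ids <- if (!is.null(gr$ID)) gr$ID else
    if (!is.null(gr$Name)) gr$Name else as.character(seq_len(nrow(gr)))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(gr$seqnames),
             tss = ifelse(st == "-", end0, start0),
             tes = ifelse(st == "-", start0, end0),
             strand = st, stringsAsFactors = FALSE)
}

#' @rdname read_gff_genes
#' @param genes gene coordinate data.frame (0-based `tss`/`tes`).
#' @export
write_gff_genes <- function(genes, path) {
  plus <- genes$strand != "-"
  start1 <- ifelse(plus, genes$tss, genes$tes) + 1L
  end1 <- ifelse(plus, genes$tes, genes$tss) + 1L
  lines <- sprintf("%s\tsvdomest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, start1, end1, genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' BED-format interval output (0-based half-open)
#'
#' @param df data.frame whose first three columns are chrom, start, end;
#'   extra columns become BED name/score fields.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Expression matrix TSV (genes x accessions)
#'
#' @param expr numeric matrix with gene ids as rownames.
#' @param path file path.
#' @return `read_expression_tsv()` returns a numeric matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Save and restore a simulation configuration as YAML
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config_yaml()` returns a [sim_config()].
#' @export
write_sim_config_yaml <- function(config, path) {
  x <- unclass(config)
  for (f in c("selected_loci", "introgression_blocks", "cis_effects"))
    if (!is.null(x[[f]])) x[[f]] <- as.list(as.data.frame(x[[f]]))
  for (f in c("group_sizes", "group_freq_a"))
    x[[f]] <- as.list(x[[f]])              # keep names as a YAML map
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("selected_loci", "introgression_blocks", "cis_effects"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]],
                                                  stringsAsFactors = FALSE)
  for (f in c("group_sizes", "group_freq_a"))
    x[[f]] <- unlist(x[[f]])
  if (!is.null(x$hotspot))
    x$hotspot$targets <- unlist(x$hotspot$targets)
  do.call(sim_config, x)
}
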