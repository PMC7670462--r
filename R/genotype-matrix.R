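#' SV genotype matrix
#'
#' Container for population SV genotypes.  Calls are stored as integer
#' dosages of the A (wild-reference) allele: 2 = homozygous A, 1 =
#' heterozygous, 0 = homozygous B, NA = missing/undetermined.  This matches
#' the flat-matrix export convention (`0/1/2/NA` coding) used by
#' [write_genotype_tsv()].
#'
#' @param dosage integer matrix, one row per SV, one column per accession.
#' @param sites data.frame describing the rows, with at least columns
#'   `sv_id`, `chrom`, `pos` (bp, 0-based) and `sv_type`.
#' @param groups named character vector (one entry per accession column)
#'   with values among `SP`, `SCG`, `SLC`, `heirloom`, `modern`, `other`.
#'
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage`, `sites`, `groups`.
#' @export
genotype_matrix <- function(dosage, sites, groups) {
  dosage <- as.matrix(dosage)
  mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites))
    stop("sites must describe every row of the dosage matrix")
  if (ncol(dosage) != length(groups))
    stop("groups must label every accession column")
  if (is.null(names(groups))) names(groups) <- colnames(dosage)
  bad <- setdiff(unique(groups), valid_groups())
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- sites$sv_id
  colnames(dosage) <- names(groups)
  structure(list(dosage = dosage, sites = as.data.frame(sites),
                 groups = groups),
            class = "genotype_matrix")
}

valid_groups <- function() c("SP", "SCG", "SLC", "heirloom", "modern", "other")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("SV genotype matrix: ", nrow(x$dosage), " SVs x ", ncol(x$dosage),
      " accessions\n", sep = "")
  tab <- table(factor(x$groups, levels = valid_groups()))
  tab <- tab[tab > 0]
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Convert dosages to genotype state labels
#'
#' @param dosage integer vector/matrix of A-allele dosages.
#' @return character of the same shape with values `A_HOM`, `HET`, `B_HOM`,
#'   `MISSING`.
#' @export
dosage_to_call <- function(dosage) {
  out <- ifelse(is.na(dosage), "MISSING",
                c("B_HOM", "HET", "A_HOM")[dosage + 1L])
  if (is.matrix(dosage)) dim(out) <- dim(dosage)
  out
}

#' @rdname dosage_to_call
#' @param call character vector of genotype state labels.
#' @export
call_to_dosage <- function(call) {
  d <- c(A_HOM = 2L, HET = 1L, B_HOM = 0L, MISSING = NA_integer_)[call]
  unname(d)
}
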