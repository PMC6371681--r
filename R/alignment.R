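# Alignment input and pattern counting. Alignments are plain character
# matrices (taxa in rows, sites in columns, upper-case A/C/G/T); readers
# wrap ape so the standard formats behave as elsewhere in the field.

.as_char_alignment <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(aln))
  if (is.list(aln)) aln <- do.call(rbind, lapply(aln, function(s) {
    if (length(s) == 1L) strsplit(toupper(s), "")[[1]] else toupper(s)
  }))
  if (!is.matrix(aln)) stop("alignment must be a matrix, DNAbin or list of sequences")
  aln <- toupper(aln)
  if (!all(aln %in% c("A", "C", "G", "T")))
    stop("alignment contains non-ACGT symbols (gaps and ambiguity codes are not supported)")
  aln
}

#' Read a nucleotide alignment
#'
#' Reads a FASTA or sequential PHYLIP alignment of 3 or 4 equal-length,
#' ungapped nucleotide sequences into the plain character-matrix form used
#' by [count_patterns()].
#'
#' @param file Path to the alignment file.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return Character matrix with one row per taxon.
#' @export
read_alignment <- function(file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  dna <- if (format == "fasta") ape::read.FASTA(file)
         else ape::read.dna(file, format = "sequential")
  if (inherits(dna, "DNAbin") && is.list(dna)) {
    len <- lengths(dna)
    if (length(unique(len)) != 1L) stop("sequences have unequal lengths")
    dna <- as.matrix(dna)
  }
  .as_char_alignment(dna)
}

#' Count site-pattern classes in a small alignment
#'
#' Collapses each column of a 3- or 4-taxon alignment to its Jukes-Cantor
#' pattern class and counts the classes. Site order is irrelevant; the
#' counts are the sufficient statistic for all inference in the package.
#'
#' @param aln Character matrix (taxa x sites), `DNAbin`, or list of strings;
#'   3 or 4 rows, A/C/G/T only.
#' @return Named count vector of length 5 (three taxa, order of
#'   [pattern_classes_3()]) or 15 (four taxa, order of
#'   [pattern_classes_4()]), with attribute `n` giving the number of sites.
#' @export
#' @examples
#' aln <- rbind(A = c("A", "A", "G"), B = c("A", "A", "G"), C = c("A", "C", "G"))
#' count_patterns(aln)
count_patterns <- function(aln) {
  aln <- .as_char_alignment(aln)
  ntax <- nrow(aln)
  n <- ncol(aln)
  if (!ntax %in% c(3L, 4L)) stop("alignment must have 3 or 4 sequences")
  if (ntax == 3L) {
    eq12 <- aln[1, ] == aln[2, ]
    eq13 <- aln[1, ] == aln[3, ]
    eq23 <- aln[2, ] == aln[3, ]
    cls <- ifelse(eq12 & eq13, 1L,
           ifelse(eq12, 2L, ifelse(eq13, 3L, ifelse(eq23, 4L, 5L))))
    out <- setNames(tabulate(cls, 5L), .classes3)
  } else {
    cls4 <- .pattern_classes4()
    key <- apply(aln, 2, function(col) {
      first <- unique(col)
      paste(match(col, first) - 1L, collapse = "")
    })
    idx <- match(key, cls4$label)
    out <- setNames(tabulate(idx, 15L), cls4$name)
  }
  attr(out, "n") <- n
  out
}

#' Write a nucleotide alignment
#'
#' @param aln Character matrix (taxa x sites).
#' @param file Output path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return Invisibly, `file`.
#' @export
write_alignment <- function(aln, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  aln <- .as_char_alignment(aln)
  if (is.null(rownames(aln)))
    rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
  seqs <- apply(aln, 1, paste, collapse = "")
  lines <- if (format == "fasta")
    as.vector(rbind(paste0(">", rownames(aln)), seqs))
  else c(paste(nrow(aln), ncol(aln)),
         paste(sprintf("%-10s", rownames(aln)), seqs))
  writeLines(lines, file)
  invisible(file)
}
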