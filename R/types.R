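# Core domain types. Sequences are kept as plain uppercase character strings
# inside light S3 wrappers; alignments are named character vectors of equal
# length, which keeps the distance and site-frequency code close to the math.

#' Legal residue characters
#'
#' The canonical bases, gap, and the IUPAC ambiguity codes accepted on input.
#' Ambiguity codes and `N` are retained in sequences but treated as missing
#' data by all pairwise comparisons (pairwise deletion).
#' @keywords internal
NUC_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a nucleotide sequence record
#'
#' @param id Record identifier (non-empty string).
#' @param residues Residue string over `A,C,G,T,-,N` and IUPAC ambiguity
#'   codes; normalised to uppercase.
#' @param strand `"+"` or `"-"`; minus-strand genomic segments are expected
#'   to be reverse-complemented into viral orientation before alignment
#'   (see [reverse_complement()]).
#' @return An object of class `nuc_seq` with fields `id`, `residues`, `strand`.
#' @export
nuc_seq <- function(id, residues, strand = "+") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) {
    stop("sequence '", id, "': zero-length residue string")
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), NUC_ALPHABET)
  if (length(bad) > 0L) {
    stop("sequence '", id, "': illegal residue character(s): ",
         paste(bad, collapse = ", "))
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(id = id, residues = residues, strand = strand),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s (%s) %d nt\n", x$id, x$strand, nchar(x$residues)))
  invisible(x)
}

#' Reverse-complement a residue string
#'
#' Handles IUPAC ambiguity codes and gaps.
#' @param residues Residue string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(residues) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(residues)))
}

# Coerce nuc_seq / character to a bare residue string
as_residues <- function(x) {
  if (inherits(x, "nuc_seq")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a nuc_seq or a single residue string")
}

#' Construct a multiple alignment
#'
#' @param seqs A list of [nuc_seq()] objects or a named character vector of
#'   residue strings; all members must have equal aligned length.
#' @param label Optional label for the alignment.
#' @return An object of class `alignment`: a named character vector with a
#'   `label` attribute.
#' @export
alignment <- function(seqs, label = "") {
  if (is.list(seqs)) {
    v <- vapply(seqs, as_residues, character(1))
    names(v) <- vapply(seqs, function(s)
      if (inherits(s, "nuc_seq")) s$id else "", character(1))
    seqs <- v
  }
  stopifnot(is.character(seqs))
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment members have unequal lengths: ",
         paste(unique(nchar(seqs)), collapse = ", "))
  structure(seqs, label = label, class = c("alignment", "character"))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s: %d sequences x %d columns\n",
              attr(x, "label"), length(x), nchar(x[[1]])))
  invisible(x)
}

# Character matrix view of an alignment (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Construct an endogenization age interval
#'
#' @param min_age,max_age Bounds in Myr, `0 <= min_age < max_age`.
#' @return An `age_interval` object.
#' @export
age_interval <- function(min_age, max_age) {
  stopifnot(is.numeric(min_age), is.numeric(max_age))
  if (min_age < 0 || min_age >= max_age)
    stop("require 0 <= min_age < max_age; got [", min_age, ", ", max_age, "]")
  structure(list(min_age = min_age, max_age = max_age), class = "age_interval")
}

#' @export
print.age_interval <- function(x, ...) {
  cat(sprintf("[%.4g, %.4g] Myr\n", x$min_age, x$max_age))
  invisible(x)
}

#' Construct a locus presence/absence pattern
#'
#' One row of an ortholog presence/absence matrix: the state of a single EVE
#' locus across sampled host taxa.
#'
#' @param locus_id Locus identifier.
#' @param states Named character vector over taxa with values in
#'   `present`, `absent`, `deleted`, `unclear` (case-insensitive).
#' @return A `locus_pattern` object.
#' @export
locus_pattern <- function(locus_id, states) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  stopifnot(is.character(states), !is.null(names(states)))
  states <- tolower(states)
  ok <- c("present", "absent", "deleted", "unclear")
  bad <- setdiff(unique(states), ok)
  if (length(bad) > 0L)
    stop("locus '", locus_id, "': unknown state token(s): ",
         paste(bad, collapse = ", "))
  if (all(states == "absent"))
    stop("locus '", locus_id, "': no presence observed")
  structure(list(locus_id = locus_id, states = states),
            class = "locus_pattern")
}
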