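# Readers and writers for the external formats: FASTA, dated Newick,
# presence/absence TSV, and deterministic TSV/JSON reports.

#' Read a multi-record FASTA file
#'
#' Residues are normalised to uppercase; gaps (`-`) are preserved. Records
#' are validated against the accepted alphabet (bases, gap, `N`, IUPAC
#' ambiguity codes).
#'
#' @param path Path to a FASTA file.
#' @return A list of [nuc_seq()] records.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("FASTA file '", path, "': duplicate record id(s): ",
         paste(dup, collapse = ", "))
  mapply(function(id, res) nuc_seq(id, res),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequences to FASTA
#'
#' @param seqs List of [nuc_seq()] records or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    v <- vapply(seqs, as_residues, character(1))
    names(v) <- vapply(seqs, function(s)
      if (inherits(s, "nuc_seq")) s$id else "", character(1))
    seqs <- v
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a dated (ultrametric) Newick tree
#'
#' Branch lengths are interpreted as Myr. Node ages are computed from root
#' depths and ultrametricity is verified: every leaf must sit at the root age
#' within a relative tolerance.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return A `dated_tree`: list with `phylo` (an [ape::read.tree()] tree),
#'   `ages` (vector of node ages in Myr indexed by ape node number), and
#'   `root_age`.
#' @export
read_newick_dated <- function(path, tol = 1e-6) {
  text <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                       collapse = "") else path
  text <- trimws(text)
  if (!grepl("\\(", text)) {
    # single-leaf degenerate tree, e.g. "A:0;" (ape cannot parse these)
    lab <- sub("^([^:;]+).*$", "\\1", text)
    phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = 0, tip.label = lab, Nnode = 1L),
                     class = "phylo", order = "cladewise")
    return(dated_tree(phy))
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) stop("Newick input has no branch lengths")
  dated_tree(phy, tol = tol)
}

#' Build a dated tree from an ape phylo object
#'
#' @param phy A rooted `phylo` with branch lengths in Myr.
#' @param tol Relative ultrametricity tolerance.
#' @return A `dated_tree` object.
#' @export
dated_tree <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ntip)])
  if (root_age > 0) {
    disc <- abs(depth[seq_len(ntip)] - root_age) / root_age
    if (any(disc > tol)) {
      worst <- which.max(disc)
      stop(sprintf(
        "tree is not ultrametric: leaf '%s' has depth %.6g vs root age %.6g (rel. discrepancy %.3g)",
        phy$tip.label[worst], depth[worst], root_age, max(disc)))
    }
  }
  ages <- root_age - depth
  ages[seq_len(ntip)] <- 0  # clamp numerically tiny leaf ages
  structure(list(phylo = phy, ages = ages, root_age = root_age),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d taxa, root age %.4g Myr: %s\n",
              length(x$phylo$tip.label), x$root_age,
              paste(x$phylo$tip.label, collapse = ", ")))
  invisible(x)
}

#' Read an ortholog presence/absence matrix
#'
#' TSV with one row per locus and one column per host taxon; the first column
#' holds locus ids and the header row the taxon names. Cells are
#' `present` / `absent` / `deleted` / `unclear` (case-insensitive).
#'
#' @param path Path to the TSV file.
#' @param tree A `dated_tree`; taxa are validated against its leaves.
#' @return A list of [locus_pattern()] objects.
#' @export
read_pattern_matrix <- function(path, tree) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("pattern matrix needs a locus column plus taxa")
  taxa <- colnames(tab)[-1]
  unknown <- setdiff(taxa, tree$phylo$tip.label)
  if (length(unknown) > 0L)
    stop("pattern matrix taxa not in tree: ", paste(unknown, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    states <- as.character(tab[i, -1])
    names(states) <- taxa
    locus_pattern(as.character(tab[i, 1]), states)
  })
}

#' Write a deterministic result report
#'
#' Serialises a result table to TSV and/or JSON with a fixed column order and
#' numbers rendered to 6 significant digits, so identical inputs yield
#' byte-identical files.
#'
#' @param results A data.frame (or object coercible to one).
#' @param path Output path; the dialect is chosen from the extension
#'   (`.json` for JSON, anything else TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  df <- as.data.frame(results, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g",
                                            digits = 6))
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    json <- jsonlite::toJSON(df, dataframe = "rows", na = "null",
                             auto_unbox = TRUE, pretty = TRUE)
    writeLines(json, path)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a structured analysis configuration
#'
#' @param path Path to a YAML configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
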