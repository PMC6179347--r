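# Pairwise nucleotide distances with pairwise deletion, and majority-rule
# consensus construction.
#
# Models: p (uncorrected proportion), JC69, and the Tamura-Nei (1993) closed
# form with optional gamma rate-variation correction. Columns holding a gap,
# N, or any IUPAC ambiguity code in either sequence are excluded before
# counting (pairwise deletion); ambiguity codes are never resolved
# fractionally.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Distance model specification
#'
#' @param model One of `"p"`, `"JC69"`, `"TN93"`.
#' @param gamma_alpha Positive gamma shape for among-site rate variation
#'   (TN93 only), or `NULL` for no gamma correction. The shape is a free
#'   analysis choice; 1.0 is the package default where a correction is
#'   requested.
#' @return A `distance_spec` list (`gap_policy` is always pairwise deletion).
#' @export
distance_spec <- function(model = c("TN93", "JC69", "p"), gamma_alpha = NULL) {
  model <- match.arg(model)
  if (!is.null(gamma_alpha)) {
    stopifnot(is.numeric(gamma_alpha), gamma_alpha > 0)
    if (model != "TN93") stop("gamma correction is only defined for TN93 here")
  }
  structure(list(model = model, gamma_alpha = gamma_alpha,
                 gap_policy = "pairwise-deletion"), class = "distance_spec")
}

#' Sufficient statistics for a sequence pair
#'
#' Counts over the comparable sites of two aligned sequences: the A<->G and
#' C<->T transition proportions, the transversion proportion, and the base
#' frequencies pooled over both sequences. Sites where either residue is not
#' one of A, C, G, T are excluded (pairwise deletion).
#'
#' @param a,b Aligned sequences ([nuc_seq()] or residue strings) of equal
#'   length.
#' @return A `pair_counts` list: `n`, `P1` (A<->G), `P2` (C<->T), `Q`
#'   (transversions), and frequencies `gA`, `gC`, `gG`, `gT`.
#' @export
pair_counts <- function(a, b) {
  ra <- strsplit(as_residues(a), "")[[1]]
  rb <- strsplit(as_residues(b), "")[[1]]
  if (length(ra) != length(rb))
    stop("sequences have unequal aligned lengths: ",
         length(ra), " vs ", length(rb))
  bases <- c("A", "C", "G", "T")
  keep <- ra %in% bases & rb %in% bases
  n <- sum(keep)
  if (n == 0L) stop("incomparable pair: no sites left after pairwise deletion")
  ra <- ra[keep]; rb <- rb[keep]
  diff <- ra != rb
  ts1 <- diff & ra %in% PURINES & rb %in% PURINES        # A<->G
  ts2 <- diff & ra %in% PYRIMIDINES & rb %in% PYRIMIDINES # C<->T
  tv <- diff & !ts1 & !ts2
  freqs <- (table(factor(ra, levels = bases)) +
            table(factor(rb, levels = bases))) / (2 * n)
  structure(list(n = n, P1 = sum(ts1) / n, P2 = sum(ts2) / n, Q = sum(tv) / n,
                 gA = unname(freqs["A"]), gC = unname(freqs["C"]),
                 gG = unname(freqs["G"]), gT = unname(freqs["T"])),
            class = "pair_counts")
}

# -log(w), or its gamma-corrected analogue alpha * (w^(-1/alpha) - 1)
neglog_term <- function(w, gamma_alpha) {
  if (is.null(gamma_alpha)) -log(w) else gamma_alpha * (w^(-1 / gamma_alpha) - 1)
}

tn93_from_counts <- function(pc, gamma_alpha = NULL) {
  gR <- pc$gA + pc$gG
  gY <- pc$gC + pc$gT
  k1 <- 2 * pc$gA * pc$gG / gR
  k2 <- 2 * pc$gC * pc$gT / gY
  k3 <- 2 * (gR * gY - pc$gA * pc$gG * gY / gR - pc$gC * pc$gT * gR / gY)
  w1 <- if (k1 > 0) 1 - pc$P1 / k1 - pc$Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - pc$P2 / k2 - pc$Q / (2 * gY) else 1
  w3 <- 1 - pc$Q / (2 * gR * gY)
  if (min(w1, w2, w3) <= 0)
    stop("saturated pair: TN93 logarithm argument <= 0")
  k1 * neglog_term(w1, gamma_alpha) + k2 * neglog_term(w2, gamma_alpha) +
    k3 * neglog_term(w3, gamma_alpha)
}

#' Pairwise distance between two aligned sequences
#'
#' @inheritParams pair_counts
#' @param spec A [distance_spec()].
#' @return Distance in substitutions/site (>= 0).
#' @export
distance <- function(a, b, spec = distance_spec("TN93")) {
  pc <- pair_counts(a, b)
  p <- pc$P1 + pc$P2 + pc$Q
  switch(spec$model,
    "p" = p,
    "JC69" = {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) stop("saturated pair: JC69 logarithm argument <= 0")
      -0.75 * log(arg)
    },
    "TN93" = tn93_from_counts(pc, spec$gamma_alpha))
}

#' Mean pairwise distance from a query to a set of targets
#'
#' Incomparable pairs (no shared sites, or model saturation) are skipped with
#' a warning; the mean is taken over the remaining pairs.
#'
#' @param query A sequence.
#' @param targets List of sequences (or named character vector).
#' @param spec A [distance_spec()].
#' @return Arithmetic mean distance in substitutions/site.
#' @export
mean_pairwise_distance <- function(query, targets, spec = distance_spec("TN93")) {
  if (is.character(targets)) targets <- as.list(targets)
  stopifnot(length(targets) >= 1L)
  ds <- vapply(targets, function(t) {
    tryCatch(distance(query, t, spec), error = function(e) {
      warning("skipping incomparable pair: ", conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  if (all(is.na(ds))) stop("all pairs incomparable")
  mean(ds, na.rm = TRUE)
}

# IUPAC code covering a base set
IUPAC_BY_SET <- c(A = "A", C = "C", G = "G", T = "T",
                  "AC" = "M", "AG" = "R", "AT" = "W",
                  "CG" = "S", "CT" = "Y", "GT" = "K",
                  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B",
                  "ACGT" = "N")

#' Majority-rule consensus of an alignment
#'
#' Per column the most frequent residue among `A,C,G,T,-` is taken; ties
#' among bases emit the covering IUPAC code, and a gap loses ties to bases.
#' Columns whose strict majority is a gap are dropped, so the consensus
#' length follows the reconstructed (viral-genome) convention rather than
#' the alignment length.
#'
#' @param aln An [alignment()] with at least 2 members.
#' @param id Identifier for the consensus record.
#' @return A [nuc_seq()].
#' @export
majority_consensus <- function(aln, id = paste0(attr(aln, "label"), "_consensus")) {
  stopifnot(length(aln) >= 2L)
  m <- aln_matrix(aln)
  cols <- apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T", "-")]
    if (length(col) == 0L) return(NA_character_)  # all-ambiguous column
    cnt <- table(factor(col, levels = c("A", "C", "G", "T", "-")))
    base_cnt <- cnt[c("A", "C", "G", "T")]
    top <- max(base_cnt)
    if (cnt["-"] > top || top == 0) return(NA_character_)  # gap plurality: drop
    winners <- names(base_cnt)[base_cnt == top]
    IUPAC_BY_SET[[paste(sort(winners), collapse = "")]]
  })
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L) stop("consensus is empty (all columns dropped)")
  nuc_seq(if (nzchar(id)) id else "consensus", paste(cols, collapse = ""))
}
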