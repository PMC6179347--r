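# Endogenization dating from ortholog presence/absence on a dated host tree.
#
# An EVE fixed on a host branch is inherited by every descendant species, so
# the age of the MRCA of the presence taxa bounds the endogenization from
# below, and the age of the first ancestor that also subtends a sampled
# absence lineage bounds it from above.

# --- small tree utilities (ape node numbering) -------------------------------

tip_index <- function(tree, taxa) {
  idx <- match(taxa, tree$phylo$tip.label)
  if (anyNA(idx))
    stop("taxa not in tree: ", paste(taxa[is.na(idx)], collapse = ", "))
  idx
}

node_parent <- function(phy, node) {
  e <- phy$edge
  p <- e[e[, 2] == node, 1]
  if (length(p) == 0L) NA_integer_ else p
}

root_node <- function(phy) length(phy$tip.label) + 1L

# tip numbers descending from `node` (the node itself if it is a tip)
descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

mrca_node <- function(tree, tips) {
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree$phylo, tips)
}

# --- conflict resolution -----------------------------------------------------

#' Reclassify absences nested inside the presence clade as deletions
#'
#' Under a single endogenization event the presence taxa must form the full
#' descendant set of the insertion branch. A taxon scored `absent` inside the
#' MRCA clade of the presence taxa is therefore interpreted as a subsequent
#' locus deletion and reclassified `deleted`; dating then proceeds on the
#' resolved pattern.
#'
#' @param pattern A [locus_pattern()].
#' @param tree A `dated_tree`.
#' @return The resolved pattern, with an attribute `conflicts` listing the
#'   reclassified taxa (possibly empty).
#' @export
resolve_conflicts <- function(pattern, tree) {
  states <- pattern$states
  pres <- names(states)[states %in% c("present", "deleted")]
  conflicts <- character(0)
  if (length(pres) > 0L) {
    mrca <- mrca_node(tree, tip_index(tree, pres))
    clade <- tree$phylo$tip.label[descendant_tips(tree$phylo, mrca)]
    nested <- intersect(clade, names(states)[states == "absent"])
    if (length(nested) > 0L) {
      states[nested] <- "deleted"
      conflicts <- nested
    }
  }
  out <- locus_pattern(pattern$locus_id, states)
  attr(out, "conflicts") <- conflicts
  out
}

# --- dating ------------------------------------------------------------------

date_interval_for <- function(tree, pres_taxa, abs_taxa) {
  phy <- tree$phylo
  mrca <- mrca_node(tree, tip_index(tree, pres_taxa))
  min_age <- tree$ages[mrca]
  abs_tips <- if (length(abs_taxa) > 0L) tip_index(tree, abs_taxa) else integer(0)
  node <- mrca
  bounding <- NA_integer_
  open_ended <- FALSE
  repeat {
    parent <- node_parent(phy, node)
    if (is.na(parent)) { # reached the root without meeting an absence lineage
      bounding <- node
      open_ended <- TRUE
      break
    }
    if (length(abs_tips) > 0L &&
        any(abs_tips %in% descendant_tips(phy, parent))) {
      bounding <- parent
      break
    }
    node <- parent
  }
  max_age <- tree$ages[bounding]
  list(mrca = mrca, bounding = bounding, min_age = unname(min_age),
       max_age = unname(max_age), open_ended = open_ended)
}

#' Date an endogenization event from a presence/absence pattern
#'
#' The lower age bound is the age of the MRCA of all taxa carrying the locus
#' (`present` or `deleted`: a deleted ortholog still witnesses the
#' insertion). The upper bound is the age of the first ancestral node on the
#' path to the root that also subtends a sampled `absent` lineage; if no
#' absence is sampled the interval is open-ended at the root age.
#'
#' `unclear` taxa contribute no evidence to the primary (strict) interval. A
#' second, optimistic interval that treats `unclear` as `present` is reported
#' alongside, so patterns whose unclear cells straddle a dating boundary
#' expose both readings instead of a silent guess.
#'
#' @param pattern A [locus_pattern()].
#' @param tree A `dated_tree` containing all pattern taxa.
#' @return A `dating_result` list: `locus_id`, `interval` (strict
#'   [age_interval()]), `interval_optimistic`, `mrca_node`, `bounding_node`,
#'   `open_ended`, and `conflicts` (taxa reclassified as deletions).
#' @export
date_locus <- function(pattern, tree) {
  resolved <- resolve_conflicts(pattern, tree)
  states <- resolved$states
  pres <- names(states)[states %in% c("present", "deleted")]
  if (length(pres) == 0L)
    stop("locus '", pattern$locus_id,
         "': undatable, no unambiguous presence (all taxa unclear)")
  abs_taxa <- names(states)[states == "absent"]
  strict <- date_interval_for(tree, pres, abs_taxa)

  # optimistic reading: unclear cells counted as presence evidence
  pres_opt <- names(states)[states %in% c("present", "deleted", "unclear")]
  opt <- date_interval_for(tree, pres_opt, abs_taxa)

  mk_interval <- function(b) {
    if (b$max_age > b$min_age) {
      age_interval(b$min_age, b$max_age)
    } else {
      # open-ended at the root with the presence MRCA at the root itself:
      # degenerate interval, informative only through its lower bound
      structure(list(min_age = b$min_age, max_age = b$max_age),
                class = "age_interval")
    }
  }
  structure(list(
    locus_id = pattern$locus_id,
    interval = mk_interval(strict),
    interval_optimistic = mk_interval(opt),
    mrca_node = strict$mrca,
    bounding_node = strict$bounding,
    open_ended = strict$open_ended,
    conflicts = attr(resolved, "conflicts")
  ), class = "dating_result")
}

#' @export
print.dating_result <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("<dating_result> %s: [%.4g, %.4g] Myr%s%s\n", x$locus_id,
              if (is.null(iv)) NA else iv$min_age,
              if (is.null(iv)) NA else iv$max_age,
              if (x$open_ended) " (open-ended at root)" else "",
              if (length(x$conflicts)) paste0("; deletions inferred: ",
                paste(x$conflicts, collapse = ",")) else ""))
  invisible(x)
}

#' Date every locus of a pattern matrix
#'
#' @param patterns List of [locus_pattern()] objects.
#' @param tree A `dated_tree`.
#' @return A data.frame with one row per locus: strict and optimistic bounds,
#'   open-ended flag, and inferred deletions.
#' @export
date_loci <- function(patterns, tree) {
  rows <- lapply(patterns, function(p) {
    d <- date_locus(p, tree)
    data.frame(
      locus_id = d$locus_id,
      min_age_myr = if (is.null(d$interval)) NA_real_ else d$interval$min_age,
      max_age_myr = if (is.null(d$interval)) NA_real_ else d$interval$max_age,
      min_age_optimistic = if (is.null(d$interval_optimistic)) NA_real_
                           else d$interval_optimistic$min_age,
      max_age_optimistic = if (is.null(d$interval_optimistic)) NA_real_
                           else d$interval_optimistic$max_age,
      open_ended = d$open_ended,
      deletions = paste(d$conflicts, collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
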