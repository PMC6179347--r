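# Synthetic endogenization simulator.
#
# Generates data with the statistical structure the inference chain assumes:
# an exogenous viral lineage evolving fast, endogenization events at known
# times, slow neutral host evolution afterwards along a dated host tree
# (producing orthologous copies at speciations), per-gene viral rate
# multipliers creating a known gene rate heterogeneity, and a young EVE group
# for consensus building. Every draw flows from the single config seed.

BASES <- c("A", "C", "G", "T")

#' TN93 substitution model for simulation
#'
#' Rate matrix with distinct A<->G and C<->T transition rate multipliers and
#' arbitrary stationary base frequencies, scaled to one expected substitution
#' per site per unit distance.
#'
#' @param kappa1 A<->G transition/transversion rate multiplier.
#' @param kappa2 C<->T transition/transversion rate multiplier.
#' @param base_freqs Stationary frequencies (A, C, G, T), summing to 1.
#' @return A `tn93_model` list with the scaled generator `Q`.
#' @export
tn93_model <- function(kappa1 = 4, kappa2 = 4,
                       base_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  stopifnot(kappa1 > 0, kappa2 > 0, length(base_freqs) == 4,
            abs(sum(base_freqs) - 1) < 1e-8, all(base_freqs > 0))
  pi <- unname(base_freqs)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    mult <- if ((BASES[i] == "A" && BASES[j] == "G") ||
                (BASES[i] == "G" && BASES[j] == "A")) kappa1
            else if ((BASES[i] == "C" && BASES[j] == "T") ||
                     (BASES[i] == "T" && BASES[j] == "C")) kappa2
            else 1
    Q[i, j] <- mult * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # expected rate at stationarity
  Q <- Q / mu
  structure(list(Q = Q, base_freqs = pi, kappa1 = kappa1, kappa2 = kappa2),
            class = "tn93_model")
}

# P(d) = exp(Q d) via eigendecomposition (TN93 is reversible, eigenvalues real)
transition_probs <- function(model, d) {
  if (d <= 0) return(diag(4))
  e <- eigen(model$Q)
  P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# draw a random sequence (integer-coded) from the stationary frequencies
random_seq_int <- function(n, model) {
  sample.int(4L, n, replace = TRUE, prob = model$base_freqs)
}

int_to_residues <- function(x) paste(BASES[x], collapse = "")
residues_to_int <- function(res) match(strsplit(res, "")[[1]], BASES)

# Evolve an integer-coded sequence for per-site expected distances `d`
# (scalar or one value per site) under the model.
evolve_int <- function(seqint, d, model) {
  if (length(d) == 1L) d <- rep(d, length(seqint))
  out <- seqint
  for (dv in unique(d)) {
    if (dv <= 0) next
    P <- transition_probs(model, dv)
    idx <- which(d == dv)
    for (b in 1:4) {
      ib <- idx[seqint[idx] == b]
      if (length(ib) > 0L)
        out[ib] <- sample.int(4L, length(ib), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

#' Evolve a sequence forward in time
#'
#' Per-site substitutions are drawn under a TN93 generator with expected
#' number `rate * years` per site; optional discrete-gamma among-site rate
#' variation (4 equal-probability categories, category means).
#'
#' @param ancestor A [nuc_seq()] or residue string (A/C/G/T only).
#' @param rate Substitution rate (substitutions/site/year, >= 0).
#' @param years Elapsed time in years (>= 0).
#' @param model A [tn93_model()].
#' @param gamma_shape Positive gamma shape for site-rate variation, or
#'   `NULL` (default) for a strict clock across sites.
#' @return A [nuc_seq()] with the same id suffixed `_t`.
#' @export
evolve_sequence <- function(ancestor, rate, years, model = tn93_model(),
                            gamma_shape = NULL) {
  stopifnot(rate >= 0, years >= 0)
  res <- as_residues(ancestor)
  seqint <- residues_to_int(res)
  if (anyNA(seqint)) stop("ancestor must contain only A, C, G, T")
  d <- rate * years
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0)
    mids <- discrete_gamma_means(gamma_shape, 4L)
    cat_of_site <- sample.int(4L, length(seqint), replace = TRUE)
    d <- d * mids[cat_of_site]
  }
  out <- evolve_int(seqint, d, model)
  id <- if (inherits(ancestor, "nuc_seq")) paste0(ancestor$id, "_t") else "evolved"
  nuc_seq(id, int_to_residues(out))
}

# Mean rates of k equal-probability discrete gamma categories (mean 1)
discrete_gamma_means <- function(shape, k = 4L) {
  cuts <- stats::qgamma(seq(0, 1, length.out = k + 1), shape, shape)
  mids <- numeric(k)
  for (i in seq_len(k)) {
    mids[i] <- k * (stats::pgamma(cuts[i + 1], shape + 1, shape) -
                    stats::pgamma(cuts[i], shape + 1, shape))
  }
  mids
}

#' The dated calibration tree for the Oryza study system
#'
#' Four taxa: two AA-genome species (O. sativa, O. meridionalis) splitting at
#' 2.41 Myr, the BB-genome O. punctata at 6.76 Myr, and the FF-genome
#' O. brachyantha at 15.00 Myr.
#'
#' @return A `dated_tree`.
#' @export
oryza_tree <- function() {
  read_newick_dated(
    "(((sativa:2.41,meridionalis:2.41):4.35,punctata:6.76):8.24,brachyantha:15.00);")
}

#' Default gene-region table for a simulated viral genome
#'
#' A divergent ORFz-like gene (rate multiplier 2) over the first third of
#' the genome and a conserved RT/RH-like gene (multiplier 1) over the
#' middle third, scaled to the genome length.
#'
#' @param genome_length Genome length in bp.
#' @return A data.frame with columns `name`, `start`, `end`, `multiplier`.
#' @export
default_gene_regions <- function(genome_length) {
  third <- genome_length %/% 3
  data.frame(name = c("ORFz", "RT_RH"),
             start = c(1L, third + 1L),
             end = c(third, 2L * third),
             multiplier = c(2, 1),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults mirror the study regime: an 8-kb pararetrovirus-like genome with
#' a divergent gene (`ORFz`-like, rate multiplier 2) and a conserved gene
#' (`RT/RH`-like, multiplier 1), long-term viral rate 5e-8
#' substitutions/site/year, neutral host rate 1e-9, endogenization on the AA
#' stem at 4 Myr, and a young group of 8 copies endogenized 0.01-0.16 Myr
#' ago (for consensus building).
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_length Viral genome length (bp).
#' @param gene_regions data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive viral coordinates), `multiplier` (viral-phase rate
#'   multiplier); regions must be non-overlapping and inside the genome.
#' @param viral_rate Viral-phase substitution rate (substitutions/site/year).
#' @param host_rate Post-insertion neutral host rate (substitutions/site/year),
#'   `0 < host_rate < viral_rate`.
#' @param endog_times_myr Endogenization times of the old loci (Myr).
#' @param tree Dated host tree; insertion branches are picked on the lineage
#'   to `reference_taxon` at each endogenization time.
#' @param reference_taxon Taxon whose genome carries every simulated locus.
#' @param n_young_copies Copies in the young group.
#' @param young_range_myr Endogenization window of the young group (Myr).
#' @param model A [tn93_model()].
#' @param gamma_shape Optional gamma shape for viral-phase site-rate
#'   variation (default off, so closed-form expectations are exact).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 8000L,
                       gene_regions = default_gene_regions(genome_length),
                       viral_rate = 5e-8,
                       host_rate = 1e-9,
                       endog_times_myr = 4,
                       tree = oryza_tree(),
                       reference_taxon = "sativa",
                       n_young_copies = 8L,
                       young_range_myr = c(0.01, 0.16),
                       model = tn93_model(),
                       gamma_shape = NULL) {
  stopifnot(viral_rate > host_rate, host_rate > 0)
  stopifnot(all(endog_times_myr > 0),
            all(endog_times_myr <= tree$root_age))
  stopifnot(reference_taxon %in% tree$phylo$tip.label)
  stopifnot(young_range_myr[1] > 0,
            young_range_myr[2] < min(endog_times_myr))
  gr <- as.data.frame(gene_regions)
  if (nrow(gr) > 0) {
    stopifnot(all(gr$start >= 1), all(gr$end <= genome_length),
              all(gr$end >= gr$start), all(gr$multiplier > 0))
    o <- order(gr$start)
    if (any(gr$start[o][-1] <= gr$end[o][-nrow(gr)]))
      stop("gene regions overlap")
  }
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 gene_regions = gr, viral_rate = viral_rate,
                 host_rate = host_rate, endog_times_myr = endog_times_myr,
                 tree = tree, reference_taxon = reference_taxon,
                 n_young_copies = as.integer(n_young_copies),
                 young_range_myr = young_range_myr, model = model,
                 gamma_shape = gamma_shape),
            class = "sim_config")
}

# per-site viral-phase rate multiplier vector
region_multipliers <- function(config) {
  mult <- rep(1, config$genome_length)
  gr <- config$gene_regions
  for (i in seq_len(nrow(gr))) mult[gr$start[i]:gr$end[i]] <- gr$multiplier[i]
  mult
}

# branch (child node) on the root-to-taxon path spanning `age_myr`
insertion_child_node <- function(tree, taxon, age_myr) {
  phy <- tree$phylo
  node <- tip_index(tree, taxon)
  path <- node
  while (!is.na(p <- node_parent(phy, node))) {
    path <- c(path, p)
    node <- p
  }
  ages <- tree$ages[path]
  # first node on the path at least as young as the insertion
  child <- path[max(which(ages < age_myr))]
  if (tree$ages[child] >= age_myr || is.na(child))
    stop("no branch spans age ", age_myr)
  child
}

# evolve a locus from its insertion point down the host tree; returns a
# named character vector taxon -> residues
evolve_down_host_tree <- function(seqint, tree, child_node, insertion_age,
                                  host_rate, model) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  out <- character(0)
  recurse <- function(node, seq_at, age_at) {
    dur_yr <- (age_at - tree$ages[node]) * 1e6
    s <- evolve_int(seq_at, host_rate * dur_yr, model)
    if (node <= ntip) {
      out[[phy$tip.label[node]]] <<- int_to_residues(s)
    } else {
      for (ch in phy$edge[phy$edge[, 1] == node, 2])
        recurse(ch, s, tree$ages[node])
    }
  }
  recurse(child_node, seqint, insertion_age)
  out
}

#' Simulate a full synthetic endogenization dataset
#'
#' Produces, deterministically from the config seed: (i) one "old" EVE locus
#' per endogenization time, copied into each descendant host lineage and
#' evolved at the host rate (providing ortholog pairs for the
#' host-accumulated distance); (ii) a young EVE group for consensus
#' building; (iii) the presence/absence matrix implied by each insertion
#' node; and (iv) a ground-truth record including the ancestral viral
#' snapshots.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes per-locus FASTA,
#'   `young_group.fasta`, `host_tree.nwk`, `patterns.tsv`, and `truth.json`.
#' @return Invisibly (and visibly when `out_dir` is `NULL`) a list with
#'   `loci` (per-locus taxon sequences, truth, snapshots), `young`
#'   (sequences and endogenization times), `patterns`, `tree`, and `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- config$model
  mult <- region_multipliers(config)
  tree <- config$tree

  # timeline of viral snapshots: old endogenizations (oldest first), then
  # the young-group endogenizations
  young_times <- sort(stats::runif(config$n_young_copies,
                                   config$young_range_myr[1],
                                   config$young_range_myr[2]),
                      decreasing = TRUE)
  old_times <- sort(config$endog_times_myr, decreasing = TRUE)
  timeline <- c(old_times, young_times)

  viral <- random_seq_int(config$genome_length, model)  # virus at oldest time
  snapshots <- vector("list", length(timeline))
  t_prev <- timeline[1]
  for (i in seq_along(timeline)) {
    dt_yr <- (t_prev - timeline[i]) * 1e6
    if (dt_yr > 0) {
      d <- config$viral_rate * mult * dt_yr
      if (!is.null(config$gamma_shape)) {
        mids <- discrete_gamma_means(config$gamma_shape, 4L)
        d <- d * mids[sample.int(4L, length(d), replace = TRUE)]
      }
      viral <- evolve_int(viral, d, model)
    }
    snapshots[[i]] <- viral
    t_prev <- timeline[i]
  }

  loci <- list()
  patterns <- list()
  for (i in seq_along(old_times)) {
    t_i <- old_times[i]
    locus_id <- sprintf("locus_%02d", i)
    child <- insertion_child_node(tree, config$reference_taxon, t_i)
    copies <- evolve_down_host_tree(snapshots[[i]], tree, child, t_i,
                                    config$host_rate, model)
    present <- names(copies)
    states <- stats::setNames(
      ifelse(tree$phylo$tip.label %in% present, "present", "absent"),
      tree$phylo$tip.label)
    patterns[[locus_id]] <- locus_pattern(locus_id, states)
    loci[[locus_id]] <- list(
      locus_id = locus_id, time_myr = t_i, insertion_child_node = child,
      present_taxa = present, copies = copies,
      viral_snapshot = int_to_residues(snapshots[[i]]))
  }

  young_idx <- length(old_times) + seq_along(young_times)
  young_seqs <- character(0)
  for (j in seq_along(young_times)) {
    # branch off the viral lineage at the endogenization time, then neutral
    # host evolution to the present
    s <- evolve_int(snapshots[[young_idx[j]]],
                    config$host_rate * young_times[j] * 1e6, model)
    young_seqs[[sprintf("young_%02d", j)]] <- int_to_residues(s)
  }

  result <- list(
    loci = loci,
    young = list(seqs = young_seqs, times_myr = young_times),
    patterns = patterns,
    tree = tree,
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(loci)) {
      v <- loci[[id]]$copies
      names(v) <- paste0(id, "_", names(v))
      write_fasta(v, file.path(out_dir, paste0(id, ".fasta")))
    }
    write_fasta(young_seqs, file.path(out_dir, "young_group.fasta"))
    ape::write.tree(tree$phylo, file.path(out_dir, "host_tree.nwk"))
    pat_tab <- do.call(rbind, lapply(patterns, function(p)
      data.frame(locus = p$locus_id, t(p$states), check.names = FALSE)))
    utils::write.table(pat_tab, file.path(out_dir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(
      seed = config$seed, viral_rate = config$viral_rate,
      host_rate = config$host_rate,
      gene_regions = config$gene_regions,
      loci = lapply(loci, function(l)
        l[c("locus_id", "time_myr", "present_taxa", "viral_snapshot")]),
      young_times_myr = young_times)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Simulate a neutrally evolving alignment on a coalescent genealogy
#'
#' Draws a Kingman coalescent genealogy ([ape::rcoal()]) for `n_seqs` copies
#' and evolves a random ancestral sequence down it, so the resulting
#' alignment is a sample from the neutral null of the site-frequency-spectrum
#' tests.
#'
#' @param n_seqs Number of sequences.
#' @param n_sites Sequence length.
#' @param subs_per_unit Expected substitutions/site per unit of coalescent
#'   branch length (controls diversity).
#' @param model A [tn93_model()].
#' @return An [alignment()].
#' @export
simulate_neutral_alignment <- function(n_seqs, n_sites,
                                       subs_per_unit = 0.003,
                                       model = tn93_model()) {
  phy <- ape::rcoal(n_seqs)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  seqs <- character(0)
  recurse <- function(node, seq_at) {
    if (node <= ntip) {
      seqs[[phy$tip.label[node]]] <<- int_to_residues(seq_at)
      return(invisible())
    }
    for (k in which(phy$edge[, 1] == node)) {
      ch <- phy$edge[k, 2]
      s <- evolve_int(seq_at, subs_per_unit * phy$edge.length[k], model)
      recurse(ch, s)
    }
  }
  recurse(root, random_seq_int(n_sites, model))
  alignment(seqs, label = "neutral_coalescent")
}
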