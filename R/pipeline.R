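# Orchestration: packaged fixtures, reference constants for the eRTBVL-D
# study system, per-locus rate analysis of a simulated dataset, and the
# full pipeline (simulate -> date -> distances/consensus -> rates -> GRH ->
# decay -> neutrality) driven by one config.

#' The 15 eRTBVL-D segment records
#'
#' Summary records of the endogenous rice tungro bacilliform virus-like
#' group D segments in the Oryza sativa genome: host coordinates (1-based
#' inclusive), strand, coordinates on the reconstructed viral genome,
#' length, and disruptive (nonsense/frameshift) mutation counts. Host
#' coordinates satisfy `end - start + 1 = length` for every record, which is
#' validated on load.
#'
#' @return A data.frame with 15 rows.
#' @export
fixtures_table1 <- function() {
  path <- system.file("extdata", "table1_segments.tsv", package = "paleorate")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 15L)
  bad <- with(tab, host_end - host_start + 1 != length_bp)
  if (any(bad))
    stop("segment record(s) violate length = end - start + 1: ",
         paste(tab$id[bad], collapse = ", "))
  if (any(tab$host_end < tab$host_start)) stop("end < start in segment record")
  tab
}

#' Reference summary values for the eRTBVL-D system
#'
#' The published summary statistics of the study system, packaged so the
#' demo analysis can reproduce the downstream arithmetic: the mean
#' uncorrected distance of the four dated segments to the young-group
#' consensus sequences, their per-segment host-accumulated distances, the
#' divergence-time bounds, the per-gene long-term rate bounds, and published
#' short-term rates of a related pararetrovirus (CaMV) with their
#' measurement timescale.
#'
#' @return A named list.
#' @export
ertbvl_reference <- function() {
  list(
    uncorrected_mean = 0.260,
    accumulated = c(d3 = 0.007, d10 = 0.006, d11 = 0.005, d14 = 0.006),
    time_bounds_myr = c(min = 2.25, max = 6.75),
    node_ages_myr = c(AA = 2.41, BB = 6.76, FF = 15.00),
    gene_rates = list(
      ORFz = c(lower = 4.72e-8, upper = 1.42e-7),
      RT_RH = c(lower = 2.69e-8, upper = 8.07e-8),
      PR = c(lower = 3.99e-8, upper = 1.20e-7)),
    whole_rate_bounds = c(lower = 3.77e-8, upper = 1.13e-7),
    short_term = data.frame(
      label = c("CaMV_ORFs_I-V", "CaMV_ORF_VI"),
      rate = c(1.71e-4, 5.81e-4),
      timescale_years_min = c(50, 50),
      timescale_years_max = c(52, 52),
      stringsAsFactors = FALSE))
}

# closest present relative of the reference taxon (youngest MRCA)
ortholog_partner <- function(tree, reference, present) {
  others <- setdiff(present, reference)
  if (length(others) == 0L) return(NA_character_)
  ages <- vapply(others, function(tx)
    tree$ages[mrca_node(tree, tip_index(tree, c(reference, tx)))], numeric(1))
  others[which.min(ages)]
}

#' Per-locus rate analysis of a simulated dataset
#'
#' Runs the full inference on the output of [simulate_dataset()]: builds the
#' young-group consensus, dates each locus from its presence/absence
#' pattern, computes uncorrected, host-accumulated, and corrected distances
#' (whole locus and per gene region), and converts them to substitution-rate
#' bounds. Divergence-time bounds are the dating bounds minus the young
#' group's endogenization window.
#'
#' @param sim Result of [simulate_dataset()].
#' @param spec A [distance_spec()].
#' @return A data.frame with one row per locus x region.
#' @export
analyze_simulation <- function(sim, spec = distance_spec("TN93")) {
  config <- sim$config
  tree <- sim$tree
  consensus <- majority_consensus(alignment(sim$young$seqs, label = "young"),
                                  id = "young_consensus")
  young_min <- min(sim$young$times_myr)
  young_max <- max(sim$young$times_myr)
  regions <- rbind(
    data.frame(name = "whole", start = 1L, end = config$genome_length,
               stringsAsFactors = FALSE),
    config$gene_regions[, c("name", "start", "end")])
  rows <- list()
  for (id in names(sim$loci)) {
    locus <- sim$loci[[id]]
    dres <- date_locus(sim$patterns[[id]], tree)
    if (dres$interval$max_age <= dres$interval$min_age) next  # undated
    T_min <- (dres$interval$min_age - young_max) * 1e6
    T_max <- (dres$interval$max_age - young_min) * 1e6
    if (T_min <= 0) next
    ref_seq <- locus$copies[[config$reference_taxon]]
    partner <- ortholog_partner(tree, config$reference_taxon,
                                locus$present_taxa)
    for (k in seq_len(nrow(regions))) {
      rg <- regions[k, ]
      sub <- function(s) substr(s, rg$start, rg$end)
      D_u <- distance(sub(ref_seq), sub(consensus$residues), spec)
      D_h <- if (is.na(partner)) 0 else
        accumulated_host_distance(
          distance(sub(ref_seq), sub(locus$copies[[partner]]), spec))
      est <- suppressWarnings(
        rate_estimate(id, rg$name, D_u, D_h, T_min, T_max))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = id, region = rg$name, true_time_myr = locus$time_myr,
        min_age_myr = dres$interval$min_age,
        max_age_myr = dres$interval$max_age,
        D_u = est$D_u, D_h = est$D_h, D_c = est$D_c,
        T_min_years = T_min, T_max_years = T_max,
        r_lower = est$r_lower, r_upper = est$r_upper,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' GRH summary from a per-locus rate table
#'
#' Pairs the divergent and conserved gene regions of each locus from the
#' output of [analyze_simulation()]; the fold is formed from the upper-bound
#' rates (identical time denominators cancel, so any consistent bound gives
#' the same fold).
#'
#' @param rates Output of [analyze_simulation()].
#' @param gene_pair Character vector (divergent, conserved).
#' @return A `grh_result` (see [grh_summary()]).
#' @export
grh_from_rates <- function(rates, gene_pair = c("ORFz", "RT_RH")) {
  div <- rates[rates$region == gene_pair[1], c("locus_id", "r_upper")]
  con <- rates[rates$region == gene_pair[2], c("locus_id", "r_upper")]
  m <- merge(div, con, by = "locus_id", suffixes = c("_div", "_con"))
  if (nrow(m) == 0L) stop("mismatched locus sets for gene pair ",
                          paste(gene_pair, collapse = "/"))
  grh_summary(data.frame(locus_id = m$locus_id,
                         rate_divergent = m$r_upper_div,
                         rate_conserved = m$r_upper_con),
              gene_pair = gene_pair)
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config: seed is required")
  if (is.null(config$out_dir)) stop("config: out_dir is required")
  tb <- config$time_bounds_myr
  if (!is.null(tb)) {
    if (!(length(tb) == 2 && tb[1] > 0 && tb[1] < tb[2]))
      stop("config: time bounds must satisfy 0 < T_min < T_max")
  }
  config
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: simulate -> date -> consensus/distances -> rates
#' -> GRH -> decay regression -> neutrality tests. Each stage logs to stderr
#' and writes a deterministic report under `out_dir`; `summary.json` indexes
#' the reports. All randomness flows from `config$seed`.
#'
#' @param config A named list (or path to a YAML file) with `seed`,
#'   `out_dir`, and optionally `sim` (overrides for [sim_config()]),
#'   `model`/`gamma_alpha` (distance spec), `gene_pair`,
#'   `decay_short_term` (data.frame `rate`, `timescale_years`, `label` of
#'   external short-term points), and `time_bounds_myr` (validated if
#'   given).
#' @return Invisibly, a list with the stage outputs and report paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...)
    message(sprintf("[paleorate:%s] %s", stage, paste0(...)))

  log_stage("simulate", "generating synthetic dataset (seed ", config$seed, ")")
  sim_args <- config$sim %||% list()
  sim_args$seed <- config$seed
  sim <- simulate_dataset(do.call(sim_config, sim_args),
                          out_dir = file.path(out_dir, "sim"))

  log_stage("date", "dating ", length(sim$patterns), " loci")
  dating <- date_loci(sim$patterns, sim$tree)
  write_report(dating, file.path(out_dir, "dating.tsv"))

  log_stage("rates", "distances, correction, rate bounds")
  spec <- distance_spec(config$model %||% "TN93",
                        gamma_alpha = config$gamma_alpha)
  rates <- analyze_simulation(sim, spec)
  write_report(rates, file.path(out_dir, "rates.tsv"))

  log_stage("grh", "gene rate heterogeneity")
  gene_pair <- config$gene_pair %||% c("ORFz", "RT_RH")
  grh <- grh_from_rates(rates, gene_pair)
  grh_df <- data.frame(gene_divergent = gene_pair[1],
                       gene_conserved = gene_pair[2],
                       mean_fold = grh$mean_fold,
                       signed_rank_p = grh$signed_rank_p,
                       n_pairs = length(grh$folds))
  write_report(grh_df, file.path(out_dir, "grh.tsv"))

  log_stage("decay", "log10-log10 rate-decay regression")
  long_points <- data.frame(
    rate = sqrt(rates$r_lower[rates$region == "whole"] *
                  rates$r_upper[rates$region == "whole"]),
    timescale_years = sqrt(rates$T_min_years[rates$region == "whole"] *
                             rates$T_max_years[rates$region == "whole"]),
    label = paste0(rates$locus_id[rates$region == "whole"], "_long"))
  st <- config$decay_short_term
  if (!is.null(st)) long_points <- rbind(long_points, as.data.frame(st))
  decay <- if (nrow(long_points) >= 2 && all(long_points$rate > 0))
    decay_regression(long_points) else NULL
  decay_df <- if (is.null(decay)) {
    data.frame(slope = NA_real_, intercept = NA_real_, n_points = nrow(long_points))
  } else {
    data.frame(slope = decay$slope, intercept = decay$intercept,
               n_points = nrow(decay$points))
  }
  write_report(decay_df, file.path(out_dir, "decay.tsv"))

  log_stage("neutrality", "site-frequency-spectrum and dN/dS tests")
  neut_rows <- lapply(names(sim$loci), function(id) {
    locus <- sim$loci[[id]]
    aln <- alignment(locus$copies, label = id)
    row <- data.frame(locus_id = id, n_seqs = length(locus$copies),
                      D = NA_real_, D_star = NA_real_, F_star = NA_real_,
                      dN = NA_real_, dS = NA_real_, dNdS = NA_real_,
                      fisher_p = NA_real_, stringsAsFactors = FALSE)
    if (length(locus$copies) >= 4L) {
      td <- tajimas_d(aln); fl <- fu_li_star(aln)
      row$D <- td$D; row$D_star <- fl$D_star; row$F_star <- fl$F_star
    }
    if (length(locus$copies) >= 2L) {
      rg <- sim$config$gene_regions
      if (nrow(rg) > 0) {
        g <- rg[1, ]
        len <- g$end - g$start + 1
        end <- g$start + (len - len %% 3) - 1
        a <- substr(locus$copies[[1]], g$start, end)
        b <- substr(locus$copies[[2]], g$start, end)
        ng <- suppressWarnings(nei_gojobori_modified(a, b))
        row$dN <- ng$dN; row$dS <- ng$dS; row$dNdS <- ng$dNdS
        row$fisher_p <- if (ng$counts$Nd + ng$counts$Sd > 0)
          fisher_selection_test(ng$counts)$p else 1.0
      }
    }
    row
  })
  neutrality <- do.call(rbind, neut_rows)
  write_report(neutrality, file.path(out_dir, "neutrality.tsv"))

  summary <- list(
    seed = config$seed,
    reports = list(dating = "dating.tsv", rates = "rates.tsv",
                   grh = "grh.tsv", decay = "decay.tsv",
                   neutrality = "neutrality.tsv"),
    n_loci = length(sim$loci),
    mean_fold = grh$mean_fold,
    decay_slope = decay_df$slope)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "reports written to ", out_dir)
  invisible(list(sim = sim, dating = dating, rates = rates, grh = grh,
                 decay = decay, neutrality = neutrality,
                 summary_path = file.path(out_dir, "summary.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
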