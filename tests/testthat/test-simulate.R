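test_that("sequence evolution respects rate zero and expected divergence", {
  anc <- nuc_seq("anc", strrep("ACGT", 100))
  expect_equal(evolve_sequence(anc, 0, 1e6)$residues, anc$residues)
  expect_equal(evolve_sequence(anc, 1e-8, 0)$residues, anc$residues)

  # expected p-distance after d = rate * years expected substitutions/site,
  # with the multiple-hit correction from the transition matrix itself
  model <- tn93_model()
  d <- 1e-8 * 1e6  # 0.01 expected substitutions/site
  e <- eigen(model$Q)
  P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors))
  exp_p <- 1 - sum(model$base_freqs * diag(P))
  for (seed in 1:3) {
    set.seed(seed)
    anc_long <- nuc_seq("a", paste(sample(c("A", "C", "G", "T"), 1e5,
                                          replace = TRUE,
                                          prob = model$base_freqs),
                                   collapse = ""))
    der <- evolve_sequence(anc_long, 1e-8, 1e6, model)
    p_hat <- distance(anc_long, der, distance_spec("p"))
    expect_equal(p_hat, exp_p, tolerance = 0.002 / exp_p)
  }
})

test_that("substitution composition follows the model's kappa", {
  model <- tn93_model(kappa1 = 6, kappa2 = 6)
  set.seed(51)
  ts <- 0; tv <- 0
  for (i in 1:10) {
    anc <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE,
                        prob = model$base_freqs), collapse = "")
    der <- evolve_sequence(nuc_seq("a", anc), 0.02, 1, model)$residues
    pc <- pair_counts(anc, der)
    ts <- ts + (pc$P1 + pc$P2) * pc$n
    tv <- tv + pc$Q * pc$n
  }
  # expected ratio from the generator itself at small divergence
  d <- 0.02
  e <- eigen(model$Q)
  P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors))
  pi <- model$base_freqs
  is_ts <- matrix(FALSE, 4, 4)
  is_ts[1, 3] <- is_ts[3, 1] <- TRUE  # A<->G
  is_ts[2, 4] <- is_ts[4, 2] <- TRUE  # C<->T
  exp_ts <- sum(pi * P * is_ts)
  exp_tv <- sum(pi * P * (!is_ts) * (1 - diag(4)))
  expect_equal(ts / tv, exp_ts / exp_tv, tolerance = 0.2)
})

test_that("gamma site-rate variation changes the divergence distribution", {
  set.seed(52)
  anc <- nuc_seq("a", paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE),
                            collapse = ""))
  flat <- evolve_sequence(anc, 0.2, 1, gamma_shape = NULL)
  gam <- evolve_sequence(anc, 0.2, 1, gamma_shape = 0.3)
  p_flat <- distance(anc, flat$residues, distance_spec("p"))
  p_gam <- distance(anc, gam$residues, distance_spec("p"))
  # strong rate variation concentrates hits on fast sites: fewer observed
  # differences for the same expected substitution count
  expect_lt(p_gam, p_flat)
})

test_that("simulated datasets are deterministic and internally consistent", {
  cfg <- sim_config(seed = 99, genome_length = 1200)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }

  sim <- simulate_dataset(cfg)
  # endogenization at 4 Myr on the Oryza-like tree: present in the two
  # AA-genome taxa only, dated to the (2.41, 6.76) node interval
  expect_equal(sort(sim$loci$locus_01$present_taxa),
               c("meridionalis", "sativa"))
  d <- date_locus(sim$patterns$locus_01, sim$tree)
  expect_equal(d$interval$min_age, 2.41)
  expect_equal(d$interval$max_age, 6.76)

  # ortholog copies exist for every present taxon and have genome length
  expect_equal(sort(names(sim$loci$locus_01$copies)),
               sort(sim$loci$locus_01$present_taxa))
  expect_true(all(nchar(sim$loci$locus_01$copies) == cfg$genome_length))

  # truth JSON records the configured regime
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$viral_rate, cfg$viral_rate)
  expect_equal(truth$loci$locus_01$time_myr, 4)
})

test_that("per-gene multipliers produce the configured substitution ratio", {
  set.seed(53)
  ratios <- vapply(1:10, function(i) {
    cfg <- sim_config(seed = 8000 + i, genome_length = 3000)
    sim <- simulate_dataset(cfg)
    snap <- sim$loci$locus_01$viral_snapshot
    young <- sim$young$seqs[[1]]
    gr <- cfg$gene_regions
    # multiple-hit-corrected per-region divergence estimates the realized
    # substitution load consistently at these depths
    dd <- function(s, e) distance(substr(snap, s, e), substr(young, s, e),
                                  distance_spec("TN93"))
    dd(gr$start[1], gr$end[1]) / dd(gr$start[2], gr$end[2])
  }, numeric(1))
  expect_equal(mean(ratios), 2.0, tolerance = 0.3 / 2.0)
})

test_that("realized divergence tracks the model expectation across regimes", {
  model <- tn93_model()
  set.seed(54)
  for (case in list(c(rate = 5e-8, yr = 4e6, L = 5000),
                    c(rate = 1e-4, yr = 100, L = 5000),
                    c(rate = 1e-9, yr = 2.41e6, L = 20000))) {
    anc <- nuc_seq("a", paste(sample(c("A", "C", "G", "T"), case[["L"]],
                                     replace = TRUE,
                                     prob = model$base_freqs), collapse = ""))
    der <- evolve_sequence(anc, case[["rate"]], case[["yr"]], model)
    d <- case[["rate"]] * case[["yr"]]
    e <- eigen(model$Q)
    P <- Re(e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors))
    exp_p <- 1 - sum(model$base_freqs * diag(P))
    se <- sqrt(exp_p * (1 - exp_p) / case[["L"]])
    p_hat <- distance(anc, der$residues, distance_spec("p"))
    expect_lt(abs(p_hat - exp_p), 3 * se + 1e-12)
  }
})

test_that("neutral coalescent alignments look like population samples", {
  set.seed(55)
  aln <- simulate_neutral_alignment(6, 2000, subs_per_unit = 0.003)
  expect_length(aln, 6L)
  expect_equal(nchar(aln[[1]]), 2000L)
  st <- sfs_stats(aln)
  expect_gt(st$S, 0)
  expect_lte(st$eta_s, st$eta)
})
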