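test_that("Tajima's D matches independent implementations", {
  aln <- toy_neutral_aln()
  td <- tajimas_d(aln)
  # from-scratch reimplementation of the published formula
  expect_equal(td$D, oracle_tajima_d(unclass(aln)), tolerance = 1e-9)
  # frozen value computed with dendropy's popgenstat on the same alignment
  expect_equal(td$D, 0.1676557950339493, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:10) {
    sim <- simulate_neutral_alignment(6, 300, subs_per_unit = 0.01)
    expect_equal(tajimas_d(sim)$D, oracle_tajima_d(unclass(sim)),
                 tolerance = 1e-9)
  }
})

test_that("Tajima's D handles no-variation and the zero-numerator case", {
  flat <- alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
                    label = "flat")
  td <- tajimas_d(flat)
  expect_true(is.na(td$D))
  expect_equal(td$classification, "no variation")

  # 8 singleton sites + 3 half-split sites makes pi equal S/a1 exactly at
  # n = 4: pi = 8/2 + 3 * (2/3) = 6 and S/a1 = 11/(11/6) = 6
  singleton_col <- c("G", "A", "A", "A")
  split_col <- c("G", "G", "A", "A")
  m <- cbind(matrix(rep(singleton_col, 8), nrow = 4),
             matrix(rep(split_col, 3), nrow = 4))
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- letters[1:4]
  td0 <- tajimas_d(alignment(seqs, label = "balanced"))
  expect_equal(td0$D, 0, tolerance = 1e-12)
})

test_that("Fu & Li's D*/F* match a dual implementation and sign analysis", {
  aln <- toy_neutral_aln()
  fl <- fu_li_star(aln)
  st <- sfs_stats(aln)
  n <- st$n_seqs; a <- st$a1; b <- st$a2
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * st$eta - a * st$eta_s) /
    sqrt(uD * st$eta + vD * st$eta^2)
  expect_equal(fl$D_star, Dstar, tolerance = 1e-9)

  # no singletons with positive S: numerator n/(n-1) * eta > 0, so D* > 0
  split_col <- c("G", "G", "A", "A")
  m <- matrix(rep(split_col, 5), nrow = 4)
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- letters[1:4]
  fl2 <- fu_li_star(alignment(seqs, label = "nosingle"))
  expect_gt(fl2$D_star, 0)
  expect_gt(fl2$F_star, 0)

  flat <- alignment(c(a = "AC", b = "AC", c = "AC", d = "AC"), label = "f")
  expect_equal(fu_li_star(flat)$classification, "no variation")
})

test_that("SFS statistics are invariant under sequence reordering", {
  set.seed(33)
  sim <- simulate_neutral_alignment(6, 500, subs_per_unit = 0.01)
  perm <- sample(seq_along(sim))
  shuffled <- alignment(stats::setNames(unclass(sim)[perm],
                                        paste0("x", seq_along(sim))),
                        label = "perm")
  expect_equal(tajimas_d(sim)$D, tajimas_d(shuffled)$D, tolerance = 1e-12)
  expect_equal(fu_li_star(sim)$D_star, fu_li_star(shuffled)$D_star,
               tolerance = 1e-12)
  expect_equal(fu_li_star(sim)$F_star, fu_li_star(shuffled)$F_star,
               tolerance = 1e-12)
})

test_that("modified Nei-Gojobori counts differences and weighted sites", {
  ng0 <- nei_gojobori_modified("TTTGCG", "TTTGCG")
  expect_equal(ng0$counts$Nd, 0)
  expect_equal(ng0$counts$Sd, 0)
  expect_equal(ng0$dN, 0)
  expect_equal(ng0$dS, 0)

  # single codon TTT (Phe) -> TTA (Leu): nonsynonymous
  ng1 <- nei_gojobori_modified("TTT", "TTA", R = 0.5)
  expect_equal(ng1$counts$Nd, 1)
  expect_equal(ng1$counts$Sd, 0)

  # site-count invariant: N_sites + S_sites = 3 * codons compared, any R
  set.seed(34)
  for (R in c(0.5, 1, 2, 5)) {
    ng <- nei_gojobori_modified("TTTGCGATGCAT", "TTAGCAATGCAC", R = R)
    expect_equal(ng$counts$N_sites + ng$counts$S_sites,
                 3 * ng$counts$codons_compared, tolerance = 1e-9)
  }

  # two-difference codons: pathway averages equal exhaustive enumeration
  pairs <- list(c("TTT", "TAC"), c("ATG", "AGA"), c("GGG", "GTC"),
                c("AAA", "AGG"), c("CCT", "CAG"))
  for (p in pairs) {
    got <- nei_gojobori_modified(p[1], p[2], R = 0.5)
    want <- oracle_codon_path(p[1], p[2])
    expect_equal(got$counts$Sd, want[1], tolerance = 1e-9)
    expect_equal(got$counts$Nd, want[2], tolerance = 1e-9)
  }

  expect_error(nei_gojobori_modified("TTTG", "TTAG"), "divisible")
  expect_warning(nei_gojobori_modified("TTTTAAGCG", "TTTTAAGCG"),
                 "stop codon")
})

test_that("R = 0.5 recovers the classical Nei-Gojobori site counts", {
  # with per-change weights 2R (transition) and 1 (transversion), R = 0.5
  # makes all weights equal: the unweighted NG site counts
  classical_syn_sites <- function(codon) {
    aa <- function(cd) as.character(Biostrings::GENETIC_CODE[[cd]])
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        mut <- ch; mut[pos] <- nb
        cd2 <- paste(mut, collapse = "")
        if (aa(cd2) == aa(codon) && aa(cd2) != "*") s <- s + 1 / 3
      }
    }
    s
  }
  for (cod in c("TTT", "CTG", "ATG", "TGG", "GGG", "AGA")) {
    ng <- nei_gojobori_modified(cod, cod, R = 0.5)
    expect_equal(ng$counts$S_sites, classical_syn_sites(cod),
                 tolerance = 1e-9)
  }
})

test_that("the codon-based Fisher test matches the hypergeometric tail", {
  ng0 <- nei_gojobori_modified("TTTGCG", "TTTGCG")
  f0 <- fisher_selection_test(ng0$counts)
  expect_equal(f0$p, 1.0)
  expect_equal(f0$direction, "none")

  counts <- structure(list(Nd = 0, Sd = 10, N_sites = 300, S_sites = 100,
                           R = 1, codons_compared = 133,
                           stop_codons_skipped = 0),
                      class = "codon_pair_counts")
  f <- fisher_selection_test(counts)
  expect_equal(f$direction, "purifying")
  expect_equal(f$p, oracle_fisher_tail(0, 10, 300, 100, lower = TRUE),
               tolerance = 1e-9)

  # proportional table: the observed value sits at the centre of the
  # hypergeometric distribution, so the one-sided tail holds >= 0.5 mass
  counts2 <- structure(list(Nd = 30, Sd = 10, N_sites = 300, S_sites = 100,
                            R = 1, codons_compared = 133,
                            stop_codons_skipped = 0),
                       class = "codon_pair_counts")
  f2 <- fisher_selection_test(counts2)
  expect_gte(f2$p, 0.5)
  expect_equal(f2$p, oracle_fisher_tail(30, 10, 300, 100, lower = FALSE),
               tolerance = 1e-9)
})
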