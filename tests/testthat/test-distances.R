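test_that("pair counts use pairwise deletion and classify change types", {
  pc <- pair_counts("ACGT", "ACGT")
  expect_equal(pc$n, 4L)
  expect_equal(pc$P1 + pc$P2 + pc$Q, 0)

  pc2 <- pair_counts("AAAA", "GAAA")
  expect_equal(pc2$n, 4L)
  expect_equal(pc2$P1, 0.25)
  expect_equal(pc2$P2, 0)
  expect_equal(pc2$Q, 0)

  expect_equal(pair_counts("AC-T", "ACGT")$n, 3L)
  expect_equal(pair_counts("ACNT", "ACGT")$n, 3L)   # N is missing data
  expect_equal(pair_counts("ACRT", "ACGT")$n, 3L)   # ambiguity is missing
  expect_equal(sum(with(pair_counts("ACGT", "TCGA"),
                        c(gA, gC, gG, gT))), 1)
  expect_error(pair_counts("----", "ACGT"), "incomparable")
  expect_error(pair_counts("ACG", "ACGT"), "unequal")
})

test_that("p and JC69 distances match their closed forms", {
  expect_equal(distance("ACGT", "ACGT", distance_spec("p")), 0)
  expect_equal(distance("ACGT", "ACGT", distance_spec("JC69")), 0)
  expect_equal(distance("ACGT", "ACGT", distance_spec("TN93")), 0)

  s1 <- strrep("A", 94)
  a <- paste0(strrep("C", 6), s1)   # 6 diffs in 100 -> p = 0.06
  b <- paste0(strrep("A", 6), s1)
  expect_equal(distance(a, b, distance_spec("p")), 0.06)
  expect_equal(distance(a, b, distance_spec("JC69")), -0.75 * log(1 - 0.08),
               tolerance = 1e-12)

  # saturation raises a model-naming error
  expect_error(distance(strrep("A", 10), strrep("C", 10),
                        distance_spec("JC69")), "JC69")
})

test_that("TN93 agrees with an independent coding of the published formula", {
  set.seed(4)
  bases <- c("A", "C", "G", "T")
  for (i in 1:20) {
    anc <- paste(sample(bases, 400, replace = TRUE,
                        prob = c(0.35, 0.15, 0.2, 0.3)), collapse = "")
    der <- evolve_sequence(nuc_seq("a", anc), 0.1, 1)$residues
    expect_equal(distance(anc, der, distance_spec("TN93")),
                 oracle_tn93(anc, der), tolerance = 1e-12)
    expect_equal(distance(anc, der, distance_spec("TN93", gamma_alpha = 0.7)),
                 oracle_tn93(anc, der, gamma_alpha = 0.7), tolerance = 1e-12)
  }
})

test_that("TN93 agrees with ape's dist.dna on gap-free pairs", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  for (i in 1:5) {
    anc <- paste(sample(bases, 600, replace = TRUE), collapse = "")
    der <- evolve_sequence(nuc_seq("a", anc), 0.08, 1)$residues
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(anc), "")[[1]],
                               b = strsplit(tolower(der), "")[[1]]))
    expect_equal(distance(anc, der, distance_spec("TN93")),
                 as.numeric(ape::dist.dna(bin, model = "TN93")),
                 tolerance = 1e-9)
    expect_equal(distance(anc, der, distance_spec("TN93", gamma_alpha = 1)),
                 as.numeric(ape::dist.dna(bin, model = "TN93", gamma = 1)),
                 tolerance = 1e-9)
  }
})

test_that("TN93 limits: equal frequencies reduce to the Kimura family and
           large gamma shape recovers the ungamma'd distance", {
  # equal frequencies, P1 = P2: TN93 collapses to the K80 closed form
  a <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  ch <- strsplit(a, "")[[1]]
  # balanced transitions (A<->G and C<->T both ways) keep frequencies equal
  ch[1] <- "G"; ch[3] <- "A"; ch[2] <- "T"; ch[4] <- "C"
  b <- paste(ch, collapse = "")
  pc <- pair_counts(a, b)
  expect_equal(pc$P1, pc$P2)
  expect_equal(c(pc$gA, pc$gC, pc$gG, pc$gT), rep(0.25, 4), tolerance = 1e-9)
  P <- pc$P1 + pc$P2; Q <- pc$Q
  k80 <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(distance(a, b, distance_spec("TN93")), k80, tolerance = 1e-9)

  set.seed(6)
  anc <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  der <- evolve_sequence(nuc_seq("x", anc), 0.05, 1)$residues
  expect_equal(distance(anc, der, distance_spec("TN93", gamma_alpha = 1e6)),
               distance(anc, der, distance_spec("TN93")), tolerance = 1e-6)
})

test_that("distances are symmetric and p-distance is monotone in mismatches", {
  set.seed(7)
  for (spec in list(distance_spec("p"), distance_spec("JC69"),
                    distance_spec("TN93"))) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    b <- evolve_sequence(nuc_seq("x", a), 0.05, 1)$residues
    expect_identical(distance(a, b, spec), distance(b, a, spec))
  }
  a <- strrep("A", 50)
  for (k in 0:10) {
    b1 <- paste0(strrep("C", k), strrep("A", 50 - k))
    b2 <- paste0(strrep("C", k + 1), strrep("A", 49 - k))
    expect_lt(distance(a, b1, distance_spec("p")),
              distance(a, b2, distance_spec("p")))
  }
})

test_that("mean pairwise distance averages comparable targets", {
  q <- "AAAAAAAAAA"
  t1 <- "AAAAAAAAAA"
  expect_equal(mean_pairwise_distance(q, list(t1), distance_spec("p")), 0)
  t2 <- "CAAAAAAAAA"  # p = 0.1
  t3 <- "CCCAAAAAAA"  # p = 0.3
  expect_equal(mean_pairwise_distance(q, list(t2, t3), distance_spec("p")), 0.2)
  set.seed(8)
  targets <- replicate(5, evolve_sequence(nuc_seq("q", strrep("ACGT", 50)),
                                          0.03, 1)$residues)
  brute <- mean(vapply(targets, function(t)
    distance(strrep("ACGT", 50), t, distance_spec("p")), numeric(1)))
  expect_equal(mean_pairwise_distance(strrep("ACGT", 50), as.list(targets),
                                      distance_spec("p")), brute)
  expect_warning(
    mean_pairwise_distance("AA", list("CC", "AA"), distance_spec("JC69")),
    "incomparable")
})

test_that("majority consensus follows plurality, IUPAC ties, and gap rules", {
  aln3 <- alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"), label = "id")
  expect_equal(majority_consensus(aln3)$residues, "ACGT")

  expect_equal(majority_consensus(
    alignment(c(a = "A", b = "A", c = "G"), label = "m"))$residues, "A")
  expect_equal(majority_consensus(
    alignment(c(a = "A", b = "G"), label = "t"))$residues, "R")
  # gap loses ties to bases; gap-plurality columns are dropped
  expect_equal(majority_consensus(
    alignment(c(a = "A-C", b = "--C", c = "A-C"), label = "g"))$residues, "AC")
  expect_equal(majority_consensus(
    alignment(c(a = "AT", b = "A-"), label = "g2"))$residues, "AT")
})
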