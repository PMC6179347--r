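# Independent oracle implementations used to cross-check the package code.
# These are written directly from the published formulas / by exhaustive
# enumeration, deliberately sharing no code with the implementation in R/.

# Tamura-Nei (1993) distance, coded from the published closed form with its
# own site counter.
oracle_tn93 <- function(sa, sb, gamma_alpha = NULL) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  P1 <- 0; P2 <- 0; Q <- 0; n <- 0
  cnt <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (!(x %in% names(cnt)) || !(y %in% names(cnt))) next
    n <- n + 1
    cnt[x] <- cnt[x] + 1; cnt[y] <- cnt[y] + 1
    if (x != y) {
      if ((x == "A" && y == "G") || (x == "G" && y == "A")) P1 <- P1 + 1
      else if ((x == "C" && y == "T") || (x == "T" && y == "C")) P2 <- P2 + 1
      else Q <- Q + 1
    }
  }
  P1 <- P1 / n; P2 <- P2 / n; Q <- Q / n
  g <- cnt / sum(cnt)
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["C"] * g["T"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  f <- if (is.null(gamma_alpha)) function(w) -log(w)
       else function(w) gamma_alpha * (w^(-1 / gamma_alpha) - 1)
  unname(k1 * f(w1) + k2 * f(w2) + k3 * f(w3))
}

# Tajima (1989) D, coded from scratch: explicit pairwise-difference loop and
# direct constant formulas.
oracle_tajima_d <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  k <- k / np
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exact Wilcoxon signed-rank p by explicit enumeration of all sign vectors
# (feasible for n <= 14).
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vs <= V + 1e-9), mean(Vs >= V - 1e-9)))
}

# Average synonymous/nonsynonymous step counts between two codons over all
# orderings of the differing positions (no stop-path exclusion), using
# Biostrings' genetic code as the amino-acid source.
oracle_codon_path <- function(ca, cb) {
  aa <- function(codon) as.character(Biostrings::GENETIC_CODE[[codon]])
  pa <- strsplit(ca, "")[[1]]; pb <- strsplit(cb, "")[[1]]
  pos <- which(pa != pb)
  perms <- if (length(pos) <= 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      do.call(c, lapply(1:3, function(i) {
        rest <- pos[-i]
        list(c(pos[i], rest), c(pos[i], rev(rest)))
      }))
    }
  }
  res <- sapply(perms, function(ord) {
    cur <- pa; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- pb[p]
      if (aa(paste(cur, collapse = "")) == aa(paste(nxt, collapse = "")))
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  })
  rowMeans(res)
}

# One-sided hypergeometric tail by direct summation of binomial coefficients.
oracle_fisher_tail <- function(Nd, Sd, Nsite, Ssite, lower = TRUE) {
  tot <- Nsite + Ssite
  draws <- Nd + Sd
  ks <- 0:draws
  probs <- choose(Nsite, ks) * choose(Ssite, draws - ks) / choose(tot, draws)
  if (lower) sum(probs[ks <= Nd]) else sum(probs[ks >= Nd])
}

# small deterministic toy alignment reused across neutrality tests
toy_neutral_aln <- function() {
  alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
              c = "ACGAACGTAT", d = "ACGAACGCAC"), label = "toy")
}
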