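# Counting-based tests of neutral evolution: Tajima's D, Fu & Li's D*/F*
# (outgroup-free), the modified Nei-Gojobori dN/dS, and the codon-based
# Fisher exact test of selection.
#
# Site-frequency-spectrum statistics use complete deletion: alignment columns
# containing any gap, N, or ambiguity code are excluded before counting, so
# every retained column is scored in every sequence.

# --- site frequency spectrum -------------------------------------------------

#' Site-frequency-spectrum summary statistics
#'
#' Computes, over the fully resolved columns of an alignment, the segregating
#' site count `S`, the mean pairwise difference count `pi`, the total
#' mutation count `eta`, the singleton count `eta_s`, and the harmonic-series
#' constants of Tajima (1989) and Fu & Li (1993) needed by [tajimas_d()] and
#' [fu_li_star()].
#'
#' @param aln An [alignment()] with at least 2 sequences.
#' @return An `sfs_stats` list.
#' @export
sfs_stats <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  L <- ncol(m)
  S <- 0L; eta <- 0L; eta_s <- 0L; pair_diffs <- 0
  npairs <- n * (n - 1) / 2
  if (L > 0L) {
    for (j in seq_len(L)) {
      cnt <- table(m[, j])
      k <- length(cnt)
      if (k > 1L) {
        S <- S + 1L
        eta <- eta + (k - 1L)
        eta_s <- eta_s + sum(cnt == 1L)
        # pairwise differences contributed by this column
        pair_diffs <- pair_diffs + (npairs - sum(cnt * (cnt - 1) / 2))
      }
    }
  }
  pi <- pair_diffs / npairs

  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)

  an1 <- a1 + 1 / n  # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- if (n == 2) 2 else
    cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)

  structure(list(n_seqs = n, n_sites = L, S = S, pi = pi, eta = eta,
                 eta_s = eta_s,
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = e1, e2 = e2, an1 = an1, cn = cn, dn = dn),
            class = "sfs_stats")
}

# Tajima's (1989) beta-distribution significance approximation: D rescaled to
# its attainable range [Dmin, Dmax] is treated as a beta variate with mean 0
# and variance 1 on the D scale. This is the generative method behind the
# published critical-value table.
tajima_beta_p <- function(D, n, a1, e2) {
  dmin <- (2 / n - 1 / a1) / sqrt(e2)
  kmax <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  dmax <- (kmax - 1 / a1) / sqrt(e2)
  rng <- dmax - dmin
  m <- -dmin / rng
  v <- 1 / rng^2
  shape_sum <- m * (1 - m) / v - 1
  if (shape_sum <= 0) return(NA_real_)
  a <- m * shape_sum; b <- (1 - m) * shape_sum
  x <- (D - dmin) / rng
  x <- min(max(x, 0), 1)
  2 * min(stats::pbeta(x, a, b), 1 - stats::pbeta(x, a, b))
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` (Tajima 1989). Significance
#' at the 0.05 level is assessed with Tajima's beta-distribution
#' approximation of the null.
#'
#' @param aln An [alignment()] with at least 4 sequences.
#' @return A list: `D`, `p` (approximate two-sided), `significant`,
#'   `classification` (`"no variation"`, `"neutral"`, or
#'   `"departure from neutrality"`), and the underlying [sfs_stats()].
#' @export
tajimas_d <- function(aln) {
  st <- sfs_stats(aln)
  if (st$n_seqs < 4L) stop("Tajima's D requires at least 4 sequences")
  if (st$S == 0L)
    return(list(D = NA_real_, p = NA_real_, significant = FALSE,
                classification = "no variation", stats = st))
  D <- (st$pi - st$S / st$a1) /
    sqrt(st$e1 * st$S + st$e2 * st$S * (st$S - 1))
  p <- tajima_beta_p(D, st$n_seqs, st$a1, st$e2)
  sig <- !is.na(p) && p < 0.05
  list(D = D, p = p, significant = sig,
       classification = if (sig) "departure from neutrality" else "neutral",
       stats = st)
}

#' Fu and Li's D* and F* (outgroup-free)
#'
#' Computed from the total mutation count `eta` and the singleton count
#' `eta_s` per Fu & Li (1993), with the corrected F* variance constants in
#' common use. Significance at 0.05 uses the conservative two-unit rule
#' (|statistic| > 2), an approximation to the published critical values.
#'
#' @param aln An [alignment()] with at least 4 sequences.
#' @return A list: `D_star`, `F_star`, `significant_D`, `significant_F`,
#'   `classification`, and the underlying [sfs_stats()].
#' @export
fu_li_star <- function(aln) {
  st <- sfs_stats(aln)
  n <- st$n_seqs
  if (n < 4L) stop("Fu & Li's D*/F* require at least 4 sequences")
  if (st$S == 0L)
    return(list(D_star = NA_real_, F_star = NA_real_, significant_D = FALSE,
                significant_F = FALSE, classification = "no variation",
                stats = st))
  a <- st$a1; b <- st$a2; an1 <- st$an1; dn <- st$dn
  eta <- st$eta; eta_s <- st$eta_s

  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  D_star <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uD * eta + vD * eta^2)

  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
  F_star <- (st$pi - ((n - 1) / n) * eta_s) /
    sqrt(uF * eta + vF * eta^2)

  sigD <- abs(D_star) > 2
  sigF <- abs(F_star) > 2
  list(D_star = D_star, F_star = F_star,
       significant_D = sigD, significant_F = sigF,
       classification = if (sigD || sigF) "departure from neutrality"
                        else "neutral",
       stats = st)
}

# --- modified Nei-Gojobori ---------------------------------------------------

GENETIC_CODE_TABLE <- {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

is_transition <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) |
    (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

# Weighted synonymous site count of one codon. Per position, each of the
# three possible changes gets weight 2R (transition) or 1 (transversion);
# the synonymous fraction is the weight-share of changes that preserve the
# amino acid. Changes creating a stop codon count as nonsynonymous, so
# s + n = 3 per codon.
codon_syn_sites <- function(codon, R) {
  ch <- strsplit(codon, "")[[1]]
  aa0 <- GENETIC_CODE_TABLE[[codon]]
  s <- 0
  for (pos in 1:3) {
    wsum <- 0; wsyn <- 0
    for (nb in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      w <- if (is_transition(ch[pos], nb)) 2 * R else 1
      mut <- ch; mut[pos] <- nb
      aa1 <- GENETIC_CODE_TABLE[[paste(mut, collapse = "")]]
      wsum <- wsum + w
      if (aa1 == aa0 && aa1 != "*") wsyn <- wsyn + w
    }
    s <- s + wsyn / wsum
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over
# minimal mutational pathways; pathways through stop codons are excluded
# unless every pathway is excluded.
codon_diffs <- function(ca, cb) {
  pa <- strsplit(ca, "")[[1]]; pb <- strsplit(cb, "")[[1]]
  pos <- which(pa != pb)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) pos[o])
    }
  }
  paths <- lapply(perms, function(order) {
    cur <- pa; sd <- 0; nd <- 0; has_stop <- FALSE
    for (p in order) {
      nxt <- cur; nxt[p] <- pb[p]
      aa_from <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
      aa_to <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
      if (aa_to == "*" && paste(nxt, collapse = "") != cb) has_stop <- TRUE
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, has_stop = has_stop)
  })
  keep <- Filter(function(p) !p$has_stop, paths)
  if (length(keep) == 0L) keep <- paths
  c(sd = mean(vapply(keep, `[[`, numeric(1), "sd")),
    nd = mean(vapply(keep, `[[`, numeric(1), "nd")))
}

#' Modified Nei-Gojobori dN/dS between two in-frame coding sequences
#'
#' Synonymous/nonsynonymous site counts are weighted by the
#' transition/transversion ratio `R` (per-change weights 2R for the
#' transition and 1 for each transversion, so the expected
#' transition:transversion ratio equals `R`; `R = 0.5` recovers the
#' classical Nei-Gojobori counts). Differences are counted by averaging over
#' minimal mutational pathways, and the Jukes-Cantor correction converts
#' `pN`, `pS` to `dN`, `dS`.
#'
#' Codons containing a gap, `N`, or ambiguity code in either sequence are
#' skipped, as are codons that are a stop codon in either observed sequence
#' (flagged in the result).
#'
#' @param a,b Aligned in-frame coding sequences, equal length divisible by 3.
#' @param R Transition/transversion ratio for site weighting; `NULL`
#'   (default) estimates it from the pair's Kimura-style transition and
#'   transversion counts (capped at 20 when no transversions are observed).
#' @return A list with `counts` (a `codon_pair_counts` list: `Nd`, `Sd`,
#'   `N_sites`, `S_sites`, `R`, `codons_compared`, `stop_codons_skipped`)
#'   and `pN`, `pS`, `dN`, `dS`, `dNdS`.
#' @export
nei_gojobori_modified <- function(a, b, R = NULL) {
  ra <- as_residues(a); rb <- as_residues(b)
  if (nchar(ra) != nchar(rb)) stop("coding sequences have unequal lengths")
  if (nchar(ra) %% 3 != 0) stop("length not divisible by 3: ", nchar(ra))
  if (is.null(R)) {
    pc <- pair_counts(ra, rb)
    ts <- (pc$P1 + pc$P2) * pc$n; tv <- pc$Q * pc$n
    R <- if (ts + tv == 0) 1 else if (tv == 0) 20 else min(ts / tv, 20)
  }
  stopifnot(R > 0)
  ca_all <- substring(ra, seq(1, nchar(ra), 3), seq(3, nchar(ra), 3))
  cb_all <- substring(rb, seq(1, nchar(rb), 3), seq(3, nchar(rb), 3))
  ok_chars <- function(cd) all(strsplit(cd, "")[[1]] %in% c("A","C","G","T"))
  Nd <- 0; Sd <- 0; Ns <- 0; Ss <- 0; ncod <- 0L; nstop <- 0L
  for (i in seq_along(ca_all)) {
    ca <- ca_all[i]; cb <- cb_all[i]
    if (!ok_chars(ca) || !ok_chars(cb)) next
    if (GENETIC_CODE_TABLE[[ca]] == "*" || GENETIC_CODE_TABLE[[cb]] == "*") {
      nstop <- nstop + 1L
      next
    }
    ncod <- ncod + 1L
    s_sites <- (codon_syn_sites(ca, R) + codon_syn_sites(cb, R)) / 2
    Ss <- Ss + s_sites
    Ns <- Ns + 3 - s_sites
    d <- codon_diffs(ca, cb)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  if (ncod == 0L) stop("no comparable codons")
  if (nstop > 0L)
    warning(nstop, " codon(s) skipped: stop codon mid-sequence")
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(NA_real_)
    d <- -0.75 * log(arg)
    if (d == 0) 0 else d  # avoid IEEE negative zero in reports
  }
  pN <- if (Ns > 0) Nd / Ns else NA_real_
  pS <- if (Ss > 0) Sd / Ss else NA_real_
  dN <- jc(pN); dS <- jc(pS)
  counts <- structure(list(Nd = Nd, Sd = Sd, N_sites = Ns, S_sites = Ss,
                           R = R, codons_compared = ncod,
                           stop_codons_skipped = nstop),
                      class = "codon_pair_counts")
  list(counts = counts, pN = pN, pS = pS, dN = dN, dS = dS,
       dNdS = if (!is.na(dS) && dS > 0) dN / dS else NA_real_)
}

#' Codon-based Fisher exact test of selection
#'
#' One-sided exact (hypergeometric) test comparing the observed synonymous
#' and nonsynonymous difference counts with their site counts. The tested
#' direction follows the data: positive selection when `pN > pS`, purifying
#' when `pN < pS`. Counts are rounded to the nearest integers for the exact
#' table.
#'
#' @param counts A `codon_pair_counts` object from [nei_gojobori_modified()].
#' @return A list: `p` (one-sided exact), `direction`
#'   (`"positive"`, `"purifying"`, or `"none"`).
#' @export
fisher_selection_test <- function(counts) {
  stopifnot(inherits(counts, "codon_pair_counts"))
  if (counts$N_sites <= 0 || counts$S_sites <= 0)
    stop("site counts must be positive")
  Nd <- round(counts$Nd); Sd <- round(counts$Sd)
  Nsite <- round(counts$N_sites); Ssite <- round(counts$S_sites)
  if (Nd + Sd == 0) return(list(p = 1.0, direction = "none"))
  pN <- Nd / Nsite; pS <- Sd / Ssite
  tab <- matrix(c(Nd, Nsite - Nd, Sd, Ssite - Sd), nrow = 2,
                dimnames = list(c("diff", "no_diff"), c("nonsyn", "syn")))
  direction <- if (pN > pS) "positive" else if (pN < pS) "purifying" else "none"
  alt <- if (pN >= pS) "greater" else "less"
  p <- stats::fisher.test(tab, alternative = alt)$p.value
  list(p = p, direction = direction)
}
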