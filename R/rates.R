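# Host-corrected substitution-rate bounds, gene rate heterogeneity (GRH),
# exact Wilcoxon signed-rank testing, short/long rate ratios, and the
# log10-log10 rate-decay regression.
#
# The rate model: the distance between an ancient EVE and a reconstructed
# (consensus) viral sequence decomposes into virus-virus divergence plus the
# neutral substitutions the EVE accumulated in the host genome since
# endogenization. Subtracting the host-accumulated part (estimated as half
# the distance between an ortholog pair) and dividing by the bounds on the
# divergence time yields bounds on the long-term viral substitution rate.

#' Host-accumulated distance from an ortholog pair distance
#'
#' Orthologous EVE copies in two host species diverged at speciation, so the
#' substitutions one copy accumulated since endogenization are approximated
#' by half the pairwise distance between the orthologs.
#'
#' @param ortholog_pair_distance Distance between two orthologous EVE copies
#'   (substitutions/site, >= 0).
#' @return Half the input.
#' @export
accumulated_host_distance <- function(ortholog_pair_distance) {
  stopifnot(is.numeric(ortholog_pair_distance))
  if (any(ortholog_pair_distance < 0)) stop("distance must be >= 0")
  ortholog_pair_distance / 2
}

#' Host-corrected viral distance
#'
#' `max(D_u - D_h, 0)`: the uncorrected EVE-to-virus distance minus the
#' host-accumulated distance, floored at zero (stochastically possible for
#' young or short segments; the floor is reported with a warning).
#'
#' @param D_u Uncorrected distance (substitutions/site).
#' @param D_h Host-accumulated distance (substitutions/site).
#' @return Corrected distance (substitutions/site).
#' @export
corrected_distance <- function(D_u, D_h) {
  stopifnot(D_u >= 0, D_h >= 0)
  d <- D_u - D_h
  if (d < 0) {
    warning(sprintf(
      "corrected distance floored at 0 (D_u = %.4g < D_h = %.4g)", D_u, D_h))
    d <- 0
  }
  d
}

#' Substitution-rate bounds from a corrected distance
#'
#' @param D_c Corrected distance (substitutions/site, >= 0).
#' @param T_min_years,T_max_years Divergence-time bounds in years,
#'   `0 < T_min < T_max`.
#' @return Named vector `c(r_lower, r_upper)` in substitutions/site/year:
#'   `r_lower = D_c / T_max`, `r_upper = D_c / T_min`.
#' @export
rate_bounds <- function(D_c, T_min_years, T_max_years) {
  stopifnot(D_c >= 0)
  if (!(T_min_years > 0 && T_max_years > T_min_years))
    stop("require 0 < T_min < T_max")
  c(r_lower = D_c / T_max_years, r_upper = D_c / T_min_years)
}

#' Full rate estimate for one locus/region
#'
#' @param locus_id Locus identifier.
#' @param region Region label (`"whole"` or a gene name).
#' @param D_u Uncorrected distance.
#' @param D_h Host-accumulated distance.
#' @param T_min_years,T_max_years Divergence-time bounds in years.
#' @return A `rate_estimate` list with the distances, time bounds, and rate
#'   bounds.
#' @export
rate_estimate <- function(locus_id, region, D_u, D_h,
                          T_min_years, T_max_years) {
  D_c <- corrected_distance(D_u, D_h)
  r <- rate_bounds(D_c, T_min_years, T_max_years)
  structure(list(locus_id = locus_id, region = region,
                 D_u = D_u, D_h = D_h, D_c = D_c,
                 T_min = T_min_years, T_max = T_max_years,
                 r_lower = unname(r["r_lower"]),
                 r_upper = unname(r["r_upper"])),
            class = "rate_estimate")
}

#' GRH fold difference between two rates
#'
#' @param rate_divergent,rate_conserved Substitution rates (> 0) measured
#'   over the same locus and time interval.
#' @return `rate_divergent / rate_conserved`.
#' @export
grh_fold <- function(rate_divergent, rate_conserved) {
  stopifnot(rate_divergent > 0)
  if (any(rate_conserved <= 0)) stop("conserved rate must be > 0")
  rate_divergent / rate_conserved
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped before ranking (Wilcoxon's convention; set
#' `zero_method = "pratt"` to rank zeros and then drop them). Ties receive
#' average ranks. For `n <= 25` nonzero differences the p-value is exact,
#' computed by full enumeration of the 2^n sign assignments of the ranks;
#' beyond that the normal approximation is used.
#'
#' @param differences Numeric vector of paired differences.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @return A list: `p` (two-sided), `V` (positive-rank sum), `n_used`,
#'   `exact` (logical).
#' @export
wilcoxon_signed_rank_exact <- function(differences,
                                       zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(is.numeric(differences), length(differences) >= 1L)
  d <- differences
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    if (length(d) == 0L) return(list(p = 1.0, V = 0, n_used = 0L, exact = TRUE))
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
    if (length(d) == 0L) return(list(p = 1.0, V = 0, n_used = 0L, exact = TRUE))
  }
  n <- length(d)
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of V over all 2^n sign assignments, built by
    # convolution over the (doubled, hence integer) ranks
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))  # counts[s + 1] = #assignments with 2V = s
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    p_low <- sum(counts[seq_len(v2 + 1L)]) / total
    p_high <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_low, p_high))
    list(p = p, V = V, n_used = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (V - mu) / sigma
    list(p = min(1, 2 * stats::pnorm(-abs(z))), V = V, n_used = n,
         exact = FALSE)
  }
}

#' Summarise gene rate heterogeneity over loci
#'
#' @param per_locus_pairs A data.frame (or matrix) with columns
#'   `rate_divergent` and `rate_conserved`, one row per paired comparison
#'   (rates from the same locus and time interval); optional column
#'   `locus_id`.
#' @param gene_pair Character vector of length 2 naming (divergent,
#'   conserved) regions.
#' @return A `grh_result` list: `gene_pair`, `folds`, `mean_fold`, and
#'   `signed_rank_p` (exact two-sided Wilcoxon on the paired rate
#'   differences).
#' @export
grh_summary <- function(per_locus_pairs,
                        gene_pair = c("divergent", "conserved")) {
  df <- as.data.frame(per_locus_pairs)
  stopifnot(nrow(df) >= 1L,
            all(c("rate_divergent", "rate_conserved") %in% colnames(df)))
  folds <- mapply(grh_fold, df$rate_divergent, df$rate_conserved)
  p <- wilcoxon_signed_rank_exact(df$rate_divergent - df$rate_conserved)$p
  structure(list(gene_pair = gene_pair, folds = unname(folds),
                 mean_fold = mean(folds), signed_rank_p = p),
            class = "grh_result")
}

#' @export
print.grh_result <- function(x, ...) {
  cat(sprintf("<grh_result> %s / %s: mean fold %.3g over %d pairs (exact signed-rank p = %.3g)\n",
              x$gene_pair[1], x$gene_pair[2], x$mean_fold, length(x$folds),
              x$signed_rank_p))
  invisible(x)
}

#' Ratio of short- to long-term substitution rates
#'
#' @param short_rate,long_rate Rates in substitutions/site/year (> 0).
#' @return `short_rate / long_rate`.
#' @export
rate_ratio <- function(short_rate, long_rate) {
  stopifnot(short_rate > 0)
  if (any(long_rate <= 0)) stop("long-term rate must be > 0")
  short_rate / long_rate
}

#' Time-dependent rate-decay regression
#'
#' Ordinary least squares of `log10(rate)` on `log10(timescale)`. With
#' exactly two points the fitted line interpolates both.
#'
#' @param points A data.frame with columns `rate` (substitutions/site/year)
#'   and `timescale_years`, all strictly positive, at least 2 rows.
#' @return A `decay_fit` list: `points`, `slope`, `intercept`, and the
#'   underlying `lm` fit.
#' @export
decay_regression <- function(points) {
  df <- as.data.frame(points)
  stopifnot(all(c("rate", "timescale_years") %in% colnames(df)))
  if (nrow(df) < 2L) stop("decay regression needs at least 2 points")
  if (any(df$rate <= 0) || any(df$timescale_years <= 0))
    stop("rates and timescales must be strictly positive")
  fit <- stats::lm(log10(rate) ~ log10(timescale_years), data = df)
  structure(list(points = df,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> log10(rate) = %.3g %+.3g * log10(years)  [%d points]\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}
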