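#' Shannon diversity index
#'
#' H = -sum over taxa with n_i > 0 of (n_i/N) log(n_i/N). Natural log by
#' default (nats); any base via `base`.
#'
#' @param counts non-negative count vector for one sample.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index (>= 0).
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n < 1) stop("all-zero count vector")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' Simpson diversity index (finite-sample estimator)
#'
#' The finite-sample dominance estimator D = sum n_i (n_i - 1) / (N (N - 1)),
#' the convention used by MOTHUR-style diversity tables. The plug-in form
#' sum p_i^2 is available with `finite_sample = FALSE`.
#'
#' @param counts non-negative count vector.
#' @param finite_sample use the finite-sample estimator (default `TRUE`).
#' @return value in `[0, 1]`; high values mean dominance by few taxa.
#' @export
simpson <- function(counts, finite_sample = TRUE) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (finite_sample) {
    if (n < 2) stop("Simpson's finite-sample estimator needs at least 2 reads")
    sum(counts * (counts - 1)) / (n * (n - 1))
  } else {
    if (n < 1) stop("all-zero count vector")
    sum((counts / n)^2)
  }
}

#' Chao1 richness estimator (bias-corrected)
#'
#' Sobs + n1 (n1 - 1) / (2 (n2 + 1)) with n1 singletons and n2 doubletons.
#' With no singletons the correction vanishes and Chao1 = Sobs.
#'
#' @param counts non-negative count vector.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) < 1) stop("all-zero count vector")
  sobs <- sum(counts > 0)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. Taxa are split at `rare_cutoff`
#' (default 10) into rare and abundant; with S_rare rare taxa holding N_rare
#' reads, F1 singletons, and sample coverage C_ace = 1 - F1/N_rare:
#' ACE = S_abund + S_rare/C_ace + (F1/C_ace) * gamma^2, where gamma^2 is the
#' standard squared coefficient of variation of the rare-class frequencies,
#' floored at 0. When C_ace = 0 (every rare taxon is a singleton) the
#' estimator is undefined and the function falls back to [chao1()].
#'
#' @param counts non-negative count vector.
#' @param rare_cutoff rare/abundant split (reads per taxon), default 10.
#' @return estimated richness.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_counts(counts)
  if (sum(counts) < 1) stop("all-zero count vector")
  pos <- counts[counts > 0]
  rare <- pos[pos <= rare_cutoff]
  s_abund <- sum(pos > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1(counts))
  fi <- tabulate(rare, nbins = rare_cutoff)
  i <- seq_len(rare_cutoff)
  gamma2 <- max((s_rare / c_ace) * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Good's coverage
#'
#' 1 - F1/N: the estimated fraction of the community represented by the
#' sample, where F1 is the number of singleton taxa.
#'
#' @param counts non-negative count vector.
#' @return proportion in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n < 1) stop("all-zero count vector")
  1 - sum(counts == 1) / n
}

#' Expected rarefied richness (analytic)
#'
#' Closed-form hypergeometric expectation of observed richness in a
#' subsample of `depth` reads drawn without replacement:
#' E(S_d) = sum_i (1 - choose(N - n_i, d) / choose(N, d)).
#'
#' @param counts non-negative count vector.
#' @param depth subsample size (<= total reads).
#' @return expected number of observed taxa.
#' @export
expected_richness <- function(counts, depth) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (depth < 1 || depth > n) stop("depth must be in [1, total reads]")
  pos <- counts[counts > 0]
  # log-scale binomials for numerical stability
  sum(1 - exp(lchoose(n - pos, depth) - lchoose(n, depth)))
}

#' Rarefaction curve by repeated subsampling
#'
#' Mean observed richness over `reps` subsamples without replacement at each
#' depth. The means converge to the analytic expectation
#' ([expected_richness()]) and are non-decreasing in depth in expectation.
#'
#' @param counts non-negative count vector.
#' @param depths increasing integer depths, all `<=` total reads.
#' @param reps subsamples per depth (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = 1) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (any(depths < 1) || any(depths > n))
    stop("every depth must be in [1, total reads = ", n, "]")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  reads <- rep.int(seq_along(counts), counts)
  res <- vapply(depths, function(d) {
    s <- vapply(seq_len(reps), function(r) {
      length(unique(sample(reads, d, replace = FALSE)))
    }, numeric(1))
    c(mean(s), stats::sd(s))
  }, numeric(2))
  data.frame(depth = as.integer(depths), mean_richness = res[1, ],
             sd_richness = res[2, ])
}

#' Per-sample alpha-diversity table
#'
#' Computes Sobs, Shannon, Simpson, ACE, Chao1 and Good's coverage for every
#' sample of a count table, plus a mean and SD row, mirroring the layout of
#' standard amplicon diversity reports.
#'
#' @param t abundance_table of counts.
#' @param rare_cutoff ACE rare cutoff.
#' @param shannon_base log base for Shannon.
#' @return data.frame, one row per sample plus a `"Mean"` and `"SD"` row.
#' @export
alpha_diversity <- function(t, rare_cutoff = 10, shannon_base = exp(1)) {
  stopifnot(inherits(t, "abundance_table"))
  v <- t$values
  per <- data.frame(
    sample = rownames(v),
    Sobs = apply(v, 1, function(x) sum(x > 0)),
    Shannon = apply(v, 1, shannon, base = shannon_base),
    Simpson = apply(v, 1, simpson),
    ACE = apply(v, 1, ace, rare_cutoff = rare_cutoff),
    Chao1 = apply(v, 1, chao1),
    Coverage = apply(v, 1, goods_coverage),
    stringsAsFactors = FALSE)
  num <- per[, -1]
  rbind(per,
        data.frame(sample = "Mean", as.list(colMeans(num))),
        data.frame(sample = "SD", as.list(apply(num, 2, stats::sd))))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts)) stop("NA in count vector")
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  round(counts)
}
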