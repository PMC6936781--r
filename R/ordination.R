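#' Hellinger transformation
#'
#' Entrywise square root of relative abundances. Euclidean distance between
#' transformed rows is the Hellinger distance between samples (range
#' `[0, sqrt(2)]`; the sqrt(2) normalisation is deliberately not applied,
#' following the dominant convention in community ecology).
#'
#' @param t abundance_table (converted to proportions if needed) or a
#'   non-negative matrix of proportions.
#' @return numeric matrix of square-rooted proportions.
#' @export
hellinger_transform <- function(t) {
  v <- block_values(t, as_proportions = TRUE)
  if (any(v < 0)) stop("negative input to the Hellinger transform")
  sqrt(v)
}

#' Hellinger distance matrix
#'
#' @param t abundance_table or proportion matrix.
#' @return `dist` object with attribute `metric = "hellinger"`.
#' @export
hellinger_distance <- function(t) {
  d <- stats::dist(hellinger_transform(t))
  attr(d, "metric") <- "hellinger"
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in `[0, 1]` for non-negative
#' data.
#'
#' @param t abundance_table or non-negative matrix (counts or proportions).
#' @return `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(t) {
  v <- block_values(t)
  if (any(v < 0)) stop("Bray-Curtis needs non-negative data")
  rs <- rowSums(v)
  if (sum(rs == 0) >= 2)
    stop("at least two all-zero samples: distance undefined")
  n <- nrow(v)
  m <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        sum(abs(v[i, ] - v[j, ])) / sum(v[i, ] + v[j, ])
    }
  }
  d <- stats::as.dist(m)
  attr(d, "metric") <- "bray_curtis"
  d
}

as_dist_checked <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance input must be square")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("negative distances")
  stats::as.dist(m)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of -D^2/2, followed by
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which arise
#' for semi-metric dissimilarities such as Bray-Curtis, are counted and
#' excluded from the variance-fraction denominator; no Lingoes/Cailliez
#' correction is applied unless `correction = "cailliez"`.
#'
#' @param d `dist` object or symmetric matrix.
#' @param n_axes number of axes to return (`< n` samples).
#' @param correction `"none"` (default) or `"cailliez"` (adds the constant
#'   that makes all eigenvalues non-negative).
#' @return object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `variance_fraction` per returned axis,
#'   `n_negative` eigenvalues.
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (n_axes >= n) stop("n_axes must be < number of samples")
  cm <- suppressWarnings(stats::cmdscale(d, k = n_axes, eig = TRUE,
                                         add = correction == "cailliez"))
  eig <- cm$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  n_neg <- sum(eig < -sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(n_axes, ncol(cm$points))
  coords <- cm$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_fraction = eig[seq_len(k)] / sum(pos),
                 n_negative = n_neg,
                 correction = correction),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  cat("variance fractions:",
      paste(sprintf("%s = %.2f%%", colnames(x$coordinates),
                    100 * x$variance_fraction), collapse = ", "), "\n")
  if (x$n_negative > 0)
    cat(x$n_negative, "negative eigenvalue(s) excluded from the denominator\n")
  invisible(x)
}

#' Hierarchical cluster analysis of samples
#'
#' Agglomerative clustering of a distance matrix (UPGMA/average linkage by
#' default). The agglomeration is deterministic; ties are resolved by the
#' lowest-index pair, as in [stats::hclust()]. The dendrogram is also
#' returned as a newick string.
#'
#' @param d `dist` or symmetric matrix.
#' @param linkage `"average"` (default), `"ward"` or `"complete"`.
#' @return object of class `hca_result`: `hclust` (the stats::hclust fit),
#'   `newick`, `linkage`.
#' @export
hca <- function(d, linkage = c("average", "ward", "complete")) {
  linkage <- match.arg(linkage)
  d <- as_dist_checked(d)
  if (attr(d, "Size") < 2) stop("need at least 2 samples to cluster")
  method <- switch(linkage, average = "average", ward = "ward.D2",
                   complete = "complete")
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc,
                 newick = ape::write.tree(ape::as.phylo(hc)),
                 linkage = linkage),
            class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat("hierarchical clustering (", x$linkage, " linkage), ",
      length(x$hclust$labels), " samples\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k groups
#' @param h `hca_result`.
#' @param k number of groups.
#' @return named integer group labels.
#' @export
cut_groups <- function(h, k = 2) {
  stopifnot(inherits(h, "hca_result"))
  stats::cutree(h$hclust, k = k)
}

#' PERMANOVA (Adonis) permutation test on a distance matrix
#'
#' One-way permutational multivariate analysis of variance. With total sum
#' of squares SS_T = (1/n) sum_{i<j} d_ij^2 and within-group
#' SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2, the statistic is
#' F = (SS_B / (g - 1)) / (SS_W / (n - g)) with SS_B = SS_T - SS_W, and
#' R^2 = SS_B / SS_T. The p-value permutes group labels; when the number of
#' distinct relabelings is at most `n_perm` the test switches automatically
#' to exhaustive enumeration (p = fraction of relabelings, including the
#' observed one, with F >= F_obs). Sampled p-values use the add-one
#' convention p = (1 + #(F_perm >= F_obs)) / (1 + n_perm), so p is never 0
#' and always >= 1/(n_perm + 1).
#'
#' @param d `dist` or symmetric matrix.
#' @param groups group label per sample (>= 2 groups, none empty, at least
#'   one group with > 1 sample... all samples in one group is an error).
#' @param n_perm permutations requested (default 999).
#' @param seed integer seed for the sampled case.
#' @return object of class `permanova_result` with `F`, `R2`, `p`,
#'   `n_perm` (permutations actually used), `method`
#'   (`"exhaustive"`/`"sampled"`), `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) stop("one group label per sample required")
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  if (g == n) stop("every sample in its own group: no within-group variation")
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- as.matrix(d)^2
  f_stat <- function(lab) {
    ssw <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    ssb <- sst - ssw
    c(F = (ssb / (g - 1)) / (ssw / (n - g)), R2 = ssb / sst)
  }
  obs <- f_stat(groups)
  counts <- table(groups)
  n_distinct <- round(exp(lfactorial(n) - sum(lfactorial(counts))))
  if (is.finite(n_distinct) && n_distinct <= n_perm) {
    labs <- multiset_permutations(as.integer(groups))
    fs <- vapply(labs, function(l)
      f_stat(factor(l, levels = seq_len(g)))[1], numeric(1))
    p <- mean(fs >= obs[1] - 1e-12)
    method <- "exhaustive"
    n_used <- length(labs)
  } else {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      fp <- f_stat(groups[sample.int(n)])[1]
      if (fp >= obs[1] - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_perm)
    method <- "sampled"
    n_used <- n_perm
  }
  structure(list(F = unname(obs[1]), R2 = unname(obs[2]), p = p,
                 n_perm = n_used, method = method, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%s, %d relabelings)\n",
              x$F, x$R2, x$p, x$method, x$n_perm))
  invisible(x)
}

# all distinct permutations of a label multiset (recursive; guarded by the
# caller which only enumerates when the count is small)
multiset_permutations <- function(labels) {
  res <- list()
  rec <- function(remaining, acc) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      rec(remaining[-i], c(acc, v))
    }
  }
  rec(sort(labels), integer(0))
  res
}
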