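#' Principal component analysis of the flavor block
#'
#' PCA of the samples-by-components flavor matrix after centering and, by
#' default, unit-variance scaling (the flavor block mixes chromatogram
#' areas and amino-acid concentrations, so autoscaling is the standard
#' chemometric choice). R2X per component is the eigenvalue fraction of the
#' total (scaled) variance.
#'
#' @param y flavor_table or numeric matrix, samples in rows.
#' @param scaling `"unit_variance"` (default) or `"center_only"`.
#' @param n_comp number of components (`<= min(n_samples - 1, n_components)`).
#' @return object of class `flavor_pca`: `scores`, `loadings`, `sdev`,
#'   `R2X`, `cum_R2X`, `scaling`, `center`, `scale`.
#' @export
pca_fit <- function(y, scaling = c("unit_variance", "center_only"),
                    n_comp = 2) {
  scaling <- match.arg(scaling)
  v <- block_values(y)
  n <- nrow(v)
  if (n_comp > min(n - 1, ncol(v)))
    stop("n_comp must be <= min(n_samples - 1, n_components)")
  sc <- scale_block(v, scaling)
  s <- svd(sc$x)
  lambda <- s$d^2 / (n - 1)
  r2x <- lambda / sum(lambda)
  k <- n_comp
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k, k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|.| loading element positive
  for (a in seq_len(k)) {
    sgn <- sign(loadings[which.max(abs(loadings[, a])), a])
    loadings[, a] <- loadings[, a] * sgn
    scores[, a] <- scores[, a] * sgn
  }
  dimnames(scores) <- list(rownames(v), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 sdev = sqrt(lambda), R2X = r2x[seq_len(k)],
                 cum_R2X = cumsum(r2x)[seq_len(k)],
                 scaling = scaling, center = sc$center, scale = sc$scale),
            class = "flavor_pca")
}

#' @export
print.flavor_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("R2X:", paste(sprintf("%.3f", x$R2X), collapse = ", "),
      " (cumulative:", sprintf("%.3f", utils::tail(x$cum_R2X, 1)), ")\n")
  invisible(x)
}

scale_block <- function(v, scaling) {
  center <- colMeans(v)
  if (scaling == "unit_variance") {
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column(s) under unit-variance scaling: ",
           paste(colnames(v)[sds == 0], collapse = ", "))
  } else {
    sds <- rep(1, ncol(v))
    names(sds) <- colnames(v)
  }
  list(x = sweep(sweep(v, 2, center), 2, sds, "/"), center = center,
       scale = sds)
}

#' Cross-validated Q2 per PCA component
#'
#' Row-wise K-fold cross-validation with per-fold re-estimation of the
#' eigenvectors. Each held-out element y_ij is predicted without using
#' itself: the rank-a score of the held-out row is estimated by regressing
#' the remaining elements of the row on the training loadings with variable
#' j removed (leave-one-variable-out projection), which avoids the
#' optimistic bias of reconstructing a row from its own full projection.
#' PRESS_a sums these squared element errors and
#' Q2_a = 1 - PRESS_a / SS_(a-1), where SS_(a-1) is the full-data residual
#' sum of squares after a - 1 components (SS_0 = total). A component is
#' flagged significant when Q2_a exceeds `limit`.
#'
#' @param y flavor_table or matrix.
#' @param n_comp components to evaluate.
#' @param n_folds folds (>= 2; capped at n, i.e. leave-one-out).
#' @param seed fold-assignment seed.
#' @param scaling as in [pca_fit()].
#' @param limit significance limit for Q2 (default 0.05; the per-component
#'   limit rule of commercial chemometrics software is proprietary, so a
#'   fixed configurable limit is used).
#' @return data.frame with columns `component`, `Q2`, `limit`,
#'   `significant`.
#' @export
pca_q2 <- function(y, n_comp = 2, n_folds = 7, seed = 1,
                   scaling = c("unit_variance", "center_only"),
                   limit = 0.05) {
  scaling <- match.arg(scaling)
  v <- block_values(y)
  n <- nrow(v)
  if (n_folds < 2) stop("n_folds must be >= 2")
  n_folds <- min(n_folds, n)
  if (n_comp > min(n - 2, ncol(v)))
    stop("n_comp too large for cross-validation")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  press <- numeric(n_comp)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(train) < 2) stop("fold with fewer than 2 training samples")
    sc <- scale_block_cv(v[train, , drop = FALSE], scaling)
    vt <- sweep(sweep(v[test, , drop = FALSE], 2, sc$center), 2, sc$scale,
                "/")
    p_all <- svd(sc$x)$v
    q <- ncol(vt)
    for (a in seq_len(n_comp)) {
      pa <- p_all[, seq_len(a), drop = FALSE]
      for (j in seq_len(q)) {
        pj <- pa[-j, , drop = FALSE]
        # rank-a score from the other variables, then predict variable j
        h <- pa[j, , drop = FALSE] %*%
          solve(crossprod(pj), t(pj))
        pred_j <- vt[, -j, drop = FALSE] %*% t(h)
        press[a] <- press[a] + sum((vt[, j] - pred_j)^2)
      }
    }
  }
  sc_full <- scale_block_cv(v, scaling)
  s <- svd(sc_full$x)
  ss <- numeric(n_comp)  # residual SS after a-1 components on full data
  ss[1] <- sum(sc_full$x^2)
  if (n_comp > 1)
    for (a in 2:n_comp) ss[a] <- ss[a - 1] - s$d[a - 1]^2
  q2 <- 1 - press / ss
  data.frame(component = seq_len(n_comp), Q2 = q2, limit = limit,
             significant = q2 > limit)
}

# like scale_block but tolerates constant columns (zero-variance columns can
# appear inside a CV fold; they carry no information and are left centered)
scale_block_cv <- function(v, scaling) {
  center <- colMeans(v)
  if (scaling == "unit_variance") {
    sds <- apply(v, 2, stats::sd)
    sds[sds == 0] <- 1
  } else sds <- rep(1, ncol(v))
  list(x = sweep(sweep(v, 2, center), 2, sds, "/"), center = center,
       scale = sds)
}

#' Count flavor components per category
#'
#' Tallies the annotation by VF chemical category and reports the VF, AA
#' and grand totals.
#'
#' @param ann annotation data.frame (see [flavor_table()]).
#' @return list with `vf_categories` (named counts over all eight
#'   categories), `vf_total`, `aa_total`, `total`.
#' @export
flavor_category_counts <- function(ann) {
  ann <- validate_annotation(ann)
  vf <- ann[ann$kind == "VF", ]
  counts <- table(factor(vf$category, levels = vf_categories))
  list(vf_categories = stats::setNames(as.integer(counts), names(counts)),
       vf_total = nrow(vf),
       aa_total = sum(ann$kind == "AA"),
       total = nrow(ann))
}

#' Per-sample amino-acid taste-class sums
#'
#' Sums the AA components of a flavor table into the three taste classes
#' (umami = Glu + Asp; sweet = Ala + Gly + Ser + Thr; bitter = Arg + His +
#' Ile + Leu + Met + Trp + Tyr + Val); AAs without a class (e.g. Lys, Phe)
#' are reported in a separate `unclassified` column.
#'
#' @param y flavor_table with annotated AA components.
#' @param strict error (instead of pooling into `unclassified`) when an AA
#'   has no taste class.
#' @return data.frame with per-sample columns `umami`, `sweet`, `bitter`,
#'   `unclassified`.
#' @export
taste_class_sums <- function(y, strict = FALSE) {
  stopifnot(inherits(y, "flavor_table"))
  ann <- y$annotation
  aa <- ann$kind == "AA"
  cls <- ann$taste_class
  if (strict && any(aa & (is.na(cls) | cls == "unclassified")))
    stop("AA component(s) without a taste class: ",
         paste(ann$component_id[aa & (is.na(cls) | cls == "unclassified")],
               collapse = ", "))
  cls[aa & is.na(cls)] <- "unclassified"
  sums <- sapply(aa_classes, function(cl) {
    idx <- which(aa & cls == cl)
    if (!length(idx)) return(rep(0, nrow(y$values)))
    rowSums(y$values[, idx, drop = FALSE])
  })
  out <- data.frame(sample = rownames(y$values), sums,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of flavor components
#'
#' Clusters the flavor components (not the samples) on the correlation
#' distance 1 - r between component profiles across samples.
#'
#' @param y flavor_table or matrix.
#' @param linkage see [hca()].
#' @return `hca_result` over components.
#' @export
flavor_hca <- function(y, linkage = "average") {
  v <- block_values(y)
  r <- suppressWarnings(stats::cor(v))
  if (anyNA(r)) stop("constant flavor component(s): correlation undefined")
  d <- stats::as.dist(1 - r)
  attr(d, "metric") <- "correlation"
  hca(d, linkage = linkage)
}
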