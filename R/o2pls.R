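#' Fit a bidirectional orthogonal PLS (O2PLS) model
#'
#' Decomposes two blocks measured on the same samples — here the microbial
#' community (X, samples x taxa) and the flavor profile (Y, samples x
#' components) — into K joint components shared by both blocks, `nx`
#' X-orthogonal and `ny` Y-orthogonal components (structured variation
#' specific to one block), and residuals:
#' X = T W' + T_orth P_orth' + E, Y = U C' + U_orth P_yorth' + F, with the
#' inner relation U ~ T B_T linking the blocks.
#'
#' The algorithm is the SVD-plus-deflation scheme: after centering/scaling,
#' (1) the joint weights W, C are the top-K singular vectors of X'Y;
#' (2) X-orthogonal components are removed one at a time — with T = X W and
#' E = X - T W', the orthogonal weight is the dominant left singular vector
#' of E'T, its score t_orth = X w_orth and loading
#' p_orth = X' t_orth / (t_orth' t_orth) are deflated from X — and
#' symmetrically for Y; (3) W, C, T, U are recomputed from the deflated
#' blocks; (4) B_T is the full K x K least-squares regression of U on T
#' (near-diagonal with SVD-paired components; reported as a diagnostic, not
#' forced); (5) fit statistics are computed on the centered/scaled blocks.
#' Each weight column's largest-magnitude element is made positive so fits
#' are deterministic.
#'
#' `R2Y` is the fraction of (scaled) Y variance captured by the full model
#' (joint prediction T B_T C' plus the Y-orthogonal part); `R2Y_pred` is
#' the joint prediction alone, which is what out-of-sample prediction can
#' deliver. `R2X` is the analogous X reconstruction (T W' plus the
#' X-orthogonal part). `R2_inner` measures how well T predicts U.
#'
#' @param x abundance_table (used as relative abundances) or numeric matrix.
#' @param y flavor_table or numeric matrix, same samples in the same order.
#' @param K number of joint components (>= 1).
#' @param nx,ny number of X-/Y-orthogonal components (>= 0).
#' @param scaling `"unit_variance"` (default) or `"center_only"`.
#' @return object of class `o2pls` with elements `W`, `C`, `T`, `U`,
#'   `T_orth`, `P_orth`, `W_orth`, `U_orth`, `P_yorth`, `C_orth`, `B_T`,
#'   `R2X`, `R2Y`, `R2Y_pred`, `R2_inner`, `Q2` (NA until cross-validated),
#'   `scaling` (centering/scaling record), `dims`, `call`.
#' @seealso [vip_pred()], [o2pls_cv()], [predict.o2pls()]
#' @export
o2pls <- function(x, y, K = 1, nx = 0, ny = 0,
                  scaling = c("unit_variance", "center_only")) {
  scaling <- match.arg(scaling)
  xv <- block_values(x, as_proportions = TRUE)
  yv <- block_values(y)
  if (nrow(xv) != nrow(yv)) stop("X and Y must have the same samples")
  if (!is.null(rownames(xv)) && !is.null(rownames(yv)) &&
      !identical(rownames(xv), rownames(yv)))
    stop("X and Y sample ids are not aligned")
  n <- nrow(xv)
  if (K < 1) stop("K must be >= 1")
  if (nx < 0 || ny < 0) stop("nx and ny must be >= 0")
  if (K + nx > min(n - 1, ncol(xv)))
    stop("K + nx exceeds the rank limit of X")
  if (K + ny > min(n - 1, ncol(yv)))
    stop("K + ny exceeds the rank limit of Y")
  scx <- scale_block(xv, scaling)
  scy <- scale_block(yv, scaling)
  fit <- o2pls_engine(scx$x, scy$x, K, nx, ny)
  fit$scaling <- list(type = scaling, x_center = scx$center,
                      x_scale = scx$scale, y_center = scy$center,
                      y_scale = scy$scale)
  fit$dims <- c(n = n, p = ncol(xv), q = ncol(yv), K = K, nx = nx, ny = ny)
  fit$taxa <- colnames(xv)
  fit$components <- colnames(yv)
  ka <- paste0("joint", seq_len(K))
  dimnames(fit$W) <- list(fit$taxa, ka)
  dimnames(fit$C) <- list(fit$components, ka)
  dimnames(fit$T) <- list(rownames(xv), ka)
  dimnames(fit$U) <- list(rownames(xv), ka)
  if (nx > 0) {
    oa <- paste0("orth", seq_len(nx))
    dimnames(fit$T_orth) <- list(rownames(xv), oa)
    dimnames(fit$P_orth) <- list(fit$taxa, oa)
    dimnames(fit$W_orth) <- list(fit$taxa, oa)
  }
  if (ny > 0) {
    oa <- paste0("orth", seq_len(ny))
    dimnames(fit$U_orth) <- list(rownames(xv), oa)
    dimnames(fit$P_yorth) <- list(fit$components, oa)
    dimnames(fit$C_orth) <- list(fit$components, oa)
  }
  fit$Q2 <- NA_real_
  fit$y_values <- yv
  fit$call <- match.call()
  class(fit) <- "o2pls"
  fit
}

# core algorithm on already centered/scaled blocks
o2pls_engine <- function(X, Y, K, nx, ny) {
  X0 <- X; Y0 <- Y
  T_orth <- P_orth <- W_orth <- NULL
  for (i in seq_len(nx)) {
    s <- svd(crossprod(X, Y), nu = K, nv = K)
    W <- s$u
    Tt <- X %*% W
    E <- X - tcrossprod(Tt, W)
    wo <- svd(crossprod(E, Tt), nu = 1, nv = 0)$u
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to^2)
    X <- X - tcrossprod(to, po)
    T_orth <- cbind(T_orth, to); P_orth <- cbind(P_orth, po)
    W_orth <- cbind(W_orth, wo)
  }
  U_orth <- P_yorth <- C_orth <- NULL
  for (i in seq_len(ny)) {
    s <- svd(crossprod(Y, X), nu = K, nv = K)
    C <- s$u
    U <- Y %*% C
    Fr <- Y - tcrossprod(U, C)
    co <- svd(crossprod(Fr, U), nu = 1, nv = 0)$u
    uo <- Y %*% co
    pyo <- crossprod(Y, uo) / sum(uo^2)
    Y <- Y - tcrossprod(uo, pyo)
    U_orth <- cbind(U_orth, uo); P_yorth <- cbind(P_yorth, pyo)
    C_orth <- cbind(C_orth, co)
  }
  s <- svd(crossprod(X, Y), nu = K, nv = K)
  W <- s$u; C <- s$v
  # sign convention: largest-|.| element of each weight column positive
  for (a in seq_len(K)) {
    sw <- sign(W[which.max(abs(W[, a])), a])
    sc <- sign(C[which.max(abs(C[, a])), a])
    W[, a] <- W[, a] * sw
    C[, a] <- C[, a] * sc
  }
  Tt <- X %*% W
  U <- Y %*% C
  B_T <- solve(crossprod(Tt), crossprod(Tt, U))
  Yhat_pred <- Tt %*% B_T %*% t(C)
  Yhat_full <- Yhat_pred
  if (ny > 0) Yhat_full <- Yhat_full + tcrossprod(U_orth, P_yorth)
  Xhat <- tcrossprod(Tt, W)
  if (nx > 0) Xhat <- Xhat + tcrossprod(T_orth, P_orth)
  list(W = W, C = C, T = Tt, U = U,
       T_orth = T_orth, P_orth = P_orth, W_orth = W_orth,
       U_orth = U_orth, P_yorth = P_yorth, C_orth = C_orth,
       B_T = B_T,
       R2X = 1 - sum((X0 - Xhat)^2) / sum(X0^2),
       R2Y = 1 - sum((Y0 - Yhat_full)^2) / sum(Y0^2),
       R2Y_pred = 1 - sum((Y0 - Yhat_pred)^2) / sum(Y0^2),
       R2_inner = 1 - sum((U - Tt %*% B_T)^2) / sum(U^2))
}

#' @export
print.o2pls <- function(x, ...) {
  d <- x$dims
  cat(sprintf("O2PLS model: %d samples, %d taxa (X), %d flavor components (Y)\n",
              d["n"], d["p"], d["q"]))
  cat(sprintf("components: K = %d joint, nx = %d X-orthogonal, ny = %d Y-orthogonal\n",
              d["K"], d["nx"], d["ny"]))
  cat(sprintf("R2X = %.3f, R2Y = %.3f (predictive %.3f), inner R2 = %.3f",
              x$R2X, x$R2Y, x$R2Y_pred, x$R2_inner))
  if (!is.na(x$Q2)) cat(sprintf(", Q2 = %.3f", x$Q2))
  cat("\n")
  invisible(x)
}

#' @export
summary.o2pls <- function(object, ...) {
  v <- vip_pred(object)
  structure(list(model = object, vip = v,
                 n_vip_above_1 = sum(v >= 1),
                 b_diag = diag(as.matrix(object$B_T)),
                 b_offdiag_max = {
                   b <- as.matrix(object$B_T)
                   if (nrow(b) > 1) max(abs(b[row(b) != col(b)])) else 0
                 }),
            class = "summary.o2pls")
}

#' @export
print.summary.o2pls <- function(x, ...) {
  print(x$model)
  cat(sprintf("inner regression B_T: diagonal %s, max |off-diagonal| %.3g\n",
              paste(sprintf("%.3f", x$b_diag), collapse = ", "),
              x$b_offdiag_max))
  cat(sprintf("VIP(pred): %d of %d taxa >= 1.0; top taxa: %s\n",
              x$n_vip_above_1, length(x$vip),
              paste(names(sort(x$vip, decreasing = TRUE))[1:min(5, length(x$vip))],
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.o2pls <- function(object, ...) {
  # regression coefficients mapping scaled X to scaled Y through the joint
  # subspace: Y ~ X W B_T C'
  object$W %*% object$B_T %*% t(object$C)
}

#' @export
fitted.o2pls <- function(object, ...) {
  predict(object)
}

#' @export
residuals.o2pls <- function(object, ...) {
  object$y_values - predict(object)
}

#' Predict the flavor block from new microbiome samples
#'
#' Applies the training centering/scaling to `newdata`, removes the
#' estimated X-orthogonal components, projects onto the joint weights,
#' applies the inner regression and Y weights, and undoes the Y scaling.
#' With no `newdata` the training X is used, in which case
#' `1 - ||Y - Yhat||^2 / ||Y_c||^2` on the scaled metric equals `R2Y_pred`.
#'
#' @param object fitted `o2pls` model.
#' @param newdata matrix or abundance_table with the training taxon set
#'   (columns matched by name when available).
#' @param ... unused.
#' @return predicted flavor matrix on the original Y scale.
#' @export
predict.o2pls <- function(object, newdata = NULL, ...) {
  sc <- object$scaling
  if (is.null(newdata)) {
    Xs <- NULL  # reconstruct from stored scores
    Tt <- object$T
  } else {
    xv <- block_values(newdata, as_proportions = TRUE)
    if (!is.null(colnames(xv)) && !is.null(object$taxa)) {
      unknown <- setdiff(colnames(xv), object$taxa)
      if (length(unknown))
        stop("unknown taxa in newdata: ", paste(unknown, collapse = ", "))
      if (!all(object$taxa %in% colnames(xv)))
        stop("newdata is missing training taxa: ",
             paste(setdiff(object$taxa, colnames(xv)), collapse = ", "))
      xv <- xv[, object$taxa, drop = FALSE]
    } else if (ncol(xv) != length(sc$x_center)) {
      stop("newdata must have the training taxon set (",
           length(sc$x_center), " taxa)")
    }
    Xs <- sweep(sweep(xv, 2, sc$x_center), 2, sc$x_scale, "/")
    nx <- object$dims[["nx"]]
    for (i in seq_len(nx)) {
      to <- Xs %*% object$W_orth[, i, drop = FALSE]
      Xs <- Xs - tcrossprod(to, object$P_orth[, i, drop = FALSE])
    }
    Tt <- Xs %*% object$W
  }
  Ys <- Tt %*% object$B_T %*% t(object$C)
  out <- sweep(sweep(Ys, 2, sc$y_scale, "*"), 2, sc$y_center, "+")
  colnames(out) <- object$components
  out
}

#' Score plot of a fitted O2PLS model
#'
#' Plots the first two joint score vectors of X (T) and, optionally, of Y
#' (U) against each other.
#'
#' @param x fitted `o2pls` model.
#' @param block `"x"` (T scores) or `"y"` (U scores).
#' @param ... passed to [graphics::plot()].
#' @export
plot.o2pls <- function(x, block = c("x", "y"), ...) {
  block <- match.arg(block)
  S <- if (block == "x") x$T else x$U
  if (ncol(S) >= 2) {
    graphics::plot(S[, 1], S[, 2], xlab = "joint component 1",
                   ylab = "joint component 2",
                   main = sprintf("O2PLS %s-scores", toupper(block)), ...)
    graphics::text(S[, 1], S[, 2], labels = rownames(S), pos = 3, cex = 0.7)
  } else {
    graphics::plot(seq_len(nrow(S)), S[, 1], xlab = "sample",
                   ylab = "joint component 1",
                   main = sprintf("O2PLS %s-scores", toupper(block)), ...)
  }
  invisible(x)
}

#' Variable importance in projection, predictive components (VIP(pred))
#'
#' The standard PLS VIP restricted to the K predictive (joint) components —
#' orthogonal components are excluded by construction:
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ),
#' where p is the number of taxa and SSY_a is the Y sum of squares
#' explained by joint component a through the inner relation. VIP is not
#' uniquely defined for O2PLS in the public literature; this predictive
#' restriction is the documented interpretation used throughout the
#' package. The normalisation identity sum_j VIP_j^2 = p holds exactly.
#' Values >= 1 conventionally flag influential taxa.
#'
#' @param m fitted `o2pls` model.
#' @return named non-negative vector, one VIP value per taxon.
#' @export
vip_pred <- function(m) {
  if (!inherits(m, "o2pls")) stop("vip_pred needs a fitted o2pls model")
  W <- m$W
  p <- nrow(W)
  K <- ncol(W)
  ssy <- vapply(seq_len(K), function(a) {
    sum((m$T[, a, drop = FALSE] %*% m$B_T[a, , drop = FALSE] %*%
           t(m$C))^2)
  }, numeric(1))
  w2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(p * as.vector(w2 %*% ssy) / sum(ssy))
  names(v) <- m$taxa
  v
}

#' Cross-validate O2PLS component numbers
#'
#' Row-wise K-fold cross-validation over a grid of (K, nx, ny). Each fold
#' is fitted on the training rows with training-derived centering/scaling
#' and predicts the held-out Y through the joint part;
#' Q2 = 1 - PRESS / SS_tot with SS_tot the error of predicting held-out Y
#' by the training column means. Leave-one-out is used when n <= 10
#' (typical fermentation series are short), otherwise `n_folds` (default
#' 7). The selected triple maximises Q2, breaking ties towards the smallest
#' K + nx + ny. Grid cells whose ranks are infeasible for a training fold
#' are marked NA rather than raising an error.
#'
#' @param x,y blocks as in [o2pls()].
#' @param K_range,nx_range,ny_range integer grids.
#' @param n_folds folds when n > 10.
#' @param seed fold-assignment seed.
#' @param scaling as in [o2pls()].
#' @return object of class `o2pls_cv`: `table` (data.frame K, nx, ny, Q2),
#'   `best` (selected row), `model` (refit on all data with `Q2` filled
#'   in), `n_folds`, `seed`.
#' @export
o2pls_cv <- function(x, y, K_range = 1:2, nx_range = 0:1, ny_range = 0:1,
                     n_folds = 7, seed = 1,
                     scaling = c("unit_variance", "center_only")) {
  scaling <- match.arg(scaling)
  xv <- block_values(x, as_proportions = TRUE)
  yv <- block_values(y)
  n <- nrow(xv)
  if (n_folds < 2) stop("n_folds must be >= 2")
  n_folds <- if (n <= 10) n else min(n_folds, n)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  grid <- expand.grid(K = K_range, nx = nx_range, ny = ny_range)
  grid$Q2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    K <- grid$K[i]; nx <- grid$nx[i]; ny <- grid$ny[i]
    n_train_min <- min(table(fold))
    n_tr <- n - n_train_min
    if (K + nx > min(n_tr - 1, ncol(xv)) ||
        K + ny > min(n_tr - 1, ncol(yv)))
      next  # infeasible for some fold: leave NA
    press <- 0; sstot <- 0
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      test <- which(fold == f); train <- which(fold != f)
      fitf <- tryCatch(
        o2pls(xv[train, , drop = FALSE], yv[train, , drop = FALSE],
              K = K, nx = nx, ny = ny, scaling = scaling),
        error = function(e) NULL)
      if (is.null(fitf)) { ok <- FALSE; break }
      pred <- predict(fitf, xv[test, , drop = FALSE])
      # PRESS and SS on the training-scaled metric, so Q2 is comparable
      # with the (scaled) R2Y of the fit
      ysc <- fitf$scaling$y_scale
      press <- press +
        sum(sweep(yv[test, , drop = FALSE] - pred, 2, ysc, "/")^2)
      mu <- colMeans(yv[train, , drop = FALSE])
      sstot <- sstot +
        sum(sweep(sweep(yv[test, , drop = FALSE], 2, mu), 2, ysc, "/")^2)
    }
    if (ok) grid$Q2[i] <- 1 - press / sstot
  }
  cand <- grid[!is.na(grid$Q2), , drop = FALSE]
  if (!nrow(cand)) stop("no feasible (K, nx, ny) cell in the grid")
  cand <- cand[order(-cand$Q2, cand$K + cand$nx + cand$ny,
                     cand$K, cand$nx, cand$ny), , drop = FALSE]
  best <- cand[1, , drop = FALSE]
  model <- o2pls(xv, yv, K = best$K, nx = best$nx, ny = best$ny,
                 scaling = scaling)
  model$Q2 <- best$Q2
  structure(list(table = grid, best = best, model = model,
                 n_folds = n_folds, seed = seed),
            class = "o2pls_cv")
}

#' @export
print.o2pls_cv <- function(x, ...) {
  cat(sprintf("O2PLS cross-validation (%d folds): selected K = %d, nx = %d, ny = %d, Q2 = %.3f\n",
              x$n_folds, x$best$K, x$best$nx, x$best$ny, x$best$Q2))
  invisible(x)
}

#' Principal angles between two column subspaces
#'
#' Utility for assessing loading recovery: the angles (radians) between the
#' subspaces spanned by the columns of `a` and `b`.
#'
#' @param a,b matrices with the same number of rows.
#' @return vector of principal angles, ascending.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}
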