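#' Simulate a paired microbiome/flavor dataset with planted structure
#'
#' Generates an abundance table and a flavor table that share K joint
#' latent components, carry block-specific orthogonal components, and
#' contain a planted set of core taxa whose joint loadings are concentrated
#' on the first joint component together with an "active" set of flavor
#' components spanning both the VF and AA sub-blocks. Downstream, the
#' planted core taxa are exactly the taxa that should pass the
#' three-criterion screen (both flavor classes, VIP >= 1, >= 16 partners).
#'
#' The latent model is
#' X_lat = T W' + T_orth P_orth' + E,  Y = offset + T C' + U_orth P_yorth' + F,
#' with Gaussian noise of sd `noise_sd`, orthonormal loading matrices, and
#' joint scores of decreasing scale (`score_sd`). The score matrices are
#' column-centered and mutually orthogonalised in sample, so the
#' decomposition is exactly identified: at `noise_sd = 0`, [o2pls()] with
#' the true (K, nx, ny) recovers the joint subspaces to machine precision
#' and R2Y = 1. X_lat is mapped to compositions by a componentwise
#' exponential (`softmax_scale` controls the nonlinearity) followed by row
#' normalisation, so the linear structure survives approximately in
#' log-relative space. Core taxa receive first-component loadings that keep
#' their overall loading norm at least 3x the non-core loading scale.
#'
#' @param n_samples samples (default 8, one per fermentation day).
#' @param n_taxa,n_vf,n_aa block widths (defaults 50 taxa, 42 VFs, 16 AAs).
#' @param K,nx,ny joint / X-orthogonal / Y-orthogonal component counts.
#' @param noise_sd residual noise sd on both latent blocks (default 0.1:
#'   low-noise conditions under which the planted component ranks and the
#'   planted core are both recoverable at the study sizes used in tests).
#' @param n_core planted core taxa (default 5).
#' @param n_active_vf,n_active_aa flavor components loaded on the core axis
#'   (defaults 16 VF + 10 AA, so each core taxon can reach the 16-partner
#'   criterion with components of both classes).
#' @param score_sd joint score sds, one per component (default
#'   `2 * 0.5^(0:(K-1))`: a dominant core axis).
#' @param orth_score_sd sd of the orthogonal component scores (default 2):
#'   block-specific structured variation, e.g. platform or batch effects,
#'   is typically on the same scale as the leading joint axis, and must be
#'   non-negligible for the planted (K, nx, ny) to be identifiable.
#' @param softmax_scale latent-to-composition scale (default 0.4).
#' @param y_offset constant added to the flavor block so intensities stay
#'   positive (default 10); values are floored at 0 as a safeguard.
#' @param seed integer seed; the generator is deterministic given the seed
#'   and touches no global random state beyond R's seeded RNG.
#' @return list with `abundance` (proportions [abundance_table()] with
#'   days and a two-stage group label), `flavor` ([flavor_table()] with a
#'   generic VF/AA annotation), and `truth` (class `synthetic_truth`):
#'   latent matrices, loadings, `planted_core` taxon ids, active flavor
#'   ids, the realised core/non-core loading margin, parameters, seed.
#' @export
simulate_dataset <- function(n_samples = 8, n_taxa = 50, n_vf = 42,
                             n_aa = 16, K = 2, nx = 1, ny = 1,
                             noise_sd = 0.1, n_core = 5,
                             n_active_vf = 16, n_active_aa = 10,
                             score_sd = NULL, orth_score_sd = 2,
                             softmax_scale = 0.4, y_offset = 10, seed = 1) {
  n <- n_samples; p <- n_taxa; q <- n_vf + n_aa
  if (is.null(score_sd)) score_sd <- 2 * 0.5^(seq_len(K) - 1)
  if (length(score_sd) != K) stop("score_sd must have one entry per joint component")
  if (K < 1) stop("K must be >= 1")
  if (K + nx + ny >= n)
    stop("infeasible ranks: K + nx + ny must be < n_samples")
  if (K + nx > p || K + ny > q) stop("infeasible ranks for the block widths")
  if (n_core > p) stop("more core taxa than taxa")
  if (n_active_vf > n_vf || n_active_aa > n_aa)
    stop("active flavor set exceeds block width")
  set.seed(seed)
  taxa <- sprintf("genus%02d", seq_len(p))
  comps <- c(sprintf("VF%02d", seq_len(n_vf)), sprintf("AA%02d", seq_len(n_aa)))
  samples <- paste0("F", seq_len(n))

  Tt <- vapply(score_sd, function(s) stats::rnorm(n, 0, s), numeric(n))
  Tt <- center_orth(Tt)
  To <- if (nx > 0)
    center_orth(matrix(stats::rnorm(n * nx, 0, orth_score_sd), n, nx), Tt)
  else matrix(0, n, 0)
  Uo <- if (ny > 0)
    center_orth(matrix(stats::rnorm(n * ny, 0, orth_score_sd), n, ny),
                cbind(Tt, To))
  else matrix(0, n, 0)

  core <- seq_len(n_core)
  W <- matrix(stats::rnorm(p * K), p, K)
  W[core, 1] <- sign(stats::rnorm(n_core)) * stats::rnorm(n_core, 1, 0.1)
  W[-core, 1] <- stats::rnorm(p - n_core, 0, 0.02)
  W <- orthonormalize(W)
  active <- c(seq_len(n_active_vf), n_vf + seq_len(n_active_aa))
  C <- matrix(stats::rnorm(q * K), q, K)
  C[active, 1] <- sign(stats::rnorm(length(active))) *
    stats::rnorm(length(active), 1, 0.1)
  C[-active, 1] <- stats::rnorm(q - length(active), 0, 0.02)
  C <- orthonormalize(C)
  # orthogonal loadings are concentrated away from the planted core taxa and
  # active flavors: block-specific structured variation lives on variables
  # unrelated to the joint axis, which keeps the planted correlation margins
  # intact while making the orthogonal components large enough to identify
  Po <- if (nx > 0) {
    M <- matrix(stats::rnorm(p * nx), p, nx)
    M[core, ] <- stats::rnorm(n_core * nx, 0, 0.02)
    orthonormalize(M)
  } else matrix(0, p, 0)
  Pyo <- if (ny > 0) {
    M <- matrix(stats::rnorm(q * ny), q, ny)
    M[active, ] <- stats::rnorm(length(active) * ny, 0, 0.02)
    orthonormalize(M)
  } else matrix(0, q, 0)

  Xlat <- tcrossprod(Tt, W) + tcrossprod(To, Po) +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  Ylat <- tcrossprod(Tt, C) + tcrossprod(Uo, Pyo) +
    matrix(stats::rnorm(n * q, 0, noise_sd), n, q)
  dimnames(Xlat) <- list(samples, taxa)
  dimnames(Ylat) <- list(samples, comps)

  Xprop <- exp(softmax_scale * Xlat)
  Xprop <- Xprop / rowSums(Xprop)
  Yval <- pmax(Ylat + y_offset, 0)

  day <- seq_len(n)
  group <- ifelse(day <= max(2, round(n / 4)), 1L, 2L)
  abundance <- abundance_table(Xprop, day = day, group = group,
                               proportions = TRUE)
  ann <- data.frame(
    component_id = comps,
    kind = rep(c("VF", "AA"), c(n_vf, n_aa)),
    category = c(rep_len(vf_categories, n_vf), rep(NA_character_, n_aa)),
    taste_class = c(rep(NA_character_, n_vf),
                    rep_len(c("umami", "sweet", "bitter", "unclassified"),
                            n_aa)),
    stringsAsFactors = FALSE)
  flavor <- flavor_table(Yval, annotation = ann)

  norms <- sqrt(rowSums(W^2))
  margin <- min(norms[core]) / stats::median(norms[-core])
  truth <- structure(list(
    T_true = Tt, W_true = W, C_true = C,
    T_orth = To, P_orth = Po, U_orth = Uo, P_yorth = Pyo,
    X_latent = Xlat, Y_latent = Ylat,
    planted_core = taxa[core],
    active_components = comps[active],
    core_margin = margin,
    params = list(n_samples = n, n_taxa = p, n_vf = n_vf, n_aa = n_aa,
                  K = K, nx = nx, ny = ny, noise_sd = noise_sd,
                  n_core = n_core, n_active_vf = n_active_vf,
                  n_active_aa = n_active_aa, score_sd = score_sd,
                  orth_score_sd = orth_score_sd,
                  softmax_scale = softmax_scale, y_offset = y_offset),
    seed = seed), class = "synthetic_truth")
  list(abundance = abundance, flavor = flavor, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic truth: n = %d, %d taxa, %d VF + %d AA, K = %d, nx = %d, ny = %d, noise sd = %g\n",
              p$n_samples, p$n_taxa, p$n_vf, p$n_aa, p$K, p$nx, p$ny,
              p$noise_sd))
  cat("planted core:", paste(x$planted_core, collapse = ", "),
      sprintf("(loading margin %.2fx)\n", x$core_margin))
  invisible(x)
}

# column-center, then project out 'against', used so latent scores are
# exactly orthogonal in sample (identifies the decomposition)
center_orth <- function(M, against = NULL) {
  M <- scale(M, scale = FALSE)
  if (!is.null(against) && ncol(against) > 0)
    M <- M - against %*% solve(crossprod(against), crossprod(against, M))
  unname(M)
}

# QR orthonormalization keeping each intended column direction
orthonormalize <- function(M) {
  qrm <- qr(M)
  Q <- qr.Q(qrm)
  sgn <- sign(diag(qr.R(qrm)))
  sgn[sgn == 0] <- 1
  Q %*% diag(sgn, ncol(M), ncol(M))
}

#' Multinomial read sampling from a proportions table
#'
#' Draws `depth` reads per sample from its taxon proportions, emulating
#' fixed-depth sequencing; row sums equal `depth` exactly.
#'
#' @param proportions abundance_table of proportions.
#' @param depth reads per sample (>= 1).
#' @param seed integer seed.
#' @return abundance_table of counts, same dimensions and metadata.
#' @export
sample_counts <- function(proportions, depth, seed = 1) {
  stopifnot(inherits(proportions, "abundance_table"))
  if (!proportions$proportions)
    stop("sample_counts needs a proportions table")
  if (depth < 1) stop("depth must be >= 1")
  set.seed(seed)
  v <- proportions$values
  counts <- t(apply(v, 1, function(pr)
    as.numeric(stats::rmultinom(1, size = depth, prob = pr))))
  dimnames(counts) <- dimnames(v)
  abundance_table(counts, day = proportions$day, group = proportions$group)
}

#' Exchangeable two-group null dataset
#'
#' Samples are drawn independently from one common compositional
#' distribution and split arbitrarily into two groups of `n_per_group`,
#' so any group effect detected downstream is a false positive. Used for
#' PERMANOVA type-I-error studies.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_taxa taxa (default 30).
#' @param seed integer seed.
#' @return abundance_table of proportions with a `group` label.
#' @export
two_group_null_dataset <- function(n_per_group, n_taxa = 30, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  set.seed(seed)
  n <- 2 * n_per_group
  lat <- matrix(stats::rnorm(n * n_taxa), n, n_taxa)
  v <- exp(lat)
  v <- v / rowSums(v)
  dimnames(v) <- list(paste0("S", seq_len(n)),
                      sprintf("genus%02d", seq_len(n_taxa)))
  abundance_table(v, day = rep(1L, n),
                  group = rep(1:2, each = n_per_group), proportions = TRUE)
}
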