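test_that("Hellinger transform takes square roots of proportions", {
  t <- abundance_table(matrix(c(0.25, 0.25, 0.5), 1, 3), proportions = TRUE)
  expect_equal(unname(hellinger_transform(t)[1, ]),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-6)
  # identical rows: distance 0; disjoint supports: sqrt(2)
  m <- abundance_table(matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE),
                       proportions = TRUE)
  d <- as.matrix(hellinger_distance(m))
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], sqrt(2))
})

test_that("Bray-Curtis matches hand values and stays within [0, 1]", {
  m <- abundance_table(matrix(c(2, 0, 2, 0, 2, 2), 2, 3, byrow = TRUE))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d[1, 2], 0.5)  # 4/8
  expect_equal(d[1, 1], 0)
  t <- random_abundance(seed = 3)
  dv <- as.vector(bray_curtis(t))
  expect_true(all(dv >= 0 & dv <= 1))
  # cross-check against vegan's implementation
  skip_if_not_installed("vegan")
  expect_equal(as.vector(bray_curtis(t)),
               as.vector(vegan::vegdist(t$values, method = "bray")),
               tolerance = 1e-12)
})

test_that("PCoA recovers planar configurations and reports variance", {
  set.seed(1)
  pts <- cbind(rnorm(8), rnorm(8))
  d <- dist(pts)
  p <- pcoa(d, n_axes = 2)
  # Procrustes-style check: distances between recovered coordinates match
  expect_equal(as.vector(dist(p$coordinates)), as.vector(d),
               tolerance = 1e-8)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-8)
  # collinear points: one axis carries everything
  d1 <- dist(matrix(c(0, 1, 3), 3, 1))
  p1 <- pcoa(d1, n_axes = 1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(pcoa(d1, n_axes = 3), "n_axes")
  # PCoA of Euclidean distances == PCA of centered coordinates
  centered <- scale(pts, scale = FALSE)
  lam_pca <- svd(centered)$d^2
  p2 <- pcoa(dist(pts), n_axes = 2)
  expect_equal(p2$eigenvalues[1:2], lam_pca[1:2], tolerance = 1e-9)
})

test_that("negative PCoA eigenvalues are reported, not swept up", {
  t <- random_abundance(n = 12, p = 8, seed = 1)
  p <- pcoa(bray_curtis(t), n_axes = 2)
  expect_gte(p$n_negative, 1)  # Bray-Curtis is semi-metric
  expect_true(all(p$variance_fraction >= 0 & p$variance_fraction <= 1))
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)
})

test_that("HCA reproduces ultrametrics and is invariant to sample order", {
  # constructed ultrametric on 4 leaves: ((a,b),(c,d)) heights 1, 1, 2
  u <- matrix(c(0, 1, 2, 2,
                1, 0, 2, 2,
                2, 2, 0, 1,
                2, 2, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h <- hca(u, linkage = "average")
  expect_equal(sort(h$hclust$height), c(1, 1, 2))
  expect_equal(unname(cut_groups(h, 2)), c(1, 1, 2, 2))
  # permuting samples leaves the k=2 partition intact
  perm <- c(3, 1, 4, 2)
  h2 <- hca(u[perm, perm])
  g1 <- cut_groups(h, 2)
  g2 <- cut_groups(h2, 2)[names(g1)]
  expect_true(all((g1 == g1[1]) == (g2 == g2[1])))
  # two well-separated clouds are recovered at k=2
  set.seed(4)
  pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 10), 5))
  hc <- hca(dist(pts))
  expect_equal(unname(cut_groups(hc, 2)), rep(1:2, each = 5))
  expect_match(hc$newick, "^\\(.*\\);$")
})

test_that("PERMANOVA agrees with an exhaustive brute-force oracle", {
  pts <- matrix(c(0, 0, 10, 10), 4, 1)
  d <- dist(pts)
  groups <- c(1, 1, 2, 2)
  res <- permanova(d, groups, n_perm = 999, seed = 1)
  expect_equal(res$method, "exhaustive")
  # brute force over all 4! relabelings, computed from first principles
  d2 <- as.matrix(d)^2
  f_of <- function(lab) {
    n <- 4; g <- 2
    sst <- sum(d2) / (2 * n)
    ssw <- sum(sapply(unique(lab), function(lv) {
      idx <- which(lab == lv)
      sum(d2[idx, idx]) / (2 * length(idx))
    }))
    ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  }
  perms <- rbind(t(sapply(combinat_perms(4), identity)))
  fs <- apply(perms, 1, function(pm) f_of(groups[pm]))
  expect_equal(res$p, mean(fs >= f_of(groups) - 1e-12))
  expect_equal(res$F, f_of(groups))
  expect_gte(res$p, 1 / (res$n_perm + 1))
})

test_that("PERMANOVA matches vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  t <- random_abundance(n = 10, p = 15, seed = 5)
  groups <- rep(1:2, each = 5)
  d <- bray_curtis(t)
  mine <- permanova(d, groups, n_perm = 999, seed = 1)
  ref <- vegan::adonis2(d ~ factor(groups), permutations = 999)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values respect the permutation bound and contracts", {
  t <- random_abundance(n = 6, p = 8, seed = 2)
  d <- bray_curtis(t)
  res <- permanova(d, rep(1:2, 3), n_perm = 19, seed = 3)
  expect_gte(res$p, 1 / 20)
  expect_lte(res$p, 1)
  expect_error(permanova(d, rep(1, 6)), "2 groups")
  # F invariant to a consistent permutation of samples and labels
  groups <- c(1, 1, 1, 2, 2, 2)
  perm <- c(4, 2, 6, 1, 3, 5)
  dm <- as.matrix(d)
  r1 <- permanova(d, groups, n_perm = 19, seed = 1)
  r2 <- permanova(dm[perm, perm], groups[perm], n_perm = 19, seed = 1)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  # a strong planted shift reaches the minimum achievable p
  shifted <- t$values
  shifted[4:6, ] <- shifted[4:6, ] + 100
  rs <- permanova(bray_curtis(abundance_table(shifted)), groups,
                  n_perm = 999, seed = 1)
  # exhaustive case with two equal groups: only the observed labeling and
  # its mirror attain F_obs, so the smallest achievable p is 2/n_distinct
  expect_equal(rs$method, "exhaustive")
  expect_equal(rs$p, 2 / rs$n_perm)
})
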