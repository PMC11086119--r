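test_that("correlation matrix matches the brute-force covariance formula", {
  tab <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 6))
  cm <- correlation_matrix(tab, "x", "y")
  # independent arithmetic oracle
  mx <- mean(tab$x); my <- mean(tab$y)
  r_oracle <- sum((tab$x - mx) * (tab$y - my)) /
    sqrt(sum((tab$x - mx)^2) * sum((tab$y - my)^2))
  expect_equal(cm$r["x", "y"], r_oracle, tolerance = 1e-12)
  expect_equal(cm$r["x", "y"], cm$r["y", "x"])
  expect_equal(diag(cm$r), c(x = 1, y = 1))
  expect_equal(cm$n["x", "y"], 5L)
})

test_that("perfect linearity, affine invariance and degenerate columns", {
  tab <- data.frame(a = 1:20, b = 2 * (1:20) + 3, flat = 7,
                    c = rnorm(20))
  cm <- correlation_matrix(tab, c("a", "c"), c("b", "flat"))
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
  expect_lt(cm$p["a", "b"], 1e-12)
  expect_true("flat" %in% cm$degenerate)
  expect_true(is.na(cm$r["a", "flat"]))
  # positive affine transforms leave r unchanged
  tab2 <- tab
  tab2$c <- 100 + 5 * tab2$c
  cm2 <- correlation_matrix(tab2, c("a", "c"), c("b", "flat"))
  expect_equal(cm2$r["a", "c"], cm$r["a", "c"], tolerance = 1e-12)
})

test_that("p-values come from the two-sided t transform on n-2 df", {
  set.seed(3)
  tab <- data.frame(u = rnorm(30), v = rnorm(30))
  cm <- correlation_matrix(tab, "u", "v")
  r <- cm$r["u", "v"]
  tstat <- r * sqrt(28 / (1 - r^2))
  expect_equal(cm$p["u", "v"], 2 * pt(-abs(tstat), df = 28), tolerance = 1e-10)
})

test_that("PCA matches a brute-force eigendecomposition oracle", {
  tab <- data.frame(delta_eps = c(67.2, 68.1, 66.9, 68.8, 67.5, 68.3),
                    tau_ps = c(8.9, 9.2, 8.7, 9.4, 9.0, 9.1),
                    alpha = c(0.984, 0.986, 0.983, 0.988, 0.985, 0.986),
                    sigma_dc = c(0.91, 0.88, 0.93, 0.86, 0.90, 0.89))
  pca <- pca_project(tab, n_components = 2)
  # oracle: standardize, eigendecompose the correlation matrix
  x <- scale(as.matrix(tab))
  eig <- eigen(cor(as.matrix(tab)))
  load_oracle <- eig$vectors[, 1:2]
  scores_oracle <- x %*% load_oracle
  for (j in 1:2) {                                   # same sign convention
    imax <- which.max(abs(load_oracle[, j]))
    if (load_oracle[imax, j] < 0) {
      load_oracle[, j] <- -load_oracle[, j]
      scores_oracle[, j] <- -scores_oracle[, j]
    }
  }
  expect_equal(unname(pca$loadings), unname(load_oracle), tolerance = 1e-10)
  expect_equal(unname(pca$scores), unname(scores_oracle), tolerance = 1e-10)
  expect_equal(pca$explained_variance_ratio,
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-10)
})

test_that("PCA loadings are orthonormal and variance ratios ordered", {
  set.seed(8)
  coh <- simulate_cohort(design_preset("pregnant_fixture", seed = 8),
                         cohort_config(n_replicates = 1L))
  tab <- coh$table
  tab[c("delta_eps", "tau_ps", "alpha", "sigma_dc")] <-
    tab[paste0("true_", c("delta_eps", "tau_ps", "alpha", "sigma_dc"))]
  pca <- pca_project(tab)
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance_ratio) <= 0))
  expect_lte(sum(pca$explained_variance_ratio), 1 + 1e-12)
})

test_that("collinear data put all variance on PC1; constant columns drop", {
  t_line <- data.frame(delta_eps = 1:10, tau_ps = 2 * (1:10),
                       alpha = -0.5 * (1:10), sigma_dc = 3 * (1:10))
  pca <- pca_project(t_line)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-10)
  t_const <- t_line
  t_const$alpha <- 1
  expect_warning(p2 <- pca_project(t_const), "constant")
  expect_equal(length(p2$vars), 3)
})

test_that("biplot export has the score/loading shape contract and round-trips", {
  tab <- data.frame(delta_eps = rnorm(3, 68), tau_ps = rnorm(3, 9),
                    alpha = rnorm(3, 0.985, 0.01), sigma_dc = rnorm(3, 0.9, 0.1))
  pca <- pca_project(tab, n_components = 2)
  bp <- biplot_export(pca, labels = c("N", "P", "P"))
  expect_equal(nrow(bp), 3 + 4)
  expect_equal(bp$label[bp$kind == "score"], c("N", "P", "P"))
  expect_error(biplot_export(pca, labels = c("N", "P")), "align")
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(bp, path)
  bp2 <- read_cohort_csv(path)
  expect_equal(bp2$PC1, bp$PC1, tolerance = 1e-12)
  expect_identical(bp2$label, bp$label)
})

test_that("pregnant transitions separate more cleanly in PC space than nonpregnant", {
  sil_p <- sil_n <- numeric(10)
  for (s in 1:10) {
    cp <- simulate_cohort(design_preset("pregnant_fixture", seed = s),
                          cohort_config(n_replicates = 1L))
    tp <- cp$table
    tp[c("delta_eps", "tau_ps", "alpha", "sigma_dc")] <-
      tp[paste0("true_", c("delta_eps", "tau_ps", "alpha", "sigma_dc"))]
    keep <- tp$stage %in% c("stage1", "stage3")
    pca <- pca_project(tp[keep, ])
    sil_p[s] <- silhouette_mean(pca$scores, tp$stage[keep], focus = "stage3")

    cn <- simulate_cohort(design_preset("nonpregnant_fixture", seed = s),
                          cohort_config(n_replicates = 1L))
    tn <- cn$table
    tn[c("delta_eps", "tau_ps", "alpha", "sigma_dc")] <-
      tn[paste0("true_", c("delta_eps", "tau_ps", "alpha", "sigma_dc"))]
    pcan <- pca_project(tn)
    sil_n[s] <- silhouette_mean(pcan$scores, tn$stage, focus = "after")
  }
  expect_gt(mean(sil_p), mean(sil_n))
})
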