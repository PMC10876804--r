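test_that("Kruskal-Wallis H matches hand-ranked examples", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
  expect_error(kruskal_wallis(list(1)), "length")
})

test_that("two-group Kruskal-Wallis equals the squared rank-sum z", {
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(8)
    b <- rnorm(10, mean = 0.8)          # continuous: no ties
    kw <- kruskal_wallis(list(a, b))
    # independent oracle: normal approximation of the Wilcoxon rank sum
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    w <- sum(rank(c(a, b))[seq_len(n1)])
    z <- (w - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kw$H, z^2, tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(11)
  groups <- list(rexp(7), rexp(9, 0.5), rexp(8, 2))
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, log))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(g) g^3))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h0)
})

test_that("Dunn post-hoc ranks the extreme pair as most distinct", {
  dn <- dunn_posthoc(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(nrow(dn), 3)
  extreme <- dn$p[dn$group_i == "g1" & dn$group_j == "g3"]
  expect_equal(extreme, min(dn$p))
  expect_true(all(dn$p_adj >= dn$p))
  # identical groups within three: that pair has z = 0, p = 1
  dn2 <- dunn_posthoc(list(c(1, 2), c(1, 2), c(9, 10)))
  expect_equal(dn2$z[dn2$group_i == "g1" & dn2$group_j == "g2"], 0)
  expect_equal(dn2$p[dn2$group_i == "g1" & dn2$group_j == "g2"], 1)
  expect_error(dunn_posthoc(list(numeric(0), 1:3)), "empty")
})

test_that("Dunn p-values agree with a permutation oracle", {
  set.seed(12)
  groups <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  dn <- dunn_posthoc(groups)
  # permutation distribution of the standardized mean-rank difference
  pooled <- unlist(groups)
  n <- lengths(groups)
  idx <- rep(1:3, n)
  obs_z <- dn$z[dn$group_i == "g1" & dn$group_j == "g2"]
  perm_z <- replicate(5000, {
    pr <- sample(idx)
    rk <- rank(pooled)
    N <- length(pooled)
    se <- sqrt((N * (N + 1) / 12) * (1 / n[1] + 1 / n[2]))
    (mean(rk[pr == 1]) - mean(rk[pr == 2])) / se
  })
  p_perm <- mean(abs(perm_z) >= abs(obs_z))
  p_mine <- dn$p[dn$group_i == "g1" & dn$group_j == "g2"]
  expect_lt(abs(p_perm - p_mine), 0.03)
})

test_that("Spearman correlation handles monotone maps, ties and reversal", {
  x <- 1:10
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  sp <- spearman_corr(c(1, 2, 3, 4, 5), c(5, 6, 4, 8, 7))
  expect_equal(sp$rho, 0.6)
  set.seed(13)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_corr(a, -b)$rho, -spearman_corr(a, b)$rho)
  expect_equal(spearman_corr(a, b)$rho,
               cor(a, b, method = "spearman"))
  degenerate <- spearman_corr(rep(1, 5), 1:5)
  expect_true(is.na(degenerate$rho))
  expect_error(spearman_corr(1:3, 1:4))
})

test_that("null features are selected at roughly the alpha rate", {
  set.seed(14)
  n_feat <- 200
  values <- matrix(rnorm(45 * n_feat), 45)
  labels <- rep(c("coma", "UWS", "MCS"), each = 15)
  tab <- toy_table(values, labels, crs_r = sample(0:20, 45, TRUE),
                   gcs = sample(3:15, 45, TRUE))
  sel <- select_features(tab, 0.05)
  rate <- length(sel$selected) / n_feat
  ci <- qbinom(c(0.025, 0.975), n_feat, 0.05) / n_feat
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("a strongly separated feature is always selected", {
  set.seed(15)
  labels <- rep(c("coma", "UWS", "MCS"), each = 15)
  strong <- rnorm(45) + 2 * (labels == "MCS") - 2 * (labels == "coma")
  values <- cbind(strong, matrix(rnorm(45 * 9), 45))
  colnames(values) <- paste0("f", 1:10)
  tab <- toy_table(values, labels, crs_r = sample(0:20, 45, TRUE),
                   gcs = sample(3:15, 45, TRUE))
  sel <- select_features(tab, 0.05)
  expect_true("f1" %in% sel$selected)
  expect_true(all(sel$stats$p[sel$stats$selected] < 0.05))
  none <- select_features(tab, 0)
  expect_length(none$selected, 0)
})

test_that("binary screening uses only the UWS and MCS rows", {
  set.seed(16)
  labels <- rep(c("coma", "UWS", "MCS"), each = 10)
  # feature separating coma from the rest but identical on UWS/MCS
  coma_only <- rnorm(30, sd = 0.1) + 5 * (labels == "coma")
  values <- cbind(coma_only = coma_only,
                  noise = rnorm(30))
  tab <- toy_table(values, labels, crs_r = sample(0:20, 30, TRUE),
                   gcs = sample(3:15, 30, TRUE))
  multi <- select_features(tab, 0.05, "multiclass")
  expect_true("coma_only" %in% multi$selected)
  binary <- select_features(tab, 0.05, "binary")
  expect_false("coma_only" %in% binary$selected)
  expect_error(select_features(toy_table(values, rep("MCS", 30))), "class")
})

test_that("selection results carry Dunn and score correlations", {
  set.seed(17)
  labels <- rep(c("coma", "UWS", "MCS"), each = 15)
  shift <- (labels == "UWS") * 1.5 + (labels == "MCS") * 3
  values <- matrix(rnorm(45 * 4), 45) + shift
  colnames(values) <- paste0("f", 1:4)
  crs_r <- c(sample(0:2, 15, TRUE), sample(3:8, 15, TRUE),
             sample(9:20, 15, TRUE))
  tab <- toy_table(values, labels, crs_r = crs_r,
                   gcs = sample(3:15, 45, TRUE))
  sel <- select_features(tab, 0.05)
  st <- sel$stats[sel$stats$selected, ]
  expect_true(all(c("dunn_p_coma_UWS", "dunn_p_coma_MCS",
                    "dunn_p_UWS_MCS") %in% names(sel$stats)))
  expect_false(any(is.na(st$rho_crsr)))
  expect_true(all(st$rho_crsr > 0)) # increases with consciousness level
})
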