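test_that("k-means labels match the brute-force best 2-partition", {
  beh <- data.frame(mouse_id = c("a", "b", "c", "d"),
                    failures = c(25, 26, 5, 6), latency_s = c(8, 9, 3, 2))
  res <- cluster_mice(beh, seed = 1)
  expect_equal(unname(res$labels), c("LH", "LH", "NLH", "NLH"))

  bf <- brute_force_kmeans2(as.matrix(beh[, c("failures", "latency_s")]))
  expect_equal(res$inertia, bf$inertia, tolerance = 1e-9)
  # partition agreement up to label swap
  expect_true(all(table(res$labels, bf$labels) %in%
                    c(0, table(res$labels))))
  expect_gt(res$centroids["LH", "failures"],
            res$centroids["NLH", "failures"])
})

test_that("cluster labels are invariant to row order", {
  beh <- data.frame(mouse_id = paste0("m", 1:6),
                    failures = c(24, 27, 25, 4, 6, 5),
                    latency_s = c(8, 9, 8.5, 2, 3, 2.5))
  r1 <- cluster_mice(beh, seed = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  r2 <- cluster_mice(beh[perm, ], seed = 2)
  expect_equal(r1$labels[beh$mouse_id], r2$labels[beh$mouse_id])
})

test_that("two distinct points become their own centroids", {
  beh <- data.frame(mouse_id = c("a", "b", "c"),
                    failures = c(20, 20, 2), latency_s = c(7, 7, 1))
  res <- cluster_mice(beh, seed = 1)
  expect_equal(unname(res$centroids["LH", ]), c(20, 7),
               ignore_attr = TRUE)
  expect_equal(unname(res$centroids["NLH", ]), c(2, 1),
               ignore_attr = TRUE)
  expect_equal(res$inertia, 0)
})

test_that("identical points cannot be clustered", {
  beh <- data.frame(mouse_id = c("a", "b"), failures = c(5, 5),
                    latency_s = c(3, 3))
  expect_error(cluster_mice(beh), "identical")
})

test_that("frozen reference model reproduces the printed scores", {
  m <- reference_discriminant()
  at0 <- classify_mice(m, 0, 0)
  expect_equal(at0$score_lh, -24.75)
  expect_equal(at0$score_nlh, -15.34)
  expect_equal(at0$class, "NLH")

  at25 <- classify_mice(m, 25, 8)
  expect_equal(at25$score_lh, -24.75 + 0.23 * 25 + 4.79 * 8)
  expect_equal(at25$score_lh, 19.32)
  expect_equal(at25$score_nlh, -2.36)
  expect_equal(at25$class, "LH")
})

test_that("frozen model score gap grows with failures at slope 3.01", {
  m <- reference_discriminant()
  lat <- 5
  gaps <- with(classify_mice(m, 0:30, lat), score_lh - score_nlh)
  expect_equal(unique(round(diff(gaps), 10)), 0.23 + 2.78)
})

test_that("frozen model partitions the plane by 3.01F - 5.52L = 9.41", {
  m <- reference_discriminant()
  grid <- expand.grid(failures = seq(0, 30, by = 2),
                      latency = seq(0, 10, by = 0.5))
  res <- classify_mice(m, grid$failures, grid$latency)
  lhs <- 3.01 * grid$failures - 5.52 * grid$latency
  expect_equal(res$class, ifelse(lhs > 9.41, "LH", "NLH"))
})

test_that("LDA on separable clusters reproduces its training labels", {
  sim <- simulate_behavior(n_lh = 10, n_nlh = 12, n_ctrl = 0, seed = 5)
  labels <- setNames(sim$truth$true_class, sim$truth$mouse_id)
  model <- fit_discriminant(sim$behavior, labels)
  pred <- classify_mice(model, sim$behavior$failures,
                        sim$behavior$latency_s)
  expect_equal(pred$class, unname(labels[sim$behavior$mouse_id]))
  # idempotence: refitting on the predicted labels changes nothing
  model2 <- fit_discriminant(sim$behavior,
                             setNames(pred$class, sim$behavior$mouse_id))
  pred2 <- classify_mice(model2, sim$behavior$failures,
                         sim$behavior$latency_s)
  expect_equal(pred2$class, pred$class)
})

test_that("fitted LDA classification agrees with MASS::lda", {
  sim <- simulate_behavior(n_lh = 8, n_nlh = 9, n_ctrl = 0, seed = 9,
                           cluster_sds = list(c(4, 2), c(4, 2)))
  labels <- setNames(sim$truth$true_class, sim$truth$mouse_id)
  model <- fit_discriminant(sim$behavior, labels)
  ours <- classify_mice(model, sim$behavior$failures,
                        sim$behavior$latency_s)$class
  ref <- MASS::lda(sim$behavior[, c("failures", "latency_s")],
                   grouping = labels[sim$behavior$mouse_id])
  theirs <- as.character(
    predict(ref, sim$behavior[, c("failures", "latency_s")])$class)
  expect_equal(ours, theirs)
})

test_that("rescaling latency to milliseconds rescales its coefficient", {
  sim <- simulate_behavior(n_lh = 10, n_nlh = 10, n_ctrl = 0, seed = 3)
  labels <- setNames(sim$truth$true_class, sim$truth$mouse_id)
  m_s <- fit_discriminant(sim$behavior, labels)
  beh_ms <- sim$behavior
  beh_ms$latency_s <- beh_ms$latency_s * 1000
  m_ms <- fit_discriminant(beh_ms, labels)
  expect_equal(m_ms$LH[["coef_latency"]],
               m_s$LH[["coef_latency"]] / 1000, tolerance = 1e-9)
  expect_equal(classify_mice(m_ms, beh_ms$failures, beh_ms$latency_s)$class,
               classify_mice(m_s, sim$behavior$failures,
                             sim$behavior$latency_s)$class)
})

test_that("singular pooled covariance is diagnosed", {
  beh <- data.frame(mouse_id = paste0("m", 1:6),
                    failures = c(1, 2, 3, 4, 5, 6),
                    latency_s = c(1, 2, 3, 4, 5, 6))  # perfectly collinear
  labels <- setNames(rep(c("LH", "NLH"), each = 3), beh$mouse_id)
  expect_error(fit_discriminant(beh, labels), "singular")
})

test_that("ANOVA F matches the closed-form one-way oracle", {
  y <- c(1, 2, 3, 4, 5, 6, 1, 2, 3)
  g <- rep(c("A", "B", "C"), each = 3)
  beh <- data.frame(failures = y, latency_s = y)
  res <- compare_groups(beh, g)
  # textbook one-way ANOVA computed by hand
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(3 * (gm - grand)^2)
  ssw <- sum((y - gm[g])^2)
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$failures$F, F_oracle, tolerance = 1e-9)
  expect_equal(res$failures$p, pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical groups give F = 0, p = 1 and Bonferroni caps at 1", {
  y <- rep(c(1, 2, 3), 3)
  g <- rep(c("A", "B", "C"), each = 3)
  beh <- data.frame(failures = y, latency_s = y)
  res <- compare_groups(beh, g)
  expect_equal(res$failures$F, 0)
  expect_equal(res$failures$p, 1)
  expect_equal(res$failures$pairwise$p_adj,
               pmin(1, res$failures$pairwise$p_raw * 3))
  expect_error(compare_groups(beh, c("A", rep("B", 8))), "< 2 members")
})

test_that("cluster-fit-classify recovers truth at 4-sd separation", {
  hits <- vapply(1:40, function(s) {
    sim <- simulate_behavior(n_lh = 14, n_nlh = 17, n_ctrl = 0, seed = s,
                             cluster_means = list(c(25, 8), c(5, 3)),
                             cluster_sds = list(c(3, 1), c(3, 1)))
    cl <- cluster_mice(sim$behavior, seed = s)
    model <- fit_discriminant(sim$behavior, cl$labels)
    pred <- classify_mice(model, sim$behavior$failures,
                          sim$behavior$latency_s)
    truth <- setNames(sim$truth$true_class, sim$truth$mouse_id)
    all(pred$class == unname(truth[sim$behavior$mouse_id]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
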