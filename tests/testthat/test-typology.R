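test_that("phase bins are ordered, contiguous and half-open", {
  b <- phase_bins()
  expect_equal(b$bin, c("JV1", "JV2", "FIN", "FL", "GF1", "GF2"))
  expect_equal(b$from[-1], b$to[-nrow(b)])
  expect_equal(b$from[1], 10)
  expect_equal(b$to[nrow(b)], 87)
})

test_that("phase stress vectors average and count per bin", {
  # unstressed season covering all bins
  daily <- data.frame(zadoks = seq(10, 92, by = 1),
                      oxdef_photo = 1)
  v <- phase_stress_vector(daily)
  expect_equal(unname(v$stress), rep(1, 6))
  expect_equal(unname(v$waterlogged_days), rep(0L, 6))
  expect_true(v$complete)

  # half-open boundaries: a day at 21.0 belongs to JV2, not JV1
  d2 <- data.frame(zadoks = c(15, 21), oxdef_photo = c(0.4, 0.6))
  v2 <- phase_stress_vector(d2)
  expect_equal(v2$stress[["JV1"]], 0.4)
  expect_equal(v2$stress[["JV2"]], 0.6)
  expect_false(v2$complete)  # remaining bins never entered

  # 10 days at 0.5 and 10 at 1.0 in GF1: mean 0.75, 10 waterlogged days
  d3 <- data.frame(zadoks = c(seq(10, 70, length.out = 60), rep(75, 20),
                              seq(80, 86, length.out = 10)),
                   oxdef_photo = 1)
  d3$oxdef_photo[61:70] <- 0.5
  v3 <- phase_stress_vector(d3)
  expect_equal(v3$stress[["GF1"]], 0.75)
  expect_equal(v3$waterlogged_days[["GF1"]], 10L)

  expect_error(phase_stress_vector(data.frame()), "empty")
})

test_that("k-means equals the exhaustive minimum-WSS partition", {
  withr::with_seed(77, {
    x <- matrix(runif(10 * 6), nrow = 10)
    for (k in 2:3) {
      oracle <- brute_force_kmeans(x, k)
      fit <- fit_typology(x, k = k, seed = 5, n_restarts = 25)
      expect_equal(sum(fit$within_ss), oracle$wss, tolerance = 1e-8)
      # same partition up to label permutation
      expect_equal(
        length(unique(paste(fit$assignments, oracle$assigned))),
        k)
    }
  })
})

test_that("trivial clustering geometries are solved exactly", {
  # 4 distinct points, k = 4: each its own cluster, all variance explained
  x4 <- diag(4) %x% matrix(1, 1, 6) * 0.5 + 0.25
  fit <- fit_typology(x4, k = 4, seed = 1)
  expect_equal(sort(tabulate(fit$assignments, 4)), rep(1L, 4))
  expect_equal(fit$variance_explained, 1)
  # identical vectors, k = 1: zero within-cluster variance
  xid <- matrix(0.7, nrow = 6, ncol = 6)
  fit1 <- fit_typology(xid, k = 1, seed = 1)
  expect_equal(sum(fit1$within_ss), 0)
  # degenerate duplicates with k larger than distinct points still return
  fit2 <- fit_typology(xid, k = 4, seed = 1)
  expect_equal(sum(fit2$within_ss), 0)
  expect_error(fit_typology(xid[1:3, ], k = 4), "at least")
})

test_that("variance explained is non-decreasing in k", {
  pv <- planted_vectors(120, seed = 9)
  ve <- vapply(1:6, function(k) {
    fit_typology(pv$x, k = k, seed = 3, n_restarts = 8)$variance_explained
  }, numeric(1))
  expect_true(all(diff(ve) >= -1e-9))
  expect_equal(ve[1], 0)
})

test_that("planted archetypes are recovered almost perfectly", {
  pv <- planted_vectors(400, seed = 15)
  fit <- fit_typology(pv$x, k = 4, seed = 6)
  tab <- table(pv$truth, fit$assignments)
  agreement <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agreement, 0.95)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(pv$truth, fit$assignments)
  expect_gte(ari, 0.9)
})

test_that("clustering is deterministic under a fixed seed", {
  pv <- planted_vectors(100, seed = 2)
  expect_identical(fit_typology(pv$x, k = 4, seed = 10),
                   fit_typology(pv$x, k = 4, seed = 10))
})

test_that("incomplete seasons are dropped from clustering with a message", {
  pv <- planted_vectors(50, seed = 4)
  x <- pv$x
  x[3, 2] <- NA
  expect_message(fit <- fit_typology(x, k = 2, seed = 1), "incomplete")
  expect_true(is.na(fit$assignments[3]))
  expect_equal(sum(!is.na(fit$assignments)), 49)
})

test_that("cluster labels order by severity with the right prefixes", {
  cents <- rbind(c(1, 1, 1, 1, 1, 1),
                 c(1, 1, 1, 0.9, 0.7, 0.8),   # late moderate
                 c(0.3, 0.4, 0.9, 1, 1, 1),   # early severe
                 c(1, 1, 0.9, 0.6, 0.4, 0.5)) # late severe
  ty <- structure(list(k = 4, centroids = cents,
                       assignments = rep(1:4, each = 5),
                       complete = rep(TRUE, 20)),
                  class = "stress_typology")
  lab <- label_clusters(ty, "spring")
  expect_equal(lab$labels[1], "SW0")
  expect_equal(lab$descriptors[1], "minimal waterlogging")
  # severity ordering: total stress 0 < late-mod < late-sev < early-sev
  ts <- rowSums(1 - cents)
  expect_equal(lab$label_order, rank(ts, ties.method = "first") - 1)
  expect_match(lab$descriptors[3], "early-onset")
  expect_match(lab$descriptors[2], "late-onset")
  wlab <- label_clusters(ty, "winter")
  expect_true(all(startsWith(wlab$labels, "WW")))
})

test_that("labelling is invariant to cluster index permutation", {
  pv <- planted_vectors(80, seed = 21)
  fit <- fit_typology(pv$x, k = 4, seed = 2)
  lab1 <- label_clusters(fit, "spring")
  perm <- c(3, 1, 4, 2)
  fit2 <- fit
  fit2$centroids <- fit$centroids[perm, ]
  fit2$assignments <- match(fit$assignments, perm)
  lab2 <- label_clusters(fit2, "spring")
  expect_equal(typology_assignments(lab1), typology_assignments(lab2))
})

test_that("pattern frequencies sum to 100 within each group", {
  labels <- c(rep("SW0", 2), "SW1", "SW2")
  f <- pattern_frequencies(labels)
  expect_equal(sum(f$pct), 100)
  expect_equal(f$pct[f$pattern == "SW0"], 50)
  f10 <- pattern_frequencies(rep("SW0", 10))
  expect_equal(f10$pct, 100)
  # grouped: each group sums to 100
  g <- rep(c("a", "b"), each = 2)
  fg <- pattern_frequencies(labels, g)
  expect_equal(as.numeric(tapply(fg$pct, fg$group, sum)),
               c(100, 100))
})
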