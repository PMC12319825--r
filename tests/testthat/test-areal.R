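# small synthetic ratio tables used across the statistical tests
ratio_table <- function(values_by_seed, area = "area01", hemi = "left",
                        region = "prefrontal") {
  do.call(rbind, lapply(names(values_by_seed), function(s) {
    v <- values_by_seed[[s]]
    data.frame(subject_id = sprintf("sub-%02d", seq_along(v)),
               hemisphere = hemi, area_name = area, region = region,
               seed = s, n_vertices = 10L, ratio = v,
               mean_z = ifelse(v > 0, 0.2, NA),
               stringsAsFactors = FALSE)
  }))
}

test_that("areal ratios count supra-threshold vertices per area", {
  g <- tiny_geom()
  nv <- nrow(g$surface)
  a <- g$areas$area_name[1]
  verts <- which(g$surface$hemisphere == "left" & g$surface$area_name == a)
  v <- rep(0, nv)
  v[verts[seq_len(floor(length(verts) * 0.4))]] <- 0.3
  maps <- list(`sub-01` = list(left = list(aVIP = v, mVIP = rep(0, nv),
                                           pVIP = rep(NA_real_, nv))))
  tab <- areal_ratios(maps, g, z_thr = 0.05)
  row <- tab[tab$area_name == a & tab$seed == "aVIP", ]
  expect_equal(row$ratio, floor(length(verts) * 0.4) / length(verts))
  expect_equal(row$mean_z, 0.3)
  # below-threshold and all-missing maps give ratio 0 with missing mean_z
  expect_true(all(tab$ratio[tab$seed == "mVIP"] == 0))
  expect_true(all(tab$ratio[tab$seed == "pVIP"] == 0))
  expect_true(all(is.na(tab$mean_z[tab$ratio == 0])))
  expect_true(all(tab$ratio >= 0 & tab$ratio <= 1))
})

test_that("Kruskal-Wallis H matches the hand-computed no-ties example", {
  tab <- ratio_table(list(aVIP = c(1, 2, 3), mVIP = c(4, 5, 6),
                          pVIP = c(7, 8, 9)))
  res <- kruskal_wallis_per_area(tab, scope = "left")
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(res$p_raw, stats::pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical groups give H = 0, p = 1", {
  tab <- ratio_table(list(aVIP = rep(0.5, 4), mVIP = rep(0.5, 4),
                          pVIP = rep(0.5, 4)))
  res <- kruskal_wallis_per_area(tab, scope = "left")
  expect_equal(res$H, 0)
  expect_equal(res$p_raw, 1)
  expect_false(res$significant)
})

test_that("H is a rank statistic: invariant under increasing transforms", {
  set.seed(41)
  v <- list(aVIP = runif(6), mVIP = runif(6), pVIP = runif(6))
  h1 <- kruskal_wallis_per_area(ratio_table(v), scope = "left")$H
  v2 <- lapply(v, function(x) exp(3 * x) - 1)
  h2 <- kruskal_wallis_per_area(ratio_table(v2), scope = "left")$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("H's null distribution is invariant under group relabeling", {
  set.seed(42)
  vals <- rnorm(9)
  h_obs <- kruskal_wallis_per_area(
    ratio_table(list(aVIP = vals[1:3], mVIP = vals[4:6], pVIP = vals[7:9])),
    scope = "left")$H
  perm <- replicate(500, {
    p <- sample(vals)
    kruskal_wallis_per_area(
      ratio_table(list(aVIP = p[1:3], mVIP = p[4:6], pVIP = p[7:9])),
      scope = "left")$H
  })
  # the observed H of pure-noise data is a typical draw of its own
  # permutation distribution (central quantile, two-sided at 1%)
  expect_gte(mean(perm >= h_obs), 0.005)
})

test_that("pooling hemispheres doubles the observations per group", {
  l <- ratio_table(list(aVIP = 1:5 / 10, mVIP = 2:6 / 10, pVIP = 3:7 / 10))
  r <- ratio_table(list(aVIP = 4:8 / 10, mVIP = 3:7 / 10, pVIP = 2:6 / 10),
                   hemi = "right")
  tab <- rbind(l, r)
  pooled <- kruskal_wallis_per_area(tab, scope = "pooled")
  left <- kruskal_wallis_per_area(tab, scope = "left")
  ref <- kruskal.test(c(tab$ratio),
                      factor(tab$seed))
  expect_equal(pooled$H, unname(ref$statistic), tolerance = 1e-12)
  ref_l <- kruskal.test(l$ratio, factor(l$seed))
  expect_equal(left$H, unname(ref_l$statistic), tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  set.seed(43)
  p <- runif(20)
  ord <- sample(20)
  expect_equal(bh_correct(p)[ord], bh_correct(p[ord]))
  # brute-force step-up oracle on many random vectors: the BH rejection
  # set at level alpha is the largest k with p_(k) <= k * alpha / m
  for (i in 1:200) {
    m <- sample(3:30, 1)
    p <- round(runif(m), 3)
    adj <- bh_correct(p)
    for (alpha in c(0.01, 0.05, 0.2)) {
      ps <- sort(p)
      k <- max(c(0, which(ps <= seq_len(m) * alpha / m)))
      reject_oracle <- if (k == 0) rep(FALSE, m) else p <= ps[k]
      expect_identical(adj <= alpha, reject_oracle)
    }
  }
})

test_that("preference classification follows the significance rules", {
  mk_tests <- function(sl, sr, sp, area = "area01") data.frame(
    area_name = area, scope = c("left", "right", "pooled"),
    H = 5, p_raw = 0.01, p_adj = 0.01,
    significant = c(sl, sr, sp), stringsAsFactors = FALSE)
  mk_summary <- function(ra, rp, za = 0.3, zp = 0.1, area = "area01")
    do.call(rbind, lapply(c("left", "right"), function(h) data.frame(
      hemisphere = h, area_name = area, region = "prefrontal",
      seed = c("aVIP", "mVIP", "pVIP"), n_subjects = 5L,
      mean_ratio = c(ra, 0.1, rp), sem_ratio = 0.01,
      mean_z = c(za, 0.05, zp), stringsAsFactors = FALSE)))

  # significant pooled, aVIP ratio dominant
  out <- classify_preference(mk_tests(FALSE, FALSE, TRUE),
                             mk_summary(0.6, 0.2))
  expect_equal(out$preferred, "aVIP")
  expect_equal(out$basis, "significant_test")
  # significant pooled, pVIP dominant
  expect_equal(classify_preference(mk_tests(TRUE, TRUE, FALSE),
                                   mk_summary(0.1, 0.7))$preferred, "pVIP")
  # near-tie goes to "both"
  expect_equal(classify_preference(mk_tests(FALSE, FALSE, TRUE),
                                   mk_summary(0.50, 0.52))$preferred, "both")
  # non-significant everywhere
  none <- classify_preference(mk_tests(FALSE, FALSE, FALSE),
                              mk_summary(0.6, 0.2))
  expect_equal(none$preferred, "none")
  expect_equal(none$basis, "none")
  # one hemisphere only: judged on the average z
  one <- classify_preference(mk_tests(TRUE, FALSE, FALSE),
                             mk_summary(0.2, 0.2, za = 0.1, zp = 0.4))
  expect_equal(one$preferred, "pVIP")
  expect_equal(one$basis, "mean_z_tiebreak")
  # missing scope refused
  expect_error(classify_preference(mk_tests(TRUE, TRUE, TRUE)[1:2, ],
                                   mk_summary(0.6, 0.2)), "scope")
})

test_that("areal summary computes across-animal mean and SEM", {
  tab <- ratio_table(list(aVIP = c(0.2, 0.4, 0.6), mVIP = rep(0, 3),
                          pVIP = rep(0, 3)))
  s <- summarize_areal_ratios(tab)
  row <- s[s$seed == "aVIP", ]
  expect_equal(row$mean_ratio, 0.4)
  expect_equal(row$sem_ratio, sd(c(0.2, 0.4, 0.6)) / sqrt(3))
  expect_equal(row$n_subjects, 3L)
})
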