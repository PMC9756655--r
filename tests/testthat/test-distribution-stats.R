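test_that("circular KDE integrates to one and wraps continuously", {
  set.seed(71)
  samples <- list(runif(50, 0, 100),
                  c(rnorm(100, 3, 2), rnorm(100, 97, 2)) %% 100,
                  rnorm(200, 50, 5) %% 100)
  for (p in samples) {
    de <- kde_circular(p)
    step <- de$grid[2] - de$grid[1]
    # trapezoidal integral over one full period (grid wraps at 100 == 0)
    integral <- sum((de$density + c(de$density[-1], de$density[1])) / 2) * step
    expect_equal(integral, 1, tolerance = 1e-6)
    # continuity across the 0/100 seam, checked at a fine grid step
    fine <- kde_circular(p, bandwidth = max(de$bandwidth, 2), n_grid = 8192L)
    expect_lt(abs(fine$density[1] - fine$density[length(fine$density)]), 1e-3)
  }
})

test_that("uniform lattice positions give a flat density", {
  p <- seq(0, 99.9, by = 0.1)
  de <- kde_circular(p, bandwidth = 3)
  expect_lt(max(de$density) - min(de$density), 0.05 * mean(de$density))
})

test_that("mass split across the wrap point forms one mode straddling 0", {
  set.seed(72)
  p <- c(rnorm(300, 1, 1.5), rnorm(300, 99, 1.5)) %% 100
  de <- kde_circular(p, bandwidth = 2)
  modes <- density_modes(de, min_height_frac = 0.5)
  # single cluster at the seam: every strong mode within 3 points of 0/100
  circ_d0 <- pmin(modes, 100 - modes)
  expect_true(all(circ_d0 < 3))
  # density at the seam is high, not split
  expect_gt(de$density[1], 0.5 * max(de$density))
})

test_that("planted wrapped-normal sample puts the density argmax near 50", {
  set.seed(73)
  p <- rnorm(500, 50, 5) %% 100
  de <- kde_circular(p)
  expect_lt(abs(de$grid[which.max(de$density)] - 50), 2)
})

test_that("KS identities: identical samples and disjoint supports", {
  x <- c(3, 1, 4, 1, 5)
  r <- ks_two_sample(x, x, method = "exact_permutation")
  expect_equal(r$d_statistic, 0)
  expect_equal(r$p_value, 1)
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$d_statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("exact permutation p matches full-enumeration oracle", {
  # independent oracle: enumerate all C(8,4) = 70 label assignments with a
  # from-scratch ECDF sup computation
  x <- c(1, 3, 5, 7); y <- c(2, 4, 6, 8)
  pooled <- c(x, y)
  sup_ecdf <- function(a, b) {
    v <- sort(pooled)
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  d_obs <- sup_ecdf(x, y)
  combos <- utils::combn(8, 4)
  d_all <- apply(combos, 2, function(ix) sup_ecdf(pooled[ix], pooled[-ix]))
  p_oracle <- mean(d_all >= d_obs - 1e-12)
  r <- ks_two_sample(x, y, method = "exact_permutation")
  expect_equal(r$d_statistic, d_obs)
  expect_equal(r$p_value, p_oracle)
})

test_that("asymptotic KS agrees with the reference implementation", {
  set.seed(81)
  for (i in 1:20) {
    x <- runif(sample(10:60, 1), 0, 100)
    y <- runif(sample(10:60, 1), 0, 100) + rnorm(1, 0, 10)
    r <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(r$d_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("exact and asymptotic p agree closely at n = 8 + 8", {
  set.seed(82)
  for (i in 1:100) {
    x <- rnorm(8); y <- rnorm(8)
    pa <- ks_two_sample(x, y)$p_value
    pe <- ks_two_sample(x, y, method = "exact_permutation")$p_value
    expect_lt(abs(pa - pe), 0.05)
  }
})

test_that("per-genus means and order quartiles recover planted values", {
  counts <- data.frame(genome_id = c("a", "b", "c"),
                       GGDEF = c(6, 8, 3), EAL = c(2, 4, 1),
                       GGDEF_EAL = c(1, 1, 0), HD_GYP = c(1, 1, 0))
  tax <- data.frame(genome_id = c("a", "b", "c"), order = "O1",
                    genus = c("g1", "g1", "g2"),
                    species_or_strain = c("s1", "s2", "s3"))
  res <- per_genus_mean_counts(counts, tax)
  expect_equal(res$genus_means$mean_count[res$genus_means$genus == "g1"], 12)
  expect_equal(res$genus_means$mean_count[res$genus_means$genus == "g2"], 4)
  expect_equal(res$order_summary$median, 8)
})

test_that("class ratios guard zero denominators and average per genus", {
  counts <- data.frame(genome_id = c("a", "b", "c"),
                       GGDEF = c(4, 8, 3), EAL = c(2, 2, 0),
                       GGDEF_EAL = c(2, 2, 1), HD_GYP = c(0, 1, 1))
  tax <- data.frame(genome_id = c("a", "b", "c"), order = "O1",
                    genus = c("g1", "g1", "g1"),
                    species_or_strain = c("s1", "s2", "s3"))
  res <- class_ratios(counts, tax)
  expect_equal(res$per_genome$GGDEF_EAL_ratio, c(2, 4, NA))
  # genus mean over the defined ratios only
  expect_equal(res$genus_means$GGDEF_EAL_ratio, 3)
  expect_true(is.na(res$per_genome$GGDEF_HD_GYP_ratio[1]))
})

test_that("median count conventions", {
  counts <- data.frame(genome_id = letters[1:3], GGDEF = c(1, 2, 3),
                       EAL = 0, GGDEF_EAL = 0, HD_GYP = 0)
  expect_equal(median_counts(counts, "GGDEF"), 2)
  counts4 <- data.frame(genome_id = letters[1:4], GGDEF = c(1, 2, 3, 4),
                        EAL = 0, GGDEF_EAL = 0, HD_GYP = 0)
  expect_equal(median_counts(counts4, "GGDEF"), 2.5)
})

test_that("Spearman correlation matches a direct rank computation", {
  expect_equal(size_count_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(size_count_correlation(1:10, rev(1:10))$rho, -1)
  set.seed(91)
  x <- sample(50); y <- sample(50)
  got <- size_count_correlation(x, y)
  # brute-force tie-free rank correlation
  rho_direct <- 1 - 6 * sum((rank(x) - rank(y))^2) / (50 * (50^2 - 1))
  expect_equal(got$rho, rho_direct, tolerance = 1e-12)
  expect_false(size_count_correlation(rep(5, 10), 1:10)$defined)
})
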