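test_that("Mann-Whitney U matches pair counting and enumeration", {
  mw <- mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(oracle_u_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets: U = n^2/2, Z = 0
  mw2 <- mann_whitney_z(1:4, 1:4)
  expect_equal(mw2$U, 8)
  expect_equal(mw2$Z, 0)
  expect_equal(mw2$p, 1)
  # antisymmetry
  set.seed(1)
  x <- rnorm(9); y <- rnorm(7) + .5
  a <- mann_whitney_z(x, y); b <- mann_whitney_z(y, x)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)
  # U equals pair counting on random samples with ties
  for (i in 1:25) {
    x <- sample(1:6, sample(3:9, 1), replace = TRUE)
    y <- sample(1:6, sample(3:9, 1), replace = TRUE)
    expect_equal(mann_whitney_z(x, y)$U, oracle_u(x, y))
    w <- suppressWarnings(wilcox.test(x, y))
    expect_equal(mann_whitney_z(x, y)$U, unname(w$statistic))
  }
  expect_equal(mann_whitney_z(rep(2, 4), rep(2, 5))$Z, 0)
  expect_error(mann_whitney_z(numeric(0), 1),
               class = "msdyn_parameter_error")
})

test_that("BH step-up equals its defining formula and p.adjust", {
  expect_equal(bh_fdr(c(0.009, 0.005, 0.09, 0.86, 0.84)),
               c(0.0225, 0.0225, 0.15, 0.86, 0.86))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  }
  p <- runif(5)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "msdyn_parameter_error")
})

test_that("Spearman rho is Pearson on midranks with a t-approximate p", {
  expect_equal(spearman_rho(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3)$rho, -1)
  # rank formula: sum(d^2) = 4, rho = 1 - 24/120 = 0.8
  r <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, oracle_spearman_noties(c(1, 2, 3, 4, 5),
                                             c(2, 1, 4, 3, 5)))
  expect_equal(r$rho, 0.8)
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1:8, 10, replace = TRUE)
    y <- rnorm(10)
    expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(spearman_rho(x, y)$rho, unname(ct$estimate),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "msdyn_undefined_correlation_error")
})

test_that("Levene's test is an ANOVA on absolute deviations from group means", {
  # identical dispersion patterns give W = 0
  expect_equal(levene_test(c(1, 3, 11, 13), rep(c("a", "b"), each = 2))$W, 0)
  big <- levene_test(c(0, 0, 0, 0, -10, 10, -10, 10),
                     rep(c("a", "b"), each = 4))
  expect_gt(big$W, 100)
  expect_lt(big$p, 0.01)
  # exchangeability within groups
  set.seed(4)
  v <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  w1 <- levene_test(v, g)$W
  v2 <- c(sample(v[1:6]), v[7:12])
  expect_equal(levene_test(v2, g)$W, w1)
  # agreement with the reference implementation (mean-centred)
  lt <- levene_test(v, g)
  ref <- car::leveneTest(v ~ factor(g), center = mean)
  expect_equal(lt$W, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(lt$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
  expect_error(levene_test(1:3, c("a", "a", "b")),
               class = "msdyn_parameter_error")
})

test_that("pooled t-test handles the textbook cases", {
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  tt <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_error(students_t(c(0, 0), c(1, 1)), class = "msdyn_undefined_error")
  wl <- students_t(rnorm(5), rnorm(6), welch = TRUE)
  expect_true(is.finite(wl$t))
})

test_that("band power integrates a sinusoid's energy in its band", {
  fs <- 125; a <- 2
  tt <- seq_len(fs * 8) / fs
  s <- a * sin(2 * pi * 10 * tt)
  rec <- average_reference(eeg_recording(rbind(s, -s), fs))
  bp <- band_power(rec, c(8, 14))
  expect_equal(bp$band_power, a^2 / 2, tolerance = 0.05)
  expect_equal(bp$total_power, a^2 / 2, tolerance = 0.05)
  # out-of-band tone leaks < 1% into the alpha band
  s20 <- a * sin(2 * pi * 20 * tt)
  rec20 <- average_reference(eeg_recording(rbind(s20, -s20), fs))
  bp20 <- band_power(rec20, c(8, 14))
  expect_lt(bp20$band_power, 0.01 * bp20$total_power)
  # quadratic amplitude scaling
  rec2 <- average_reference(eeg_recording(rbind(2 * s, -2 * s), fs))
  expect_equal(band_power(rec2, c(8, 14))$band_power / bp$band_power, 4,
               tolerance = 1e-6)
  expect_error(band_power(rec, c(8, 70)), class = "msdyn_parameter_error")
  short <- eeg_recording(matrix(rnorm(2 * 100), 2, 100), fs)
  expect_error(band_power(short), class = "msdyn_parameter_error")
})

test_that("group comparison emits one corrected family per parameter", {
  set.seed(5)
  k <- 5; n <- 12
  tab <- expand.grid(subject = sprintf("S%02d", 1:n), class = 1:k)
  tab$group <- ifelse(as.integer(sub("S", "", tab$subject)) <= n / 2,
                      "patient", "control")
  tab$occurrence <- rnorm(nrow(tab), 3)
  tab$coverage <- rnorm(nrow(tab), 20)
  tab$duration <- rnorm(nrow(tab), 60)
  # plant a strong effect on class 2 occurrence
  sel <- tab$class == 2 & tab$group == "patient"
  tab$occurrence[sel] <- tab$occurrence[sel] + 10
  cmp <- compare_groups(tab)
  expect_equal(nrow(cmp), 3 * k)
  expect_true(all(cmp$p_fdr >= cmp$p))
  occ <- cmp[cmp$parameter == "occurrence", ]
  expect_lt(occ$p_fdr[occ$class == "B"], 0.05)
  expect_equal(occ$p_fdr, bh_fdr(occ$p))
  # correlations: a score equal to a parameter column correlates at rho 1
  scores <- data.frame(subject = sprintf("S%02d", 1:n),
                       group = tab$group[match(sprintf("S%02d", 1:n),
                                               tab$subject)])
  scores$MADRS <- tab$coverage[tab$class == 3][
    match(scores$subject, tab$subject[tab$class == 3])]
  cc <- correlate_clinical(tab, scores,
                           data.frame(parameter = "coverage", class = "C"),
                           score_vars = "MADRS")
  expect_equal(cc$rho, 1)
})
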