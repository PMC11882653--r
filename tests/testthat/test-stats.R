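# Species-comparison statistics and ordinal regression, checked against
# independent oracles (anova(lm), cor.test, glm, MASS::polr) and brute-force
# definitions.

test_that("one-way ANOVA matches hand computation and the lm oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("A", "B", "C"), each = 3)
  a <- one_way_anova(v, g)
  expect_equal(a$ssb, 42, tolerance = 1e-12)
  expect_equal(a$ssw, 6, tolerance = 1e-12)
  expect_equal(a$F, 21, tolerance = 1e-12)
  expect_identical(c(a$df_between, a$df_within), c(2L, 6L))
  expect_equal(a$p, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # oracle property on random data
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n <- sample(3:7, k, replace = TRUE)
    gg <- rep(letters[1:k], n)
    vv <- rnorm(sum(n), mean = rep(runif(k, 0, 3), n))
    mine <- one_way_anova(vv, gg)
    orc <- anova(lm(vv ~ gg))
    expect_equal(mine$F, orc$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, orc$`Pr(>F)`[1], tolerance = 1e-10)
    # shift invariance
    expect_equal(one_way_anova(vv + 17.3, gg)$F, mine$F, tolerance = 1e-9)
  }

  expect_identical(one_way_anova(rep(c(1, 2, 3), each = 3),
                                 rep(letters[1:3], each = 3))$F, Inf)
  expect_identical(one_way_anova(rep(1, 9), rep(letters[1:3], each = 3))$F, 0)
})

test_that("normality screen applies the transformation ladder and skip rule", {
  set.seed(14)
  g <- rep(c("A", "B", "C"), each = 17)
  v <- rnorm(51)
  s1 <- normality_screen(v, g)
  expect_identical(s1$transformation, "identity")
  expect_gt(s1$shapiro_p, 0.05)

  vlog <- exp(rnorm(51, sd = 1.6) + rep(c(0, 1, 2), each = 17))
  s2 <- normality_screen(vlog, g)
  expect_identical(s2$transformation, "log")

  # n = 2 group excluded with a notice
  g3 <- c(rep("A", 17), rep("B", 17), rep("tiny", 2))
  v3 <- c(rnorm(34), 5, 6)
  expect_message(s3 <- normality_screen(v3, g3), "tiny")
  expect_identical(s3$skipped_groups, "tiny")
})

test_that("Tukey pairwise tests and CLD satisfy the defining property", {
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("A", "B", "C"), each = 3)
  tk <- tukey_cld(v, g)
  expect_identical(unname(tk$letters[c("A", "B", "C")]), c("a", "a", "b"))
  # A-B not significant (q ~= 1.73), C distinct (q ~= 8.66)
  pr <- tk$pairs
  ab <- pr[pr$group1 %in% c("A", "B") & pr$group2 %in% c("A", "B"), ]
  expect_false(ab$significant)
  expect_equal(ab$q, 1 / sqrt(1 / 3), tolerance = 1e-9)

  # all-equal groups: everybody shares one letter
  tk0 <- tukey_cld(rnorm(9, sd = 1e-3) + 5, g)
  expect_true(all(tk0$letters == "a"))

  # brute-force CLD property on random data: groups share a letter iff the
  # pair is not significantly different
  set.seed(27)
  for (i in 1:8) {
    k <- sample(3:6, 1)
    gg <- rep(letters[1:k], each = 4)
    vv <- rnorm(4 * k, mean = rep(sample(0:3, k, replace = TRUE), each = 4))
    tkk <- tukey_cld(vv, gg)
    share <- function(x, y)
      length(intersect(strsplit(tkk$letters[[x]], "")[[1]],
                       strsplit(tkk$letters[[y]], "")[[1]])) > 0
    for (r in seq_len(nrow(tkk$pairs))) {
      pair <- tkk$pairs[r, ]
      expect_identical(share(pair$group1, pair$group2), !pair$significant)
    }
  }
})

test_that("pearson_cor matches the closed form and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_cor(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  y <- c(2.3, 1.9, 4.4, 6.1, 9.0)
  mine <- pearson_cor(x, y)
  orc <- cor.test(x, y)
  expect_equal(mine$r, unname(orc$estimate), tolerance = 1e-12)
  expect_equal(mine$p, orc$p.value, tolerance = 1e-12)
  expect_identical(mine$df, 3L)
  expect_error(pearson_cor(x, rep(1, 5)), class = "hydroniche_validation_error")
})

test_that("proportional-odds fit matches symmetry, equivariance and oracles", {
  # symmetric design: slope exactly zero
  fs <- fit_proportional_odds(c(1, 2, 1, 2), c(0, 0, 1, 1))
  expect_lt(abs(fs$beta), 1e-4)

  set.seed(42)
  n <- 300; x <- rnorm(n)
  y <- sim_ordinal(n, x, beta = 1.2, zeta = c(-1, 0.5, 2))
  ft <- fit_proportional_odds(y, x)
  expect_true(ft$converged)
  expect_true(all(diff(ft$zeta) > 0))
  expect_equal(ft$t, ft$beta / ft$se_beta, tolerance = 1e-12)

  # affine equivariance: x/10 scales beta by 10, t invariant
  fa <- fit_proportional_odds(y, x / 10)
  expect_equal(fa$beta, 10 * ft$beta, tolerance = 1e-6)
  expect_equal(fa$t, ft$t, tolerance = 1e-6)

  # independent ML oracle
  dd <- data.frame(yy = factor(y, ordered = TRUE), x = x)
  pol <- suppressWarnings(MASS::polr(yy ~ x, data = dd, Hess = TRUE))
  expect_equal(ft$beta, unname(coef(pol)), tolerance = 1e-4)
  expect_equal(unname(ft$zeta), unname(pol$zeta), tolerance = 1e-4)
  expect_equal(ft$se_beta, sqrt(vcov(pol)[1, 1]), tolerance = 1e-3)
  # optimum beats the beta = 0 model, whose ML value is the multinomial
  # entropy bound sum n_j log(n_j / n)
  tab <- table(y)
  loglik0 <- sum(tab * log(tab / n))
  expect_gte(ft$loglik, loglik0 - 1e-6)

  # complete separation is flagged, never a silent number
  expect_warning(fsep <- fit_proportional_odds(c(1, 1, 1, 2, 2, 2),
                                               c(1, 2, 3, 10, 11, 12)),
                 "separation")
  expect_false(fsep$converged)
})

test_that("habitat association scan has power on rank-correlated panels", {
  ref <- reference_core_parameters()
  set.seed(9)
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    d <- draw_species_values(ref, "maxwc_mm", "maxwc_mm_sd")
    ft <- fit_proportional_odds(d$rank, d$value)
    if (ft$beta > 0 && ft$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)

  # scan plumbing: per-sample rows inherit species ranks, table sorted by |t|
  panel <- fixture_panel(seed = 3, n_replicates = 3, n_curves = 8)
  core <- extract_core_parameters(panel$runs)
  sc <- habitat_association_scan(core, panel$ranks)
  expect_true(all(diff(abs(sc$table$t)) <= 1e-9))
  expect_true(all(c("max_wc_mm", "min_wc_mm", "opt_wc_mm") %in%
                  sc$table$parameter))
  # water-relations slopes positive on the calibrated world
  expect_gt(sc$fits$max_wc_mm$beta, 0)
  expect_error(habitat_association_scan(core, habitat_ranks("X", 1)),
               class = "hydroniche_validation_error")
})
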