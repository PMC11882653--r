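# Core-parameter extraction: water contents, light points, WC bounds.

test_that("water content conversions match their definitions", {
  expect_identical(water_content_pct(200, 100), 100)
  expect_identical(water_content_pct(100, 100), 0)
  expect_equal(water_content_pct(100 * 5.87, 100), 487, tolerance = 1e-12)
  expect_error(water_content_pct(90, 100), class = "hydroniche_validation_error")

  expect_identical(water_content_mm(300, 100, 2), 1)    # 100 mg cm-2 == 1 mm
  expect_identical(water_content_mm(100, 100, 5), 0)
  expect_error(water_content_mm(300, 100, 0), class = "hydroniche_validation_error")

  expect_identical(stm(100, 2), 50)
  expect_identical(whc(100, 100, 3), 0)

  # algebraic identity wc_mm == wc_pct * STM / 1e4, on random valid triples
  set.seed(31)
  for (i in 1:50) {
    dm <- runif(1, 50, 800); area <- runif(1, 2, 60)
    mass <- dm * (1 + runif(1, 0, 6))
    expect_equal(water_content_mm(mass, dm, area),
                 water_content_pct(mass, dm) * stm(dm, area) / 1e4,
                 tolerance = 1e-12)
  }
})

test_that("curve_wc follows the mass convention with bounded discrepancy", {
  s <- thallus_sample("x", "sp", "site", 100, 2, 800)
  cv <- light_curve(1L, c(0, 100, 500), c(-1, 1, 2), 300, 280)
  mid <- curve_wc(cv, s)
  expect_equal(mid$wc_pct, 190)
  expect_equal(mid$wc_mm, 0.95)
  ep <- curve_wc(cv, s, convention = "endpoint")
  expect_equal(ep$wc_pct, 180)
  # equal bracketing masses: conventions coincide
  cv2 <- light_curve(1L, c(0, 100, 500), c(-1, 1, 2), 300, 300)
  expect_identical(curve_wc(cv2, s), curve_wc(cv2, s, convention = "endpoint"))
  # bounded discrepancy: |midpoint - endpoint| <= (before-after)/(2 dry) * 100
  set.seed(8)
  for (i in 1:25) {
    before <- runif(1, 150, 700); after <- runif(1, 101, before)
    cvv <- light_curve(1L, c(0, 100), c(-1, 1), before, after)
    d <- abs(curve_wc(cvv, s)$wc_pct - curve_wc(cvv, s, "endpoint")$wc_pct)
    expect_lte(d, (before - after) / (2 * s$dry_mass_mg) * 100 + 1e-9)
  }
})

test_that("lcp interpolates the first zero crossing", {
  cv <- test_curve(c(-2, -0.8, 0.5, 2, 4, 6, 7, 8, 8))
  expect_equal(lcp(cv), 12 + 13 * 0.8 / 1.3, tolerance = 1e-12)  # 20.0
  cv2 <- test_curve(c(-2, -1, 0, 2, 4, 6, 7, 8, 8))
  expect_identical(lcp(cv2), 25)                                  # exact hit
  inactive <- test_curve(c(-3, -2.5, -2, -1.8, -1.5, -1.2, -1, -1, -1))
  expect_true(is.na(lcp(inactive)))
  all_pos <- test_curve(c(0.5, 1, 2, 3, 4, 5, 6, 7, 7))
  expect_error(lcp(all_pos), class = "hydroniche_validation_error")
  # noisy positive dark reading but later negatives: compensation at 0
  odd <- test_curve(c(0.2, -0.1, 0.5, 2, 4, 6, 7, 8, 8))
  expect_identical(as.numeric(lcp(odd)), 0)
})

test_that("lsp interpolates the 90%-of-maximum crossing", {
  cv <- test_curve(c(-2, 0, 2, 4, 6.5, 8.8, 9.5, 10, 10))
  expect_equal(lsp(cv), 300 + 200 * 0.2 / 0.7, tolerance = 1e-12) # ~357.1
  expect_true(is.na(lsp(test_curve(c(-3, -2, -1, -0.5, -0.4, -0.3, -0.2, -0.1, -0.1)))))
  # plateau from the first nonzero step: LSP no later than that step
  flat <- test_curve(c(-1, 5, 5, 5, 5, 5, 5, 5, 5))
  expect_lte(lsp(flat), 12)
})

test_that("lcp < lsp on every valid noisy synthetic curve", {
  cfg <- test_cfg(n_curves = 8, noise_sd_frac = 0.05)
  smp <- test_sample(cfg)
  for (s in 1:10) {
    run <- generate_drying_run(smp, cfg, seed = 100 + s)
    for (cv in run$curves) {
      if (cv$assim[1] >= 0 || max(cv$assim) <= 0) next  # not a valid LCP curve
      l1 <- lcp(cv); l2 <- lsp(cv)
      if (is.na(l1) || is.na(l2)) next
      expect_lt(l1, l2)
    }
  }
})

test_that("np_wc_response reproduces the closed form on noise-free runs", {
  cfg <- test_cfg(n_curves = 8)
  smp <- test_sample(cfg)
  run <- generate_drying_run(smp, cfg, seed = NULL)
  resp <- np_wc_response(run, lsp_ref = 900)
  expect_equal(resp$wc_pct, sort(resp$wc_pct, decreasing = TRUE))
  for (i in seq_len(nrow(resp))) {
    steps <- protocol_ppfd()[protocol_ppfd() >= 900]
    expect_equal(resp$np[i],
                 max(model_np(steps, rep(resp$wc_pct[i], length(steps)), cfg)),
                 tolerance = 1e-9)
    expect_equal(resp$dr[i], model_np(0, resp$wc_pct[i], cfg), tolerance = 1e-9)
  }
  # DR magnitude non-decreasing with WC for the saturating respiration model
  expect_true(all(diff(-resp$dr[order(resp$wc_pct)]) >= -1e-9))
  expect_error(np_wc_response(run, lsp_ref = 2000),
               class = "hydroniche_validation_error")
})

test_that("optimal_wc_bounds interpolates, censors and stays unit-consistent", {
  r <- test_response(wc_pct = c(5, 10, 20, 30, 50, 80),
                     np = c(2, 8, 10, 9.5, 8, 4))
  b <- optimal_wc_bounds(r, threshold = 0.9)
  expect_equal(b$min_wc_pct, 15, tolerance = 1e-12)
  expect_equal(b$max_wc_pct, 30 + 20 * 0.5 / 1.5, tolerance = 1e-12)
  expect_equal(b$opt_wc_pct, b$max_wc_pct - b$min_wc_pct, tolerance = 1e-15)
  expect_equal(b$min_wc_mm, b$min_wc_pct * 15 / 1e4, tolerance = 1e-12)
  expect_false(b$censored_low); expect_false(b$censored_high)

  # degenerate plateau: both bounds censored at the data range
  flat <- test_response(wc_pct = c(10, 40, 90), np = c(5, 5, 5))
  bf <- optimal_wc_bounds(flat)
  expect_identical(bf$min_wc_pct, 10)
  expect_identical(bf$max_wc_pct, 90)
  expect_true(bf$censored_low && bf$censored_high)

  expect_error(optimal_wc_bounds(test_response(numeric(), numeric())),
               class = "hydroniche_validation_error")
})

test_that("extraction is invariant to uniform rescaling of assimilation", {
  cfg <- test_cfg(n_curves = 10, noise_sd_frac = 0.03)
  smp <- test_sample(cfg)
  run <- generate_drying_run(smp, cfg, seed = 5)
  run2 <- run
  for (i in seq_along(run2$curves))
    run2$curves[[i]]$assim <- run2$curves[[i]]$assim * 37.5
  a <- compile_core_parameters(run)
  b <- compile_core_parameters(run2)
  expect_equal(b$max_np, 37.5 * a$max_np, tolerance = 1e-9)
  expect_equal(b$dr_max, 37.5 * a$dr_max, tolerance = 1e-9)
  expect_equal(b$lcp, a$lcp, tolerance = 1e-9)
  expect_equal(b$lsp, a$lsp, tolerance = 1e-9)
  expect_equal(b$min_wc_pct, a$min_wc_pct, tolerance = 1e-9)
  expect_equal(b$max_wc_pct, a$max_wc_pct, tolerance = 1e-9)
  expect_equal(b$cge, a$cge, tolerance = 1e-9)
})

test_that("compile_core_parameters orchestrates and computes CGE", {
  cfg <- test_cfg(n_curves = 10)
  smp <- test_sample(cfg)
  run <- generate_drying_run(smp, cfg, seed = NULL)
  cp <- compile_core_parameters(run)
  expect_s3_class(cp, "core_parameters")
  expect_identical(cp$opt_wc_pct, cp$max_wc_pct - cp$min_wc_pct)
  expect_identical(cp$opt_wc_mm, cp$max_wc_mm - cp$min_wc_mm)
  expect_equal(cp$stm, cfg$stm_true, tolerance = 1e-9)
  expect_equal(cp$whc_mm, cfg$whc_true, tolerance = 1e-9)
  # CGE definition on a hand-built run: MaxNP 10 against DR -2 gives 5
  resp <- test_response(wc_pct = c(20, 60, 120), np = c(4, 10, 7),
                        dr = c(-1, -2, -3))
  i <- which.max(resp$np)
  expect_identical(max(resp$np) / abs(resp$dr[i]), 5)
  # drop_first removes the wettest curve
  cp2 <- compile_core_parameters(run, drop_first = TRUE)
  expect_s3_class(cp2, "core_parameters")
  # extract_core_parameters assembles the canonical table
  tab <- extract_core_parameters(list(t1 = run))
  expect_identical(tab$sample_id, "t1")
  expect_equal(tab$max_np, cp$max_np)
})
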