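# Shared fixtures, all built in code.

# Fresh scratch directory per call (under the session temp dir).
tmpd <- function() {
  d <- tempfile("hydroniche_test_")
  dir.create(d)
  d
}

# A mid-sized generic configuration: optimum around WC 150-220%, full
# hydration at 300% (WHC 0.45 mm at STM 15), MaxNP near 10.
test_cfg <- function(...) {
  args <- utils::modifyList(
    list(np_max_true = 10, phi = 2.5 * 10 / 1500, rd_max = 2,
         k_rd = 20, w_rise = 30, w_supra = 150, w_decay = 75,
         stm_true = 15, whc_true = 0.45, noise_sd_frac = 0, n_curves = 10),
    list(...))
  do.call(species_config, args)
}

# Thallus sample hydrated exactly to the configuration's WHC.
test_sample <- function(cfg, id = "t1", species = "TEST", dry_mass_mg = 300) {
  area <- dry_mass_mg / cfg$stm_true
  thallus_sample(id, species, "lab", dry_mass_mg, area,
                 dry_mass_mg + cfg$whc_true * 100 * area)
}

# The nine-step protocol curve from explicit assimilation values.
test_curve <- function(assim, index = 1L, mass_before = 350, mass_after = 340) {
  light_curve(index, protocol_ppfd(), assim, mass_before, mass_after)
}

# Response table with wc_mm consistent with a given STM.
test_response <- function(wc_pct, np, stm_val = 15,
                          dr = rep(-1, length(wc_pct))) {
  data.frame(curve_index = seq_along(wc_pct), wc_pct = wc_pct,
             wc_mm = wc_pct * stm_val / 1e4, np = np, dr = dr)
}

# Draw an ordinal response from the proportional-odds model.
sim_ordinal <- function(n, x, beta, zeta) {
  u <- stats::runif(n)
  cum <- vapply(zeta, function(z) stats::plogis(z - beta * x), numeric(n))
  1L + rowSums(u > cum)
}

# Per-sample species panel values drawn lognormally around the published
# means/SDs (used for ordinal power / type-I experiments without running
# the full simulator).
draw_species_values <- function(ref, column, sd_column, n_rep = 3L) {
  means <- ref[[column]]; sds <- ref[[sd_column]]
  do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    cv <- if (means[i] > 0) sds[i] / means[i] else 0
    s <- sqrt(log1p(cv^2))
    data.frame(species_code = ref$species_code[i], rank = ref$rank[i],
               value = means[i] * stats::rlnorm(n_rep, -s^2 / 2, s))
  }))
}
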