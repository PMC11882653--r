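# Species-comparison statistics and the habitat-association inference.
#
# Everything here is implemented from first principles (sums of squares,
# studentized-range pairwise tests with an insert-and-absorb compact letter
# display, product-moment correlation, and a proportional-odds ordinal
# regression fitted by maximum likelihood with ordered-increment
# thresholds). Base distribution functions (pf, ptukey, pt, plogis, pnorm)
# supply the reference distributions.

#' Shapiro-Wilk normality screen with transformation ladder
#'
#' Groups with fewer than `min_n` observations are excluded from the screen
#' (too small to test), the Shapiro-Wilk test is run on the pooled
#' within-group residuals, and if normality is rejected at `alpha` the
#' transformations `log` then `sqrt` are tried in that order; the first that
#' passes is kept, otherwise the identity is retained with a warning.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @param alpha Rejection level for the screen.
#' @param min_n Minimum group size to enter the screen.
#' @return List with `transformation` (`"identity"`, `"log"` or `"sqrt"`),
#'   `shapiro_p` (for the chosen transformation), `attempts` (named vector
#'   of p-values tried), `skipped_groups`, and `transform` (the function).
#' @export
normality_screen <- function(values, groups, alpha = 0.05, min_n = 3L) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  n_by <- table(groups)
  small <- names(n_by)[n_by < min_n]
  keep <- !(groups %in% small)
  if (length(small))
    message("normality screen: skipping group(s) with n < ", min_n, ": ",
            paste(small, collapse = ", "))
  v <- values[keep]; g <- groups[keep]
  if (length(v) < 3L) validation_error("normality_screen: fewer than 3 usable values")
  resid_p <- function(x) {
    r <- x - stats::ave(x, g)
    if (stats::sd(r) == 0) return(1)
    stats::shapiro.test(r)$p.value
  }
  attempts <- c(identity = resid_p(v))
  if (attempts[["identity"]] >= alpha)
    return(list(transformation = "identity", shapiro_p = attempts[["identity"]],
                attempts = attempts, skipped_groups = small,
                transform = identity))
  if (all(v > 0)) {
    attempts["log"] <- resid_p(log(v))
    if (attempts[["log"]] >= alpha)
      return(list(transformation = "log", shapiro_p = attempts[["log"]],
                  attempts = attempts, skipped_groups = small, transform = log))
  }
  if (all(v >= 0)) {
    attempts["sqrt"] <- resid_p(sqrt(v))
    if (attempts[["sqrt"]] >= alpha)
      return(list(transformation = "sqrt", shapiro_p = attempts[["sqrt"]],
                  attempts = attempts, skipped_groups = small, transform = sqrt))
  }
  warning("no transformation achieved normality; keeping identity", call. = FALSE)
  list(transformation = "identity", shapiro_p = attempts[["identity"]],
       attempts = attempts, skipped_groups = small, transform = identity)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F = MSB / MSW` with
#' `df = (k - 1, N - k)` and the upper tail of the F distribution. When the
#' within-group variance is exactly zero but group means differ, `F` is
#' `Inf` with `p = 0` (degenerate-data sentinel).
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length; >= 2 groups.
#' @param parameter Optional parameter name carried into the result.
#' @param transformation Label of any transformation already applied.
#' @return List of class `anova_result` with `F`, `df_between`, `df_within`,
#'   `p`, `ssb`, `ssw`, `means`, `n`.
#' @export
one_way_anova <- function(values, groups, parameter = "",
                          transformation = "identity") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2L) validation_error("one_way_anova: need >= 2 groups")
  N <- length(values)
  if (N <= k) validation_error("one_way_anova: no within-group degrees of freedom")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((values - stats::ave(values, groups))^2)
  dfb <- k - 1L; dfw <- N - k
  if (ssw == 0) {
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(parameter = parameter, F = f, df_between = dfb,
                 df_within = dfw, p = p, ssb = ssb, ssw = ssw,
                 means = means, n = n, transformation = transformation),
            class = "anova_result")
}

#' Tukey pairwise tests and compact letter display
#'
#' All pairwise comparisons with the studentized range (Tukey-Kramer for
#' unequal n), adjusted p-values from `ptukey`, and a compact letter display
#' built by insert-and-absorb: starting from one letter covering all groups,
#' each significant pair splits every letter containing both members, and
#' letters that become subsets of others are absorbed. Groups sharing a
#' letter are therefore exactly the pairs not significantly different.
#'
#' @param values,groups As in [one_way_anova()].
#' @param alpha Familywise significance level.
#' @return List of class `tukey_cld` with `pairs` (data.frame: group1,
#'   group2, diff, q, p_adj, significant) and `letters` (named character
#'   vector, groups ordered by increasing mean).
#' @export
tukey_cld <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  a <- one_way_anova(values, groups)
  means <- a$means; n <- a$n
  k <- length(means); dfw <- a$df_within
  msw <- a$ssw / dfw
  gl <- names(sort(means))                 # ascending mean order
  pairs <- utils::combn(gl, 2L)
  pr <- apply(pairs, 2L, function(pp) {
    d <- abs(means[[pp[1L]]] - means[[pp[2L]]])
    se <- sqrt(msw / 2 * (1 / n[[pp[1L]]] + 1 / n[[pp[2L]]]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else d / se
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    c(diff = d, q = q, p_adj = p)
  })
  pair_df <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                        t(pr), stringsAsFactors = FALSE)
  pair_df$significant <- pair_df$p_adj < alpha

  # insert-and-absorb
  sets <- list(gl)
  for (r in which(pair_df$significant)) {
    g1 <- pair_df$group1[r]; g2 <- pair_df$group2[r]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  # letter order: by the lowest-mean member of each set
  first_pos <- vapply(sets, function(s) min(match(s, gl)), numeric(1))
  sets <- sets[order(first_pos)]
  letters_by_group <- vapply(gl, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  structure(list(pairs = pair_df, letters = letters_by_group, alpha = alpha,
                 anova = a),
            class = "tukey_cld")
}

#' Pearson product-moment correlation with t test
#'
#' @param x,y Numeric vectors, length >= 3, finite.
#' @return List with `r`, `t`, `df` (n - 2) and two-sided `p`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) validation_error("pearson_cor: need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    validation_error("pearson_cor: non-finite values")
  sx <- x - mean(x); sy <- y - mean(y)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) validation_error("pearson_cor: zero variance")
  r <- sum(sx * sy) / den
  df <- length(x) - 2L
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Proportional-odds ordinal regression (single predictor)
#'
#' Maximum-likelihood fit of the cumulative-logit model
#' `P(Y <= j | x) = plogis(zeta_j - beta * x)` with a common slope and
#' strictly increasing thresholds (enforced by optimizing `zeta_1` plus log
#' increments). Standard errors come from the inverse observed information
#' (numerical Hessian at the optimum in the natural `(beta, zeta)`
#' parameterization); `t = beta / se`, with a two-sided p-value from the
#' standard normal. Complete or quasi-complete separation is detected as a
#' diverging slope and reported as a non-converged fit with `beta` capped,
#' never as a silent number.
#'
#' @param y Ordinal response: ordered factor or integer codes.
#' @param x Numeric predictor, same length.
#' @param beta_cap Absolute slope (on the standardized-x scale) beyond which
#'   the fit is declared separated.
#' @return List of class `ordinal_fit`: `predictor`, `beta`, `se_beta`, `t`,
#'   `p`, `zeta`, `loglik`, `converged`, `n`, `n_categories`.
#' @export
fit_proportional_odds <- function(y, x, beta_cap = 40) {
  stopifnot(length(y) == length(x))
  if (any(!is.finite(x))) validation_error("fit_proportional_odds: non-finite x")
  yf <- if (is.ordered(y)) droplevels(y) else factor(y, levels = sort(unique(y)))
  j <- as.integer(yf)
  J <- nlevels(yf)
  if (J < 2L) validation_error("fit_proportional_odds: need >= 2 observed categories")
  n <- length(j)
  xs <- stats::sd(x)
  if (xs == 0) validation_error("fit_proportional_odds: constant predictor")
  xc <- (x - mean(x)) / xs                # standardized for optimization

  nll_nat <- function(beta, zeta, xv) {
    z_lo <- c(-Inf, zeta); z_hi <- c(zeta, Inf)
    pr <- stats::plogis(z_hi[j] - beta * xv) - stats::plogis(z_lo[j] - beta * xv)
    pr <- pmax(pr, 1e-300)
    -sum(log(pr))
  }
  # theta = (beta, zeta1, log diff(zeta))
  unpack <- function(theta) {
    zeta <- theta[2L]
    if (J > 2L) zeta <- cumsum(c(theta[2L], exp(theta[3:J])))
    list(beta = theta[1L], zeta = zeta)
  }
  nll <- function(theta) {
    p <- unpack(theta)
    nll_nat(p$beta, p$zeta, xc)
  }
  cum <- cumsum(tabulate(j, J))[-J] / n
  zeta0 <- stats::qlogis(pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n)))
  theta0 <- c(0, zeta0[1L], if (J > 2L) log(pmax(diff(zeta0), 1e-3)))
  fit <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  fit <- stats::optim(fit$par, nll, method = "BFGS",   # polish
                      control = list(maxit = 200, reltol = 1e-14))
  p <- unpack(fit$par)
  # complete separation: category x-ranges perfectly ordered (either way)
  rng <- vapply(seq_len(J), function(k) range(xc[j == k]), numeric(2))
  sep_up <- all(rng[2L, -J] < rng[1L, -1L])    # max of k < min of k+1
  sep_dn <- all(rng[1L, -J] > rng[2L, -1L])    # min of k > max of k+1
  separated <- abs(p$beta) > beta_cap || sep_up || sep_dn
  # observed information in the natural parameterization
  nat <- c(p$beta, p$zeta)
  H <- tryCatch(stats::optimHess(nat, function(th)
    nll_nat(th[1L], th[2:J], xc)), error = function(e) NULL)
  se_std <- NA_real_
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[1L, 1L]) && V[1L, 1L] > 0)
      se_std <- sqrt(V[1L, 1L])
  }
  converged <- fit$convergence == 0 && !separated && is.finite(se_std)
  if (separated) {
    warning("proportional-odds fit: separation detected; estimate unreliable",
            call. = FALSE)
    p$beta <- sign(p$beta) * min(abs(p$beta), beta_cap)
  }
  # back-transform to the original x scale
  beta <- p$beta / xs
  se_beta <- se_std / xs
  zeta <- p$zeta + p$beta * mean(x) / xs
  t <- beta / se_beta
  structure(list(predictor = deparse1(substitute(x)), beta = beta,
                 se_beta = se_beta, t = t,
                 p = 2 * stats::pnorm(-abs(t)), zeta = zeta,
                 loglik = -fit$value, converged = converged,
                 separated = separated, n = n, n_categories = J),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> beta = %.4g (SE %.3g), t = %.3f, p = %.4g%s\n",
              x$beta, x$se_beta, x$t, x$p,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Ordinal habitat-association scan over all core parameters
#'
#' One univariate proportional-odds fit per core parameter, per-sample rows
#' inheriting their species' habitat rank (the published analysis design);
#' results are sorted by decreasing `|t|`.
#'
#' @param core_params data.frame from [extract_core_parameters()] (columns
#'   `species_code` plus the parameter columns).
#' @param ranks Rank table from [habitat_ranks()].
#' @param parameters Parameter columns to scan.
#' @param species_means Collapse to species means before fitting (n = 7
#'   sensitivity mode)?
#' @return List with `table` (data.frame: parameter, beta, se, t, p,
#'   converged) and `fits` (named list of `ordinal_fit`s).
#' @export
habitat_association_scan <- function(core_params, ranks,
                                     parameters = c("max_wc_mm", "min_wc_mm",
                                                    "opt_wc_mm", "lcp", "lsp",
                                                    "max_np", "dr_max", "cge",
                                                    "chl_a"),
                                     species_means = FALSE) {
  miss <- setdiff(unique(core_params$species_code), ranks$species_code)
  if (length(miss))
    validation_error(sprintf("no habitat rank for species: %s",
                             paste(miss, collapse = ", ")))
  df <- core_params
  if (species_means) {
    df <- stats::aggregate(df[parameters],
                           by = list(species_code = df$species_code),
                           FUN = mean, na.rm = TRUE)
  }
  df$rank <- ranks$rank[match(df$species_code, ranks$species_code)]
  fits <- list()
  for (pm in parameters) {
    v <- df[[pm]]
    ok <- is.finite(v)
    if (sum(ok) < 4L || length(unique(df$rank[ok])) < 2L) next
    ft <- fit_proportional_odds(df$rank[ok], v[ok])
    ft$predictor <- pm
    fits[[pm]] <- ft
  }
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(parameter = f$predictor, beta = f$beta, se = f$se_beta,
               t = f$t, p = f$p, converged = f$converged,
               stringsAsFactors = FALSE)))
  tab <- tab[order(-abs(tab$t)), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
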