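#' Specification of the hierarchical CNDD model
#'
#' The seed-to-seedling transition is modelled as a power law
#' `R = a * S^b` with negative-binomial errors.  On the log scale the
#' expected recruit count of species `s` in a plot of cell `c` (edge
#' category x treatment) at station `j` is
#'
#' `log mu = alpha + a_s + g_j + (beta_c + u_s) * (z - zbar)`
#'
#' where `z = log S` is the (latent or fixed) log seed density;
#' `alpha + a_s + g_j` plays the role of `log a` with species and
#' station deviations, and `beta_c + u_s` is the slope `b`.
#' Single-cell fits centre `z` (`zbar` = mean prior log density) and
#' centre the species slopes hierarchically, which greatly improves
#' mixing; multi-cell fits keep `z` uncentred (`zbar = 0`), since a
#' common shift would impose cell-specific intercepts the power law
#' does not have.  `b = 1` means no CNDD; smaller
#' values mean stronger conspecific negative density dependence.
#' Observation law: `R ~ NegBin(mean = mu, size = phi)`.
#'
#' Priors are weakly informative and centred on "no CNDD":
#' `beta_c ~ N(1, 1)`, `alpha ~ N(-1, 1.5)`, all hierarchical SDs
#' (species intercept, station intercept, species slope `tau`)
#' half-Normal(0, 1), `phi ~ Gamma(shape 2, rate 0.2)`.
#'
#' @param chains Number of MCMC chains.
#' @param iter Total iterations per chain (including warmup).
#' @param warmup Iterations discarded as adaptation + burn-in.
#' @param seed Integer RNG seed; identical seeds and settings
#'   reproduce draws exactly.
#' @param cells Cell structure for the slope: `"edge_treatment"`
#'   (default; one `beta` per edge x treatment cell), `"treatment"`,
#'   `"edge"`, or `"single"` (one community-wide slope).
#' @param species_slope `"shared"` (one deviation `u_s` per species
#'   across all cells, the default) or `"by_cell"` (independent
#'   deviations per species and cell).
#' @param priors Named list overriding any of `beta_mean`, `beta_sd`,
#'   `alpha_mean`, `alpha_sd`, `sd_scale`, `phi_shape`, `phi_rate`.
#' @param rhat_threshold Split R-hat above which the fit is flagged
#'   non-converged (default 1.01).
#' @return An object of class `cndd_model_spec`.
#' @export
cndd_model_spec <- function(chains = 4, iter = 2000, warmup = 1000,
                            seed = 1L,
                            cells = c("edge_treatment", "treatment", "edge",
                                      "single"),
                            species_slope = c("shared", "by_cell"),
                            priors = list(),
                            rhat_threshold = 1.01) {
  cells <- match.arg(cells)
  species_slope <- match.arg(species_slope)
  stopifnot(chains >= 1, iter > warmup, warmup >= 2)
  pr <- list(beta_mean = 1, beta_sd = 1, alpha_mean = -1, alpha_sd = 1.5,
             sd_scale = 1, phi_shape = 2, phi_rate = 0.2)
  stopifnot(all(names(priors) %in% names(pr)))
  pr[names(priors)] <- priors
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 cells = cells, species_slope = species_slope, priors = pr,
                 rhat_threshold = rhat_threshold),
            class = "cndd_model_spec")
}

cndd_cell_labels <- function(edge, treatment, cells) {
  switch(cells,
         edge_treatment = paste(edge, treatment_cell(treatment), sep = ":"),
         treatment = treatment_cell(treatment),
         edge = edge,
         single = rep("all", length(edge)))
}

# one observation per retained (station, species) pair per plot at that
# station; zero recruit counts are real observations
build_cndd_obs <- function(data, priors, spec) {
  pl <- data$plots
  edge_of <- stats::setNames(data$stations$edge_category,
                             data$stations$station_id)
  pr <- priors
  pr$pair <- seq_len(nrow(pr))
  obs <- merge(pr[, c("station_id", "species_id", "pair")],
               pl, by = "station_id")
  sl <- data$seedlings
  cnt <- tapply(sl$recruits, paste(sl$plot_id, sl$species_id), sum)
  obs$recruits <- cnt[paste(obs$plot_id, obs$species_id)]
  obs$recruits[is.na(obs$recruits)] <- 0
  obs$edge_category <- unname(edge_of[obs$station_id])
  obs$cell <- cndd_cell_labels(obs$edge_category, obs$treatment, spec$cells)
  obs[order(obs$pair, obs$plot_id), ]
}

cndd_jags_model <- function(naive, by_cell, centered = FALSE, n_cells = 1) {
  z_block <- if (naive) "" else
    "  for (k in 1:K) { z[k] ~ dnorm(mu_z[k], prec_z[k]) }\n"
  zi <- if (naive) "zfix[pair[i]]" else "z[pair[i]]"
  if (centered) {
    # single-cell fits centre the species slopes hierarchically:
    # bsl[s] ~ N(beta, tau^2).  In the non-centred (beta + u) form the
    # species-mean of u is only prior-identified against beta, and
    # single-site samplers can strand a chain far out on that ridge.
    slope <- "bsl[sp[i]]"
    u_block <- paste0(
      "  for (s in 1:S) {\n",
      "    bsl[s] ~ dnorm(beta[1], prec_u)\n",
      "    u[s] <- bsl[s] - beta[1]\n",
      "  }\n")
    delta_term <- ""
    delta_block <- ""
  } else {
    slope <- if (by_cell) "(beta[cell[i]] + u[sp[i], cell[i]])"
             else "(beta[cell[i]] + u[sp[i]])"
    u_block <- if (by_cell)
      "  for (s in 1:S) { for (c in 1:C) { u[s, c] ~ dnorm(0, prec_u) } }\n"
    else
      "  for (s in 1:S) { u[s] ~ dnorm(0, prec_u) }\n"
    # cell main effects on the baseline transition rate (reference cell 1);
    # treatments alter recruitment rates, not only the slope, and with the
    # covariate centred these also absorb the beta_c * zbar offsets
    if (n_cells > 1) {
      delta_term <- "delta[cell[i]] + "
      delta_block <- paste0(
        "  delta[1] <- 0\n",
        "  for (c in 2:C) { delta[c] ~ dnorm(0, pow(alpha_sd, -2)) }\n")
    } else {
      delta_term <- ""
      delta_block <- ""
    }
  }
  paste0(
    "model {\n", z_block,
    "  for (i in 1:N) {\n",
    "    logm[i] <- alpha + ", delta_term, "asp[sp[i]] + gst[st[i]] + ", slope,
    " * (", zi, " - zbar)\n",
    "    pnb[i] <- phi / (phi + exp(logm[i]))\n",
    "    R[i] ~ dnegbin(pnb[i], phi)\n",
    "  }\n",
    "  for (c in 1:C) { beta[c] ~ dnorm(beta_mean, pow(beta_sd, -2)) }\n",
    delta_block, u_block,
    "  for (s in 1:S) { asp[s] ~ dnorm(0, prec_a) }\n",
    "  for (j in 1:J) { gst[j] ~ dnorm(0, prec_g) }\n",
    "  alpha ~ dnorm(alpha_mean, pow(alpha_sd, -2))\n",
    "  sd_sp ~ dnorm(0, pow(sd_scale, -2)) T(0,)\n",
    "  prec_a <- pow(sd_sp, -2)\n",
    "  tau ~ dnorm(0, pow(sd_scale, -2)) T(0,)\n",
    "  prec_u <- pow(tau, -2)\n",
    "  sd_st ~ dnorm(0, pow(sd_scale, -2)) T(0,)\n",
    "  prec_g <- pow(sd_st, -2)\n",
    "  phi ~ dgamma(phi_shape, phi_rate)\n",
    "}\n")
}

run_cndd_jags <- function(obs, priors, spec, naive) {
  cell_levels <- sort(unique(obs$cell))
  sp_levels <- sort(unique(obs$species_id))
  st_levels <- sort(unique(obs$station_id))
  pair_ids <- sort(unique(obs$pair))
  pr <- priors[match(pair_ids, seq_len(nrow(priors))), ]
  zbar <- mean(pr$mu)

  dat <- list(N = nrow(obs), K = length(pair_ids),
              C = length(cell_levels), S = length(sp_levels),
              J = length(st_levels),
              R = as.integer(obs$recruits),
              pair = match(obs$pair, pair_ids),
              sp = match(obs$species_id, sp_levels),
              st = match(obs$station_id, st_levels),
              cell = match(obs$cell, cell_levels),
              zbar = zbar,
              beta_mean = spec$priors$beta_mean,
              beta_sd = spec$priors$beta_sd,
              alpha_mean = spec$priors$alpha_mean,
              alpha_sd = spec$priors$alpha_sd,
              sd_scale = spec$priors$sd_scale,
              phi_shape = spec$priors$phi_shape,
              phi_rate = spec$priors$phi_rate)
  if (naive) {
    dat$zfix <- log(pmax((pr$trap1 + pr$trap2) / 2, 0.5))
  } else {
    dat$mu_z <- pr$mu
    dat$prec_z <- 1 / pr$sigma^2
  }

  by_cell <- spec$species_slope == "by_cell"
  centered <- spec$cells == "single" && !by_cell
  model_txt <- cndd_jags_model(naive, by_cell, centered,
                               n_cells = length(cell_levels))
  inits <- lapply(seq_len(spec$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = spec$seed * 101L + ch,
                beta = rep(spec$priors$beta_mean, dat$C),
                alpha = spec$priors$alpha_mean,
                tau = 0.1, sd_sp = 0.5, sd_st = 0.5, phi = 1)
    if (centered) ini$bsl <- rep(spec$priors$beta_mean, dat$S)
    if (!naive) ini$z <- dat$mu_z
    ini
  })
  n_adapt <- max(100L, spec$warmup %/% 2L)
  n_burn <- spec$warmup - n_adapt
  jm <- rjags::jags.model(textConnection(model_txt), data = dat,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) stats::update(jm, n.iter = n_burn, progress.bar = "none")
  monitors <- c("beta", "alpha", "tau", "phi", "sd_sp", "sd_st", "u")
  if (!centered && length(cell_levels) > 1) monitors <- c(monitors, "delta")
  draws <- rjags::coda.samples(jm, variable.names = monitors,
                               n.iter = spec$iter - spec$warmup,
                               progress.bar = "none")
  list(draws = draws, cell_levels = cell_levels, sp_levels = sp_levels,
       st_levels = st_levels, zbar = zbar)
}

#' Fit the CNDD model with measurement-error correction
#'
#' Samples the joint posterior of the power-law slope per cell, the
#' species and station effects, and the latent log seed densities.
#' The latent density of each (station, species) pair has the
#' moment-matched log-normal prior from the pair of adjacent traps
#' ([latent_seed_priors()]); recruit counts from every plot at the
#' station (including zero counts, and with control and water plots as
#' separate observations sharing the pair's latent density) form the
#' likelihood.
#'
#' @param data An [edge_data()] object.
#' @param species Retained species ids (see [filter_species()]).
#' @param spec A [cndd_model_spec()].
#' @param priors Optional precomputed [latent_seed_priors()] table.
#' @return An object of class `cndd_fit`: `draws` (a
#'   [coda::mcmc.list]), `summary` (per-cell slope table, see
#'   [summarize_cndd()]), `diagnostics` (split R-hat and effective
#'   sample size per monitored parameter, plus a `converged` flag),
#'   `cell_levels`, `spec`, `naive`, and bookkeeping counts.
#' @export
fit_cndd_model <- function(data, species, spec = cndd_model_spec(),
                           priors = NULL) {
  stopifnot(inherits(data, "edge_data"), inherits(spec, "cndd_model_spec"))
  if (is.null(priors)) priors <- latent_seed_priors(data, species)
  obs <- build_cndd_obs(data, priors, spec)
  res <- run_cndd_jags(obs, priors, spec, naive = FALSE)
  finish_cndd_fit(res, obs, priors, spec, naive = FALSE)
}

#' Fit the naive CNDD model without measurement-error correction
#'
#' Identical structure to [fit_cndd_model()] but the log seed density
#' is fixed at the observed trap-pair mean, `log(max(m, 0.5))`, with
#' no latent layer.  Trap-pair counting noise then acts as classical
#' errors-in-variables and attenuates the slope towards zero —
#' mimicking spuriously strong CNDD.  This model exists as the
#' comparison arm for that attenuation property.
#'
#' @inheritParams fit_cndd_model
#' @return A `cndd_fit` with `naive = TRUE`.
#' @export
fit_naive_model <- function(data, species, spec = cndd_model_spec(),
                            priors = NULL) {
  stopifnot(inherits(data, "edge_data"), inherits(spec, "cndd_model_spec"))
  if (is.null(priors)) priors <- latent_seed_priors(data, species)
  obs <- build_cndd_obs(data, priors, spec)
  res <- run_cndd_jags(obs, priors, spec, naive = TRUE)
  finish_cndd_fit(res, obs, priors, spec, naive = TRUE)
}

finish_cndd_fit <- function(res, obs, priors, spec, naive) {
  diag <- cndd_diagnostics(res$draws, spec)
  fit <- structure(list(draws = res$draws, cell_levels = res$cell_levels,
                        species = res$sp_levels, stations = res$st_levels,
                        zbar = res$zbar, spec = spec, naive = naive,
                        diagnostics = diag,
                        n_obs = nrow(obs), n_pairs = length(unique(obs$pair)),
                        n_imputed = sum(priors$provenance ==
                                          "imputed_from_seedlings")),
                   class = "cndd_fit")
  fit$summary <- summarize_cndd(fit)
  fit
}

cndd_diagnostics <- function(draws, spec) {
  mat <- as.matrix(draws)
  keep <- !grepl("^u\\[", colnames(mat))
  params <- colnames(mat)[keep]
  rhat <- vapply(params, function(p) {
    split_rhat(sapply(draws, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- vapply(params, function(p) {
    sum(vapply(draws, function(ch) {
      as.numeric(coda::effectiveSize(ch[, p]))
    }, numeric(1)))
  }, numeric(1))
  converged <- all(is.na(rhat) | rhat <= spec$rhat_threshold)
  if (!converged)
    warning("split R-hat above ", spec$rhat_threshold, " for: ",
            paste(params[!is.na(rhat) & rhat > spec$rhat_threshold],
                  collapse = ", "),
            "; summaries are still reported", call. = FALSE)
  list(table = data.frame(parameter = params, rhat = rhat, ess = ess,
                          row.names = NULL, stringsAsFactors = FALSE),
       converged = converged)
}

# split R-hat: each chain is halved, then the standard potential
# scale-reduction factor is computed across the split chains
split_rhat <- function(chains_mat) {
  chains_mat <- as.matrix(chains_mat)
  n <- nrow(chains_mat)
  half <- n %/% 2
  splits <- do.call(cbind, lapply(seq_len(ncol(chains_mat)), function(j) {
    cbind(chains_mat[seq_len(half), j],
          chains_mat[(n - half + 1):n, j])
  }))
  m <- ncol(splits); len <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Posterior summary of the community-wide slope per cell
#'
#' Recomputes, from the stored draws alone, the posterior mean and
#' central 95% credible interval of the community mean slope
#' `beta_cell`, a CNDD indicator (upper bound below 1), and a
#' description of credible-interval overlap between treatment cells
#' within each edge category.
#'
#' @param fit A `cndd_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame: `cell`, `mean_b`, `ci_low`, `ci_high`,
#'   `cndd_flag`, with attribute `"overlap"` holding the pairwise
#'   within-edge overlap table when the cell structure includes both
#'   edge and treatment.
#' @export
summarize_cndd <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "cndd_fit"))
  a <- (1 - prob) / 2
  mat <- as.matrix(fit$draws)
  idx <- grep("^beta\\[", colnames(mat))
  if (!length(idx)) idx <- which(colnames(mat) == "beta")
  bm <- mat[, idx, drop = FALSE]
  out <- data.frame(cell = fit$cell_levels,
                    mean_b = colMeans(bm),
                    ci_low = apply(bm, 2, stats::quantile, a),
                    ci_high = apply(bm, 2, stats::quantile, 1 - a),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$cndd_flag <- out$ci_high < 1

  if (fit$spec$cells == "edge_treatment") {
    parts <- strsplit(out$cell, ":", fixed = TRUE)
    out$edge <- vapply(parts, `[`, character(1), 1)
    out$treatment <- vapply(parts, `[`, character(1), 2)
    ov <- do.call(rbind, lapply(split(out, out$edge), function(g) {
      if (nrow(g) < 2) return(NULL)
      cmb <- utils::combn(seq_len(nrow(g)), 2)
      data.frame(edge = g$edge[1],
                 cell_a = g$cell[cmb[1, ]], cell_b = g$cell[cmb[2, ]],
                 overlap = pmin(g$ci_high[cmb[1, ]], g$ci_high[cmb[2, ]]) >=
                           pmax(g$ci_low[cmb[1, ]], g$ci_low[cmb[2, ]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(ov) <- NULL
    attr(out, "overlap") <- ov
  }
  out
}

#' @export
print.cndd_fit <- function(x, ...) {
  cat("Hierarchical CNDD fit (",
      if (x$naive) "naive, no" else "with", " measurement-error correction)\n",
      sep = "")
  cat(x$n_obs, "observations;", x$n_pairs, "station x species pairs (",
      x$n_imputed, "imputed );", length(x$species), "species\n")
  cat("Converged:", x$diagnostics$converged, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export posterior draws in long format
#'
#' @param fit A `cndd_fit`.
#' @return Data frame `parameter`, `chain`, `iteration`, `value`.
#' @export
cndd_draws_long <- function(fit) {
  stopifnot(inherits(fit, "cndd_fit"))
  do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               value = as.numeric(m), stringsAsFactors = FALSE)
  }))
}
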