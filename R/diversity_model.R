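#' Mixed-model contrasts of recruit diversity across edge and treatment
#'
#' Fits a Gaussian linear mixed model of seedling diversity against the
#' edge-distance x treatment interaction, with the station's seed
#' diversity (same index) as an additive covariate and a random
#' intercept per station:
#' `value ~ edge_category * treatment + seed_diversity + (1 | station_id)`.
#' Control and water plots are pooled to a single Control value per
#' station beforehand (see [pool_controls()]).  Pairwise treatment
#' contrasts within each edge category use Wald z tests, optionally
#' with Tukey familywise adjustment, and are summarised as a compact
#' letter display.
#'
#' Plots with undefined diversity (no recruits, or fewer individuals
#' than the rarefaction size) are dropped with a logged count — a zero
#' is a statement about abundance, not diversity.  A singular random
#' effect triggers a warning and a fixed-intercept (plain linear
#' model) fallback.
#'
#' @param dtable A [diversity_table()] (both seed and seedling rows).
#' @param index Which index to model.
#' @param correction `"tukey"` (default) or `"none"` for the pairwise
#'   contrasts.
#' @param alpha Significance level for the letter display.
#' @return An object of class `diversity_fit`: list with `model`,
#'   `cell_means` (emmeans per edge x treatment), `contrasts`
#'   (pairwise within edge: estimate, z, p), `letters`,
#'   `seed_coef` (estimate, SE, z, p for the seed-diversity
#'   covariate), `n_dropped`, `singular`.
#' @export
fit_diversity_model <- function(dtable,
                                index = "inverse_simpson",
                                correction = c("tukey", "none"),
                                alpha = 0.05) {
  correction <- match.arg(correction)
  index <- match.arg(index, diversity_index_names())
  dat <- assemble_model_frame(dtable, index)
  fit_cell_model(dat, value ~ edge_category * treatment + seed_diversity +
                   (1 | station_id),
                 by = "edge_category", correction = correction, alpha = alpha,
                 index = index)
}

#' Diversity against canopy light x treatment
#'
#' Same contract as [fit_diversity_model()] with the edge category
#' replaced by a continuous per-plot canopy-openness covariate
#' interacting with treatment.  Control/water plots are kept separate
#' (they carry different light readings) but share the Control cell
#' label.  Rows without a light value are dropped with a logged count;
#' a light covariate without variance is inestimable and reported as
#' `NA` with a warning; near-collinear fixed effects trigger a
#' condition-number warning.
#'
#' @param dtable A [diversity_table()].
#' @param light Data frame with `plot_id` and `light` (e.g. percent
#'   canopy openness).
#' @inheritParams fit_diversity_model
#' @return A `diversity_fit` with `light_coef` in place of cell
#'   contrasts by edge (contrasts are between treatments at the mean
#'   light level).
#' @export
fit_light_model <- function(dtable, light, index = "inverse_simpson",
                            correction = c("tukey", "none"), alpha = 0.05) {
  correction <- match.arg(correction)
  index <- match.arg(index, diversity_index_names())
  stopifnot(all(c("plot_id", "light") %in% names(light)))

  d <- dtable[dtable$unit_kind == "seedling" & dtable$index == index, ]
  d$light <- light$light[match(d$unit_id, light$plot_id)]
  n_nolight <- sum(is.na(d$light))
  if (n_nolight)
    message("fit_light_model: dropping ", n_nolight, " plot(s) without ",
            "a light value")
  d <- d[!is.na(d$light), , drop = FALSE]
  d$treatment <- treatment_cell(d$treatment)
  seed <- dtable[dtable$unit_kind == "seed" & dtable$index == index, ]
  d$seed_diversity <- seed$value[match(d$station_id, seed$unit_id)]
  names(d)[names(d) == "unit_id"] <- "plot_id"
  d <- d[, c("plot_id", "station_id", "edge_category", "treatment", "light",
             "seed_diversity", "value")]

  if (stats::var(d$light) == 0) {
    warning("light covariate is constant; its coefficient is inestimable")
    return(structure(list(model = NULL, light_coef = c(estimate = NA_real_,
                                                       se = NA_real_,
                                                       z = NA_real_,
                                                       p = NA_real_),
                          cell_means = NULL, contrasts = NULL, letters = NULL,
                          n_dropped = n_nolight, singular = NA, index = index),
                     class = "diversity_fit"))
  }
  # near-collinearity with the (implicit) edge structure shows up as an
  # ill-conditioned fixed-effects design
  mm <- stats::model.matrix(~ light * treatment + seed_diversity,
                            data = stats::na.omit(d))
  kp <- kappa(mm, exact = TRUE)
  if (kp > 1e7)
    warning("fixed-effects design is near-singular (condition number ",
            format(kp, digits = 3), ")")

  fit <- fit_cell_model(d, value ~ light * treatment + seed_diversity +
                          (1 | station_id),
                        by = NULL, correction = correction, alpha = alpha,
                        index = index, extra_dropped = n_nolight)
  co <- extract_fixed(fit$model)
  fit$light_coef <- co["light", ]
  fit
}

# ---- internals -------------------------------------------------------------

assemble_model_frame <- function(dtable, index) {
  pooled <- pool_controls(dtable[dtable$index == index, , drop = FALSE])
  seed <- dtable[dtable$unit_kind == "seed" & dtable$index == index, ]
  pooled$seed_diversity <- seed$value[match(pooled$station_id, seed$unit_id)]
  pooled
}

fit_cell_model <- function(dat, formula, by, correction, alpha, index,
                           extra_dropped = 0) {
  ok <- !is.na(dat$value) & !is.na(dat$seed_diversity)
  n_dropped <- sum(!ok) + extra_dropped
  d <- dat[ok, , drop = FALSE]
  if (!is.null(by)) d[[by]] <- factor(d[[by]])
  d$treatment <- factor(d$treatment)
  if (nrow(d) < 4) stop("too few usable diversity values to fit a model")

  singular <- FALSE
  model <- tryCatch({
    m <- suppressMessages(lme4::lmer(formula, data = d, REML = TRUE))
    if (lme4::isSingular(m)) {
      singular <- TRUE
      warning("station random intercept is singular; ",
              "falling back to a fixed-intercept model")
      stats::lm(strip_ranef(formula), data = d)
    } else m
  }, error = function(e) {
    warning("mixed model failed (", conditionMessage(e),
            "); falling back to a fixed-intercept model")
    singular <<- TRUE
    stats::lm(strip_ranef(formula), data = d)
  })

  spec <- if (is.null(by)) "~ treatment" else paste("~ treatment |", by)
  emm <- emmeans::emmeans(model, stats::as.formula(spec),
                          lmer.df = "asymptotic")
  cell_means <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = correction))
  pcol <- names(prs)[grepl("p\\.value", names(prs))][1]
  prs$p <- ifelse(is.finite(prs[[pcol]]), prs[[pcol]], 1)
  prs$z <- ifelse(is.finite(prs$estimate / prs$SE), prs$estimate / prs$SE, 0)
  # numerically-zero differences (degenerate responses) are never significant
  zero <- abs(prs$estimate) < 1e-8 * max(1, mean(abs(d$value)))
  prs$p[zero] <- 1
  prs$z[zero] <- 0
  letters <- letters_from_contrasts(cell_means, prs, by = by, alpha = alpha)

  sc <- tryCatch(extract_fixed(model)["seed_diversity", ],
                 error = function(e) c(estimate = NA, se = NA, z = NA, p = NA))
  structure(list(model = model, cell_means = cell_means, contrasts = prs,
                 letters = letters, seed_coef = sc, n_dropped = n_dropped,
                 singular = singular, correction = correction, index = index),
            class = "diversity_fit")
}

strip_ranef <- function(formula) {
  rhs <- deparse(formula[[3]])
  rhs <- gsub("\\+\\s*\\(1\\s*\\|[^)]*\\)", "", rhs)
  stats::as.formula(paste(deparse(formula[[2]]), "~", rhs))
}

extract_fixed <- function(model) {
  if (inherits(model, "merMod")) {
    co <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
  } else {
    sm <- summary(model)$coefficients
    co <- sm[, 1]
    se <- sm[, 2]
  }
  z <- co / se
  out <- cbind(estimate = co, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  out
}

letters_from_contrasts <- function(cell_means, prs, by, alpha) {
  groups <- if (is.null(by)) list(all = prs) else split(prs, prs[[by]])
  out <- lapply(names(groups), function(g) {
    pr <- groups[[g]]
    cm <- if (is.null(by)) cell_means else cell_means[cell_means[[by]] == g, ]
    lv <- as.character(cm$treatment[order(cm$emmean, decreasing = TRUE)])
    sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
    for (i in seq_len(nrow(pr))) {
      ab <- strsplit(as.character(pr$contrast[i]), " - ", fixed = TRUE)[[1]]
      ab <- gsub("^\\(|\\)$", "", ab)
      if (all(ab %in% lv) && pr$p[i] < alpha)
        sig[ab[1], ab[2]] <- sig[ab[2], ab[1]] <- TRUE
    }
    data.frame(group = g, treatment = lv,
               letters = insert_absorb_letters(sig),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# compact-letter display by the insert-and-absorb algorithm on a logical
# "significantly different" matrix whose rows are ordered by decreasing mean
insert_absorb_letters <- function(sig) {
  n <- nrow(sig)
  items <- rownames(sig)
  grps <- list(rep(TRUE, n))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (!sig[i, j]) next
    for (gi in seq_along(grps)) {
      g <- grps[[gi]]
      if (g[i] && g[j]) {
        g1 <- g; g1[i] <- FALSE
        g2 <- g; g2[j] <- FALSE
        grps[[gi]] <- g1
        grps[[length(grps) + 1]] <- g2
      }
    }
    # absorb groups that are subsets of another
    keep <- rep(TRUE, length(grps))
    for (aa in seq_along(grps)) for (bb in seq_along(grps)) {
      if (aa != bb && keep[aa] && keep[bb] &&
          all(grps[[aa]] | !grps[[bb]]) && !identical(grps[[aa]], grps[[bb]]))
        keep[bb] <- FALSE
    }
    dup <- duplicated(grps)
    grps <- grps[keep & !dup]
  }
  ord <- order(vapply(grps, function(g) which(g)[1], integer(1)))
  grps <- grps[ord]
  lab <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(grps, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(lab, items)
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Diversity model (", x$index, ")",
      if (isTRUE(x$singular)) " [fixed-intercept fallback]", "\n", sep = "")
  cat("Dropped units:", x$n_dropped, "\n")
  if (!is.null(x$seed_coef) && !all(is.na(x$seed_coef)))
    cat("Seed-diversity coefficient:",
        sprintf("%.3f (z = %.2f, p = %.3g)", x$seed_coef["estimate"],
                x$seed_coef["z"], x$seed_coef["p"]), "\n")
  if (!is.null(x$letters)) {
    cat("Letters (", x$correction, " adjustment):\n", sep = "")
    print(x$letters, row.names = FALSE)
  }
  invisible(x)
}
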