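# Cross-species skew modelling: linear mixed-effects models of T_skew on the
# thermal optimum and habitat associations with nested taxonomic random
# intercepts, AICc / likelihood-ratio model comparison, and the
# tropical-vs-temperate slope contrast.

# Small-sample corrected AIC.
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the skew mixed-effects model for one guild
#'
#' `tskew ~ topt + coral_assoc + macroalgae_assoc` with a nested random
#' intercept of order / family / genus (when `include_random`), by REML for
#' coefficient reporting or ML for likelihood-ratio comparison. Species with
#' missing covariates are dropped. A singular random-effects fit is refit
#' with the innermost taxonomic level removed (repeatedly if needed) and
#' flagged.
#'
#' @param profiles Thermal-profiles data.frame with columns `tskew`, `topt`,
#'   `coral_assoc`, `macroalgae_assoc`, `guild`, `order`, `family`, `genus`.
#' @param guild `"tropical"`, `"temperate"` or `"all"`.
#' @param include_random Include the nested taxonomic random intercepts.
#' @param method `"REML"` (reporting) or `"ML"` (model comparison).
#' @return An object of class `skew_model_fit`: `fixed_effects` (estimate,
#'   SE, z, p per coefficient), `random_intercept_variances`, `loglik`, `k`,
#'   `n_species`, `aicc`, `terms`, `method`, `singular_dropped`, `model`.
#' @export
fit_skew_lmm <- function(profiles, guild = c("all", "tropical", "temperate"),
                         include_random = TRUE,
                         method = c("REML", "ML")) {
  guild <- match.arg(guild)
  method <- match.arg(method)
  d <- profiles
  if (guild != "all") d <- d[d$guild == guild, , drop = FALSE]
  vars <- c("tskew", "topt", "coral_assoc", "macroalgae_assoc")
  ok <- stats::complete.cases(d[, vars])
  if (any(!ok)) {
    message(sum(!ok), " species dropped for missing covariates")
    d <- d[ok, , drop = FALSE]
  }
  if (nrow(d) < 10) stop("need at least 10 species in the guild")
  fixed <- tskew ~ topt + coral_assoc + macroalgae_assoc
  dropped <- character(0)
  if (include_random && !all(c("order", "family", "genus") %in% names(d))) {
    message("no taxonomy columns (order/family/genus); ",
            "fitting without random intercepts")
    include_random <- FALSE
  }
  if (include_random) {
    re_levels <- c("order", "family", "genus")
    model <- NULL
    repeat {
      re <- paste0("(1 | ", paste(re_levels, collapse = "/"), ")")
      form <- stats::as.formula(paste("tskew ~ topt + coral_assoc +",
                                      "macroalgae_assoc +", re))
      model <- suppressMessages(
        lme4::lmer(form, data = d, REML = method == "REML",
                   control = lme4::lmerControl(calc.derivs = FALSE))
      )
      if (!lme4::isSingular(model, tol = 1e-5) || length(re_levels) == 1) {
        break
      }
      # drop the taxonomic level whose estimated variance collapsed
      vc <- as.data.frame(lme4::VarCorr(model))
      vc <- vc[vc$grp != "Residual", , drop = FALSE]
      worst <- vc$grp[which.min(vc$vcov)]
      # grouping labels look like "genus:(family:order)" etc.
      lvl <- re_levels[vapply(re_levels, function(l) {
        startsWith(as.character(worst), l) ||
          grepl(paste0("^", l, "[.:]"), worst)
      }, logical(1))][1]
      if (is.na(lvl)) lvl <- re_levels[length(re_levels)]
      dropped <- c(dropped, lvl)
      re_levels <- setdiff(re_levels, lvl)
    }
    co <- summary(model)$coefficients
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(model))
    rv <- stats::setNames(vc$vcov, vc$grp)
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
  } else {
    model <- stats::lm(fixed, data = d)
    co <- summary(model)$coefficients
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], row.names = NULL)
    rv <- numeric(0)
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
  }
  fe$z <- fe$estimate / fe$se
  fe$p <- 2 * stats::pnorm(-abs(fe$z))
  n <- nrow(d)
  structure(list(
    fixed_effects = fe,
    random_intercept_variances = rv,
    loglik = ll, k = k, n_species = n,
    aicc = aicc(ll, k, n),
    terms = attr(stats::terms(fixed), "term.labels"),
    include_random = include_random,
    method = method,
    guild = guild,
    singular_dropped = dropped,
    model = model
  ), class = "skew_model_fit")
}

#' @export
print.skew_model_fit <- function(x, ...) {
  cat("Skew model (", x$guild, "guild,",
      if (x$include_random) "taxonomic random intercepts," else "no random effects,",
      x$method, ")\n")
  cat("  n =", x$n_species, " logLik =", format(x$loglik, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  print(x$fixed_effects, digits = 4)
  if (length(x$singular_dropped)) {
    cat("  singular fit: dropped random levels",
        paste(x$singular_dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare skew models by AICc and likelihood-ratio tests
#'
#' Produces an AICc ranking of the supplied fits and likelihood-ratio tests
#' for every nested pair (nesting judged by fixed-effect terms and random
#' structure). LRTs require ML fits on identical data; requesting an LRT
#' between non-nested models is an error.
#'
#' @param fits List of `skew_model_fit` objects on the same data.
#' @param lrt Also compute likelihood-ratio tests for nested pairs.
#' @return List with `aicc_table` (sorted) and `lrt_table`.
#' @export
compare_models <- function(fits, lrt = TRUE) {
  if (!all(vapply(fits, inherits, TRUE, "skew_model_fit"))) {
    stop("all elements must be skew_model_fit objects")
  }
  n <- vapply(fits, function(f) f$n_species, 0)
  if (length(unique(n)) != 1) stop("fits must be on identical data")
  labs <- names(fits)
  if (is.null(labs)) labs <- paste0("model", seq_along(fits))
  tab <- data.frame(
    model = labs,
    k = vapply(fits, function(f) f$k, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aicc = vapply(fits, function(f) f$aicc, 0)
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  lrt_tab <- NULL
  if (lrt && length(fits) > 1) {
    rows <- list()
    for (i in seq_along(fits)) {
      for (j in seq_along(fits)) {
        if (i == j) next
        fi <- fits[[i]]; fj <- fits[[j]]
        nested <- all(fi$terms %in% fj$terms) && fi$k < fj$k &&
          (!fi$include_random || fj$include_random)
        if (!nested) next
        if (fi$method != "ML" || fj$method != "ML") {
          stop("likelihood-ratio tests require ML fits")
        }
        stat <- 2 * (fj$loglik - fi$loglik)
        df <- fj$k - fi$k
        rows[[length(rows) + 1]] <- data.frame(
          reduced = labs[i], full = labs[j], statistic = stat, df = df,
          p = stats::pchisq(max(0, stat), df, lower.tail = FALSE)
        )
      }
    }
    if (length(rows)) lrt_tab <- do.call(rbind, rows)
  }
  list(aicc_table = tab, lrt_table = lrt_tab)
}

# Pull an estimate/SE pair for `term` out of a skew_model_fit, or accept a
# bare numeric c(estimate, se).
coef_se <- function(fit, term) {
  if (inherits(fit, "skew_model_fit")) {
    row <- fit$fixed_effects[fit$fixed_effects$term == term, ]
    if (nrow(row) != 1) stop("term not found in fit: ", term)
    c(row$estimate, row$se)
  } else if (is.numeric(fit) && length(fit) == 2) {
    fit
  } else {
    stop("supply a skew_model_fit or c(estimate, se)")
  }
}

#' Compare a fixed-effect slope between two guilds
#'
#' Two-sample Wald contrast `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a
#' two-sided normal p-value.
#'
#' @param fit_tropical,fit_temperate `skew_model_fit` objects sharing a
#'   fixed-effect specification, or bare `c(estimate, se)` pairs.
#' @param term Fixed-effect term to contrast.
#' @return List with `z` and `p`.
#' @export
slope_difference_test <- function(fit_tropical, fit_temperate,
                                  term = "topt") {
  a <- coef_se(fit_tropical, term)
  b <- coef_se(fit_temperate, term)
  z <- (a[1] - b[1]) / sqrt(a[2]^2 + b[2]^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
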