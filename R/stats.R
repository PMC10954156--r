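# Statistical comparison of modeling choices: two-way ANOVA with
# interaction, simple-main-effects follow-up with Bonferroni correction,
# pairwise Tukey tests, and the branching decision pipeline that ties them
# together.
#
# Balanced tables use classical sums of squares (sequential and marginal SS
# coincide); unbalanced tables (e.g. failed runs removed) fall back to
# Type-II SS with a warning.

prep_factors <- function(data, response, a, b) {
  y <- dplyr::pull(data, {{ response }})
  fa <- factor(dplyr::pull(data, {{ a }}))
  fb <- factor(dplyr::pull(data, {{ b }}))
  keep <- !is.na(y)
  if (!all(keep)) {
    warning(sum(!keep), " rows with missing response removed (failed runs)",
            call. = FALSE)
  }
  d <- data.frame(y = y[keep], A = fa[keep], B = fb[keep])
  tab <- table(d$A, d$B)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cell: ", paste(rownames(tab)[bad[, 1]],
                                      colnames(tab)[bad[, 2]],
                                      sep = ":", collapse = ", "),
         call. = FALSE)
  }
  attr(d, "balanced") <- length(unique(as.vector(tab))) == 1L
  attr(d, "names_ab") <- c(rlang::as_name(rlang::enquo(a)),
                           rlang::as_name(rlang::enquo(b)))
  d
}

anova_tidy <- function(fit, name_a, name_b) {
  s <- summary(fit)[[1]]
  out <- tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
    statistic = s$`F value`, p.value = s$`Pr(>F)`)
  # a term with zero between-group variation carries no evidence: F = 0
  degen <- is.nan(out$statistic) & out$sumsq == 0
  degen[is.na(degen)] <- FALSE
  out$statistic[degen] <- 0
  out$p.value[degen] <- 1
  out$term <- sub("^A$", name_a, out$term)
  out$term <- sub("^B$", name_b, out$term)
  out$term <- sub("^A:B$", paste0(name_a, ":", name_b), out$term)
  out
}

#' Two-way analysis of variance
#'
#' Classical two-way ANOVA of a metric against two design factors, with or
#' without the interaction term. Balanced tables use classical sums of
#' squares; unbalanced tables use Type-II sums of squares with a warning.
#' Tables with an empty factor cell are refused with a diagnostic naming the
#' missing condition.
#'
#' @param data A data frame with one row per replicate.
#' @param response,factor_a,factor_b Unquoted column names of the metric and
#'   the two factors.
#' @param interaction Include the A:B interaction term.
#' @return A tibble with one row per term: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (the Residuals row carries the error SS).
#' @export
anova_two_way <- function(data, response, factor_a, factor_b,
                          interaction = TRUE) {
  d <- prep_factors(data, {{ response }}, {{ factor_a }}, {{ factor_b }})
  nm <- attr(d, "names_ab")
  if (interaction && any(table(d$A, d$B) < 2)) {
    stop("ANOVA with interaction needs >= 2 replicates per cell",
         call. = FALSE)
  }
  form <- if (interaction) y ~ A * B else y ~ A + B
  if (stats::var(d$y) == 0) {
    # a constant response has zero variation at every level: all F = 0
    terms <- c(nm[1], nm[2],
               if (interaction) paste0(nm[1], ":", nm[2]), "Residuals")
    dfs <- c(nlevels(d$A) - 1L, nlevels(d$B) - 1L,
             if (interaction) (nlevels(d$A) - 1L) * (nlevels(d$B) - 1L))
    dfs <- c(dfs, nrow(d) - 1L - sum(dfs))
    return(tibble::tibble(term = terms, df = dfs, sumsq = 0, meansq = 0,
                          statistic = c(rep(0, length(terms) - 1L), NA),
                          p.value = c(rep(1, length(terms) - 1L), NA)))
  }
  if (attr(d, "balanced") || !interaction) {
    fit <- stats::aov(form, data = d)
    out <- anova_tidy(fit, nm[1], nm[2])
  } else {
    warning("unbalanced design: using Type-II sums of squares",
            call. = FALSE)
    if (!requireNamespace("car", quietly = TRUE)) {
      stop("package 'car' is required for unbalanced (Type-II) ANOVA",
           call. = FALSE)
    }
    fit <- stats::lm(form, data = d)
    a2 <- car::Anova(fit, type = 2)
    out <- tibble::tibble(
      term = trimws(rownames(a2)),
      df = a2$Df, sumsq = a2$`Sum Sq`, meansq = a2$`Sum Sq` / a2$Df,
      statistic = a2$`F value`, p.value = a2$`Pr(>F)`)
    out$term <- sub("^A$", nm[1], out$term)
    out$term <- sub("^B$", nm[2], out$term)
    out$term <- sub("^A:B$", paste0(nm[1], ":", nm[2]), out$term)
  }
  out
}

#' Simple main effects after a significant interaction
#'
#' One-way ANOVA of each factor within each level of the other factor, with
#' a Bonferroni correction whose divisor is the number of levels of the
#' conditioning factor. The procedure is gated: it refuses to run when the
#' two-way interaction is not significant at `alpha` (set `gate = FALSE`
#' only to inspect the tests regardless).
#'
#' @inheritParams anova_two_way
#' @param alpha Significance level (0.05 with Bonferroni correction).
#' @param gate Enforce the significant-interaction precondition.
#' @return A tibble with one row per (tested factor, conditioning level):
#'   `factor`, `within`, `level`, `df1`, `df2`, `statistic`, `p.value`,
#'   `p.adjusted` (Bonferroni), `significant`.
#' @export
simple_main_effects <- function(data, response, factor_a, factor_b,
                                alpha = 0.05, gate = TRUE) {
  d <- prep_factors(data, {{ response }}, {{ factor_a }}, {{ factor_b }})
  nm <- attr(d, "names_ab")
  if (gate) {
    int <- anova_two_way(data, {{ response }}, {{ factor_a }},
                         {{ factor_b }}, interaction = TRUE)
    p_int <- int$p.value[grepl(":", int$term)]
    if (!is.na(p_int) && p_int >= alpha) {
      stop(sprintf(paste0("interaction not significant (p = %.3f >= %.2f); ",
                          "simple main effects are not applicable"),
                   p_int, alpha), call. = FALSE)
    }
  }
  one <- function(test_col, cond_col, test_name, cond_name) {
    divisor <- nlevels(d[[cond_col]])
    purrr::map_dfr(levels(d[[cond_col]]), function(lv) {
      dd <- d[d[[cond_col]] == lv, ]
      s <- summary(stats::aov(y ~ f, data = data.frame(y = dd$y,
                                                       f = dd[[test_col]])))[[1]]
      tibble::tibble(factor = test_name, within = cond_name, level = lv,
                     df1 = s$Df[1], df2 = s$Df[2],
                     statistic = s$`F value`[1], p.value = s$`Pr(>F)`[1],
                     p.adjusted = pmin(1, s$`Pr(>F)`[1] * divisor),
                     significant = s$`Pr(>F)`[1] < alpha / divisor)
    })
  }
  dplyr::bind_rows(one("A", "B", nm[1], nm[2]),
                   one("B", "A", nm[2], nm[1]))
}

#' Pairwise Tukey comparisons
#'
#' All k(k-1)/2 pairwise comparisons of a factor's levels via the
#' studentized-range (Tukey HSD) procedure, either within each level of a
#' conditioning factor (after a significant interaction) or on the full
#' data set (after a non-significant interaction). Requires more than two
#' levels.
#'
#' @param data A data frame with one row per replicate.
#' @param response,factor Unquoted columns of the metric and the factor
#'   whose levels are compared.
#' @param within Optional unquoted conditioning factor; comparisons run
#'   separately at each of its levels.
#' @param alpha Family-wise significance level (0.01).
#' @return A tibble with columns `within` (or `"(all)"`), `contrast`,
#'   `estimate`, `conf.low`, `conf.high`, `adj.p.value`, `significant`.
#' @export
tukey_pairwise <- function(data, response, factor, within = NULL,
                           alpha = 0.01) {
  y <- dplyr::pull(data, {{ response }})
  f <- as.factor(dplyr::pull(data, {{ factor }}))
  keep <- !is.na(y)
  y <- y[keep]; f <- droplevels(f[keep])
  if (nlevels(f) <= 2L) {
    stop("pairwise Tukey tests need a factor with more than 2 levels",
         call. = FALSE)
  }
  wq <- rlang::enquo(within)
  groups <- if (rlang::quo_is_null(wq)) {
    list(`(all)` = rep(TRUE, length(y)))
  } else {
    w <- as.factor(dplyr::pull(data, {{ within }}))[keep]
    stats::setNames(lapply(levels(w), function(lv) w == lv), levels(w))
  }
  purrr::imap_dfr(groups, function(sel, gname) {
    fit <- stats::aov(y ~ f, data = data.frame(y = y[sel],
                                               f = droplevels(f[sel])))
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
    tibble::tibble(within = gname, contrast = rownames(tk),
                   estimate = unname(tk[, "diff"]),
                   conf.low = unname(tk[, "lwr"]),
                   conf.high = unname(tk[, "upr"]),
                   adj.p.value = unname(tk[, "p adj"]),
                   significant = unname(tk[, "p adj"] < alpha))
  })
}

#' The ANOVA decision pipeline for design-choice comparisons
#'
#' Implements the full branching analysis: a two-way ANOVA with interaction
#' at `alpha_anova`; if the interaction is significant, simple main effects
#' (Bonferroni-corrected) and pairwise Tukey tests within levels of the
#' other factor (`alpha_tukey`); if not, the two-way ANOVA is refit without
#' the interaction term and significant factors with more than two levels
#' receive full-data Tukey tests. Also emits interval-plot-ready level
#' means with standard deviations.
#'
#' @inheritParams anova_two_way
#' @param alpha_anova ANOVA significance level (0.05).
#' @param alpha_tukey Tukey significance level (0.01).
#' @return An object of class `design_anova`: a list with `branch`
#'   (`"interaction"` or `"additive"`), `anova`, `simple_effects`, `tukey`,
#'   and `means`. Has [tidy()], [glance()], and [ggplot2::autoplot()]
#'   methods.
#' @export
decision_pipeline <- function(data, response, factor_a, factor_b,
                              alpha_anova = 0.05, alpha_tukey = 0.01) {
  nm_a <- rlang::as_name(rlang::ensym(factor_a))
  nm_b <- rlang::as_name(rlang::ensym(factor_b))
  nm_y <- rlang::as_name(rlang::ensym(response))
  full <- anova_two_way(data, !!nm_y, !!nm_a, !!nm_b, interaction = TRUE)
  p_int <- full$p.value[grepl(":", full$term)]
  level_means <- function(nm) {
    d <- tibble::tibble(level = as.character(data[[nm]]),
                        y = data[[nm_y]])
    out <- dplyr::summarise(dplyr::group_by(d, .data$level),
                            mean = mean(.data$y, na.rm = TRUE),
                            sd = stats::sd(.data$y, na.rm = TRUE),
                            n = dplyr::n(), .groups = "drop")
    dplyr::mutate(out, factor = nm, .before = 1)
  }
  means <- dplyr::bind_rows(level_means(nm_a), level_means(nm_b))

  tukey_for <- function(fac_name, within_name) {
    if (nlevels(factor(data[[fac_name]])) <= 2L) return(NULL)
    out <- if (is.null(within_name)) {
      tukey_pairwise(data, !!nm_y, !!fac_name, alpha = alpha_tukey)
    } else {
      tukey_pairwise(data, !!nm_y, !!fac_name, within = !!within_name,
                     alpha = alpha_tukey)
    }
    dplyr::mutate(out, factor = fac_name, .before = 1)
  }

  if (!is.na(p_int) && p_int < alpha_anova) {
    branch <- "interaction"
    sme <- simple_main_effects(data, !!nm_y, !!nm_a, !!nm_b,
                               alpha = alpha_anova)
    tk <- dplyr::bind_rows(tukey_for(nm_a, nm_b), tukey_for(nm_b, nm_a))
    final <- full
  } else {
    branch <- "additive"
    sme <- NULL
    final <- anova_two_way(data, !!nm_y, !!nm_a, !!nm_b, interaction = FALSE)
    sig <- final$term[!is.na(final$p.value) & final$p.value < alpha_anova]
    tk <- dplyr::bind_rows(
      if (nm_a %in% sig) tukey_for(nm_a, NULL),
      if (nm_b %in% sig) tukey_for(nm_b, NULL))
  }
  structure(list(branch = branch, interaction_p = unname(p_int),
                 anova_full = full, anova = final,
                 simple_effects = sme,
                 tukey = if (nrow(tk) > 0) tk else NULL,
                 means = means,
                 factors = c(nm_a, nm_b),
                 alpha_anova = alpha_anova, alpha_tukey = alpha_tukey),
            class = "design_anova")
}

#' @export
print.design_anova <- function(x, ...) {
  cat(sprintf("<design_anova> %s x %s; branch: %s (interaction p = %.4g)\n",
              x$factors[1], x$factors[2], x$branch, x$interaction_p))
  print(x$anova)
  invisible(x)
}

#' @rdname decision_pipeline
#' @param x A `design_anova` object.
#' @param ... Unused.
#' @export
tidy.design_anova <- function(x, ...) x$anova

#' @rdname decision_pipeline
#' @export
glance.design_anova <- function(x, ...) {
  tibble::tibble(branch = x$branch, interaction_p = x$interaction_p,
                 alpha_anova = x$alpha_anova, alpha_tukey = x$alpha_tukey)
}
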