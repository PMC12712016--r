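#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation between two case-level statistics, with the
#' two-sided p-value from the t distribution on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return list of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_value("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_value("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_value("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.3f, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegating to [stats::p.adjust()] after validating the input range).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_value("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial rate-ratio regression between region groups
#'
#' Compares callosal labeling rates between groups of injection cases by
#' regressing the contralateral (CPN) count on the group label with the log
#' of the case's total labeled neurons as an exposure offset, under an NB2
#' (log link, variance mu + alpha * mu^2) model. Cross-case counts are
#' strongly overdispersed relative to Poisson, so the dispersion alpha is
#' estimated by maximum likelihood (via [MASS::glm.nb()], whose `theta` is
#' `1/alpha`) unless fixed by the caller. All pairwise group contrasts are
#' exponentiated into rate ratios with Wald p-values, Benjamini-Hochberg
#' adjusted across exactly that pairwise set.
#'
#' @param counts integer vector of contralateral (event) counts per case.
#' @param totals integer vector of total labeled neurons per case
#'   (exposure; must be positive).
#' @param group group label per case (>= 2 cases per group).
#' @param dispersion `NULL` to estimate alpha by ML (the default); a
#'   positive value to fix it; `0` for the Poisson limit.
#' @return object of class `nb_regression`: list with `groups`,
#'   `coefficients` (per-group log rates relative to the first group),
#'   `rate_ratios`, `se`, `p_values`, `p_adjusted` (named "A_vs_B"),
#'   `dispersion`, `theta`, `converged`, and the underlying `model`.
#' @examples
#' tab <- load_table2_fixture()
#' sub <- tab[tab$region %in% c("prefrontal", "premotor", "parietal"), ]
#' fit <- nb_rate_regression(sub$contra, sub$total, sub$region)
#' fit$rate_ratios[["parietal_vs_prefrontal"]]  # ~0.46
#' @export
nb_rate_regression <- function(counts, totals, group, dispersion = NULL) {
  if (length(counts) != length(totals) || length(counts) != length(group))
    stop_value("counts, totals, group must have equal length")
  if (any(totals <= 0)) stop_value("totals must be positive (exposure offset)")
  if (any(counts < 0)) stop_value("counts must be nonnegative")
  group <- if (is.factor(group)) droplevels(group) else factor(group, levels = unique(group))
  sizes <- table(group)
  if (length(sizes) < 2L) stop_value("need at least 2 groups")
  if (any(sizes < 2L))
    stop_value(paste0("each group needs >= 2 cases; too small: ",
                      paste(names(sizes)[sizes < 2L], collapse = ", ")))
  zero_groups <- names(which(tapply(counts, group, sum) == 0))
  if (length(zero_groups))
    warning("group(s) with all-zero counts (separation risk): ",
            paste(zero_groups, collapse = ", "))
  dat <- data.frame(counts = counts, totals = totals, group = group)
  if (is.null(dispersion)) {
    fit <- MASS::glm.nb(counts ~ group + offset(log(totals)), data = dat,
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    theta <- fit$theta
    alpha <- 1 / theta
  } else if (dispersion > 0) {
    theta <- 1 / dispersion
    fit <- stats::glm(counts ~ group + offset(log(totals)), data = dat,
                      family = MASS::negative.binomial(theta = theta),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    alpha <- dispersion
  } else {
    fit <- stats::glm(counts ~ group + offset(log(totals)), data = dat,
                      family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    theta <- Inf
    alpha <- 0
  }
  if (!fit$converged)
    warning("IRLS did not converge in 100 iterations; estimates may be unstable")

  levs <- levels(group)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  # per-group log-rate coefficient relative to the baseline level
  gcoef <- stats::setNames(c(0, beta[paste0("group", levs[-1])]), levs)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rr <- se <- pv <- stats::setNames(numeric(length(pairs)), vapply(
    pairs, function(pr) paste0(pr[2], "_vs_", pr[1]), character(1)))
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][2]; b <- pairs[[k]][1]   # contrast: a vs b
    cv <- stats::setNames(numeric(length(beta)), names(beta))
    if (a != levs[1]) cv[paste0("group", a)] <- 1
    if (b != levs[1]) cv[paste0("group", b)] <- -1
    est <- sum(cv * beta)
    s <- sqrt(drop(t(cv) %*% V %*% cv))
    rr[k] <- exp(est)
    se[k] <- s
    pv[k] <- 2 * stats::pnorm(-abs(est / s))
  }
  structure(list(groups = levs, group_sizes = as.integer(sizes),
                 coefficients = gcoef, rate_ratios = rr, se = se,
                 p_values = pv, p_adjusted = bh_adjust(pv),
                 dispersion = alpha, theta = theta,
                 converged = fit$converged, model = fit),
            class = "nb_regression")
}

#' @export
print.nb_regression <- function(x, ...) {
  cat("Negative-binomial rate-ratio regression (offset = log total)\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups, x$group_sizes),
                         collapse = ", "), "\n")
  cat(sprintf("  dispersion alpha = %.4f (theta = %.3f)\n", x$dispersion, x$theta))
  for (nm in names(x$rate_ratios))
    cat(sprintf("  %s: RR = %.3f, p = %.4f, p.adj = %.4f\n",
                nm, x$rate_ratios[nm], x$p_values[nm], x$p_adjusted[nm]))
  invisible(x)
}

#' Per-region summary of %CPN
#'
#' Mean, minimum, and maximum of the per-case callosal percentage within
#' one region group, recomputed at full precision from the counts (never
#' from rounded presentation columns). Presentation rounds the mean to the
#' nearest integer.
#'
#' @param tab data.frame with columns `region`, `ipsi`, `contra` (and
#'   `injected_area` if `exclude_areas` is used), e.g.
#'   [load_table2_fixture()] or a stack of [aggregate_counts()] rows with a
#'   region column.
#' @param region region label to summarize.
#' @param exclude_areas optional injected-area labels to drop (e.g. "PF"
#'   when summarizing the parietal group without its weakly callosal
#'   rostral-IPL cases).
#' @return list of class `region_summary`: `region`, `mean_pct_cpn`,
#'   `min_pct_cpn`, `max_pct_cpn`, `n_cases`.
#' @export
region_summary <- function(tab, region, exclude_areas = NULL) {
  rows <- tab[tab$region == region, , drop = FALSE]
  if (!is.null(exclude_areas))
    rows <- rows[!(rows$injected_area %in% exclude_areas), , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_value(paste0("no cases in region '", region, "'"))
  pc <- percent_cpn(rows)
  structure(list(region = region, mean_pct_cpn = mean(pc),
                 min_pct_cpn = min(pc), max_pct_cpn = max(pc),
                 n_cases = nrow(rows)),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("%s: mean %%CPN = %.0f (range %.0f-%.0f), n = %d\n",
              x$region, round_half_up(x$mean_pct_cpn, 0),
              round_half_up(x$min_pct_cpn, 0), round_half_up(x$max_pct_cpn, 0),
              x$n_cases))
  invisible(x)
}
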