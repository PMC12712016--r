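# Independent oracles used to cross-check the implementation paths.

# Benjamini-Hochberg step-up, written from the definition: sort p, compute
# p_(i) * m / i, enforce monotonicity from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson r and two-sided t-test p from the closed-form definitions.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# NB2 log-likelihood at given means and theta, from the density.
nb2_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
}

# The worked toy case: injection in F7; 10 ipsi neurons in F2, 5 ipsi in the
# injected area F7 (deposit, excluded from counting), 4 contra in F7
# (homotopic), 2 contra in F6.
toy_dataset <- function() {
  cases <- data.frame(case_id = "T1", species = "synthetic", sex = "F",
                      age_years = 5, injected_hemisphere = "R",
                      injected_area = "F7", tracer = "FB", amount_ul = 0.2)
  records <- data.frame(
    case_id = "T1",
    section_um = c(0, 300, 600, 900, 1200),
    hemisphere = c("ipsi", "ipsi", "contra", "contra", "contra"),
    area = c("F2", "F7", "F7", "F7", "F6"),
    layer = "superficial",
    count = c(10L, 5L, 2L, 2L, 2L))
  labeling_dataset(cases, records)
}

# Aggregated records for one projection with exact laminar counts on a
# 300-um grid.
laminar_records <- function(case_id, hemisphere, area, n_sup, n_deep,
                            n_unknown = 0) {
  parts <- c(superficial = n_sup, deep = n_deep, unknown = n_unknown)
  parts <- parts[parts > 0]
  do.call(rbind, lapply(names(parts), function(layer)
    data.frame(case_id = case_id, section_um = 300L * (seq_len(parts[[layer]]) %% 20L),
               hemisphere = hemisphere, area = area, layer = layer,
               count = 1L)))
}
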