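# Independent oracles and small fixture builders used across test files.
# These deliberately avoid the code paths of the package functions they check.

# pure cosine signal builder
cosine_signal <- function(t, mesor, amplitude, phase, period = 24) {
  mesor + amplitude * cos(2 * pi * (t - phase) / period)
}

# brute-force normal-equations solution of the cosinor regression
oracle_normal_equations <- function(y, t, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# four-model BICs by explicit per-model lm() fits and dnorm() likelihood sums
oracle_four_bics <- function(yy, yo, ty, to, period = 24) {
  w <- 2 * pi / period
  y <- c(yy, yo)
  tt <- c(ty, to)
  g <- factor(rep(c("young", "old"), c(length(yy), length(yo))),
              levels = c("young", "old"))
  cw <- cos(w * tt); sw <- sin(w * tt)
  iy <- as.numeric(g == "young"); io <- as.numeric(g == "old")
  forms <- list(
    neither    = y ~ 0 + g,
    young_only = y ~ 0 + g + I(iy * cw) + I(iy * sw),
    old_only   = y ~ 0 + g + I(io * cw) + I(io * sw),
    both       = y ~ 0 + g + I(iy * cw) + I(iy * sw) + I(io * cw) + I(io * sw)
  )
  n <- length(y)
  vapply(names(forms), function(nm) {
    fit <- lm(forms[[nm]])
    sigma <- sqrt(sum(residuals(fit)^2) / n)
    ll <- sum(dnorm(y, fitted(fit), sigma, log = TRUE))
    k <- length(coef(fit)) + 1
    k * log(n) - 2 * ll
  }, numeric(1))
}

# Kuiper V by direct evaluation of both ECDF differences at every pooled point
oracle_kuiper_V <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- ecdf(x)(pts); Fy <- ecdf(y)(pts)
  max(c(Fx - Fy, 0)) + max(c(Fy - Fx, 0))
}

# exact Kuiper permutation p by complete enumeration of all splits
oracle_kuiper_enum_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  v_obs <- oracle_kuiper_V(x, y)
  splits <- combn(length(z), n1)
  vs <- apply(splits, 2, function(idx) oracle_kuiper_V(z[idx], z[-idx]))
  mean(vs >= v_obs - 1e-12)
}

# exact two-sided Wilcoxon p by complete enumeration of rank assignments;
# uses the symmetric-distance definition, equivalent to doubling the smaller
# tail for the symmetric null distribution of W
oracle_wilcoxon_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  splits <- combn(n1 + n2, n1)
  ws <- apply(splits, 2, function(idx) sum(seq_len(n1 + n2)[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# hand BH: sorted step-up with cummin, independent of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  q[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q
}

# noise-free two-group expression dataset with explicit per-group parameters
make_two_group_dataset <- function(genes, tp = seq(32, 58, 2), donors = 4,
                                   noise_sd = 0, seed = 1) {
  # genes: list of lists with fields m_y, a_y, p_y, m_o, a_o, p_o
  samples <- expand.grid(timepoint_hr = tp, donor = LETTERS[1:donors],
                         group = c("young", "old"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_t%02d", samples$group, samples$donor,
                               samples$timepoint_hr)
  samples <- samples[, c("sample_id", "group", "donor", "timepoint_hr")]
  set.seed(seed)
  vals <- t(vapply(genes, function(gp) {
    mu <- ifelse(samples$group == "young",
                 cosine_signal(samples$timepoint_hr, gp$m_y, gp$a_y, gp$p_y),
                 cosine_signal(samples$timepoint_hr, gp$m_o, gp$a_o, gp$p_o))
    mu + rnorm(nrow(samples), 0, noise_sd)
  }, numeric(nrow(samples))))
  rownames(vals) <- sprintf("g%03d", seq_along(genes))
  colnames(vals) <- samples$sample_id
  expression_dataset(vals, samples)
}
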