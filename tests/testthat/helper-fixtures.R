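# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# quick expression matrix from a plain matrix or dims
make_expr <- function(values, genes = NULL, samples = NULL,
                      scale = "log2", platform = "rtpcr") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = scale, platform = platform)
}

# balanced case/control records with alternating sex and spread ages
make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("s%02d", seq_len(n)),
    status = rep(c("case", "control"), length.out = n),
    sex = rep(c("M", "F"), each = ceiling(n / 2))[seq_len(n)],
    age = round(runif(n, 40, 80)),
    stringsAsFactors = FALSE
  )
}

# matched-pair records: n_pairs pairs, with per-gene case-control differences
# supplied directly
make_paired_fixture <- function(d, gene = "g01", seed = 1) {
  n <- length(d)
  set.seed(seed)
  ids_case <- sprintf("ca%02d", seq_len(n))
  ids_ctrl <- sprintf("co%02d", seq_len(n))
  base <- rnorm(n, 10, 1)
  vals <- matrix(c(base + d, base), nrow = 1,
                 dimnames = list(gene, c(ids_case, ids_ctrl)))
  rec <- data.frame(
    id = c(ids_case, ids_ctrl),
    status = rep(c("case", "control"), each = n),
    sex = "M", age = 60,
    pair_id = rep(sprintf("P%02d", seq_len(n)), 2),
    stringsAsFactors = FALSE
  )
  list(expr = expression_matrix(vals), records = rec)
}

# independent profile-likelihood grid-search oracle for simple logistic
# regression y ~ 1 + x: for each beta on a refining grid, the intercept is
# profiled out by 1-d golden-section optimization; independent of glm's IRLS.
logistic_grid_oracle <- function(x, y, beta_range = c(-10, 10)) {
  loglik <- function(b0, b1) sum(y * (b0 + b1 * x) - log1p(exp(b0 + b1 * x)))
  profile <- function(b1) {
    stats::optimize(function(b0) loglik(b0, b1), c(-50, 50),
                    maximum = TRUE, tol = 1e-10)$objective
  }
  lo <- beta_range[1]; hi <- beta_range[2]
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, profile, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  }
  (lo + hi) / 2
}

# grid maximizer of the 1:1 matched-pair conditional likelihood
clogit_grid_oracle <- function(d, beta_range = c(-10, 10)) {
  ll <- function(b) sum(stats::plogis(b * d, log.p = TRUE))
  lo <- beta_range[1]; hi <- beta_range[2]
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, ll, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  }
  (lo + hi) / 2
}

# pair-counting AUC oracle: (concordant + 0.5 * ties) / all case-control pairs
auc_pair_oracle <- function(scores, labels) {
  cases <- scores[labels]
  ctrls <- scores[!labels]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# direct step-up BH oracle written from the definitional formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact enumeration oracle for the hypergeometric upper tail
hyper_enum_oracle <- function(universe_n, study_n, term_n, overlap) {
  draws <- utils::combn(universe_n, study_n)
  term <- seq_len(term_n)
  hits <- apply(draws, 2, function(s) sum(s %in% term))
  mean(hits >= overlap)
}

# attach pair ids produced by match_pairs back onto the records
attach_pairs <- function(records, pairs) {
  records$pair_id <- NA_character_
  records$pair_id[match(pairs$case_id, records$id)] <- pairs$pair_id
  records$pair_id[match(pairs$control_id, records$id)] <- pairs$pair_id
  records[!is.na(records$pair_id), , drop = FALSE]
}
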