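# Discovery-stage statistics: normalization, sample QC, per-gene CAD
# association (unpaired/adjusted/robust and matched-pair conditional
# logistic), multiple-testing control, cross-cohort intersection, gene-set
# enrichment, and clinical factor statistics.

#' Trimmed-mean scaling followed by log2 transformation
#'
#' Each sample (column) of a linear-scale matrix is rescaled so its two-sided
#' trimmed mean equals `target` (100 by default), then transformed as
#' `log2(scaled + offset)`. The offset (+1 by default) keeps zeros finite and
#' the transform monotone. Output is invariant to per-sample positive
#' rescaling of the raw input.
#'
#' @param raw linear-scale [expression_matrix()] with non-negative values.
#' @param target target trimmed mean after scaling.
#' @param trim_fraction fraction trimmed from each tail, in \[0, 0.5).
#' @param offset additive offset before log2.
#' @return A log2-scale [expression_matrix()].
#' @export
normalize_trimmed_mean <- function(raw, target = 100, trim_fraction = 0.02,
                                   offset = 1) {
  if (!is.null(attr(raw, "scale")) && attr(raw, "scale") != "linear") {
    stop("normalize_trimmed_mean expects linear-scale input")
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)")
  }
  if (any(raw < 0, na.rm = TRUE)) stop("raw intensities must be >= 0")
  vals <- unclass(raw)
  tm <- apply(vals, 2, mean, trim = trim_fraction, na.rm = TRUE)
  zero <- which(!is.finite(tm) | tm <= 0)
  if (length(zero)) {
    stop("sample(s) with non-positive trimmed mean: ",
         paste(colnames(vals)[zero], collapse = ", "))
  }
  scaled <- sweep(vals, 2, target / tm, `*`)
  out <- log2(scaled + offset)
  expression_matrix(out, scale = "log2",
                    platform = attr(raw, "platform") %||% "microarray")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample array quality control
#'
#' Computes, per sample: percent present (share of finite values above a
#' detection floor), median pairwise correlation with all other samples, and
#' median signal intensity. A sample passes when percent present and
#' correlation clear their minima and its median intensity lies within
#' `intensity_mad` robust SDs (MAD) of the cohort median.
#'
#' @param mat an [expression_matrix()].
#' @param percent_present_min minimum percent present (0-100).
#' @param corr_min minimum median pairwise Pearson correlation.
#' @param intensity_mad allowed deviation of median intensity, in MAD units.
#' @param present_floor detection floor; values must exceed it to count as
#'   present.
#' @return list with `metrics` (per-sample data.frame with `pass`) and
#'   `excluded` (character vector of failing sample ids).
#' @export
qc_samples <- function(mat, percent_present_min = 60, corr_min = 0.6,
                       intensity_mad = 3, present_floor = 0) {
  vals <- unclass(mat)
  n <- ncol(vals)
  if (n < 1) stop("empty matrix")
  pp <- 100 * colMeans(is.finite(vals) & vals > present_floor)
  med_int <- apply(vals, 2, stats::median, na.rm = TRUE)
  if (n >= 2) {
    cc <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
    diag(cc) <- NA
    med_cor <- apply(cc, 2, stats::median, na.rm = TRUE)
    corr_pass <- !is.na(med_cor) & med_cor >= corr_min
  } else {
    warning("single sample: pairwise correlation unavailable, ",
            "passing on remaining metrics only")
    med_cor <- NA_real_
    corr_pass <- TRUE
  }
  center <- stats::median(med_int)
  spread <- stats::mad(med_int)
  int_pass <- if (spread == 0) rep(TRUE, n) else
    abs(med_int - center) <= intensity_mad * spread
  pass <- pp >= percent_present_min & corr_pass & int_pass
  metrics <- data.frame(
    sample = colnames(vals),
    percent_present = pp,
    median_pairwise_cor = med_cor,
    median_intensity = med_int,
    pass_percent_present = pp >= percent_present_min,
    pass_correlation = corr_pass,
    pass_intensity = int_pass,
    pass = pass,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(metrics = metrics, excluded = colnames(vals)[!pass])
}

.align_records <- function(mat, records) {
  missing_rec <- setdiff(colnames(mat), records$id)
  missing_mat <- setdiff(records$id, colnames(mat))
  if (length(missing_rec) || length(missing_mat)) {
    stop("sample id mismatch; in matrix only: ",
         paste(missing_rec, collapse = ", "), "; in records only: ",
         paste(missing_mat, collapse = ", "))
  }
  records[match(colnames(mat), records$id), , drop = FALSE]
}

# Huber-type robust logistic regression: IRLS with case weights
# min(1, k/|r|) on Pearson residuals, tuning constant k = 1.345.
.robust_logit <- function(X, y, k = 1.345, max_rounds = 10) {
  w <- rep(1, length(y))
  fit <- NULL
  for (round in seq_len(max_rounds)) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, weights = w, family = stats::binomial(),
                     control = list(maxit = 25)))
    mu <- fit$fitted.values
    r <- (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-10))
    w_new <- pmin(1, k / pmax(abs(r), 1e-10))
    if (max(abs(w_new - w)) < 1e-6) {
      w <- w_new
      break
    }
    w <- w_new
  }
  fit$robust_weights <- w
  fit
}

.wald_from_fit <- function(fit, coef_name) {
  cf <- fit$coefficients
  i <- match(coef_name, names(cf))
  rank <- fit$rank
  # dispersion fixed at 1 (binomial); respect QR pivoting as summary.glm does
  cov_un <- tryCatch(
    chol2inv(fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]),
    error = function(e) NULL)
  pos <- match(i, fit$qr$pivot[seq_len(rank)])
  if (is.null(cov_un) || is.na(pos) || is.na(cf[i])) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  }
  se <- sqrt(diag(cov_un))[pos]
  z <- cf[i] / se
  list(beta = unname(cf[i]), se = unname(se),
       p = 2 * stats::pnorm(-abs(z)))
}

#' Per-gene logistic regression association with case status
#'
#' For each gene, fits `status ~ expression` (optionally `+ sex + age`) by
#' maximum-likelihood logistic regression and reports the Wald test on the
#' expression coefficient. With `robust = TRUE`, estimation down-weights
#' observations with large Pearson residuals (Huber weights, tuning constant
#' 1.345), the conventional robust-GLM choice for RT-PCR panels. Constant
#' genes are flagged `degenerate` (beta 0, p 1); complete separation is
#' flagged `separated` with the iteration-capped estimate reported.
#'
#' @param mat [expression_matrix()], samples in columns.
#' @param records sample records aligned by id.
#' @param adjust `"none"` or `"sex_age"`.
#' @param robust use Huber-down-weighted estimation.
#' @return data.frame: gene, beta, se, p_unadj, p_adj, q, flag.
#' @export
gene_association <- function(mat, records, adjust = c("none", "sex_age"),
                             robust = FALSE) {
  adjust <- match.arg(adjust)
  records <- .align_records(mat, records)
  if (length(unique(records$status)) < 2) {
    stop("need both cases and controls")
  }
  y <- as.numeric(records$status == "case")
  covars <- NULL
  if (adjust == "sex_age") {
    if (any(is.na(records$age))) stop("age required for sex/age adjustment")
    covars <- cbind(sexM = as.numeric(records$sex == "M"), age = records$age)
  }
  genes <- rownames(mat)
  out <- data.frame(gene = genes, beta = NA_real_, se = NA_real_,
                    p_unadj = NA_real_, p_adj = NA_real_, q = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    x <- as.numeric(mat[i, ])
    if (stats::sd(x) == 0) {
      out$beta[i] <- 0
      out$p_unadj[i] <- 1
      out$p_adj[i] <- if (adjust == "sex_age") 1 else NA_real_
      out$flag[i] <- "degenerate"
      next
    }
    fit_one <- function(X) {
      if (robust) .robust_logit(X, y) else
        suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                        control = list(maxit = 25)))
    }
    X0 <- cbind(`(Intercept)` = 1, expr = x)
    f0 <- fit_one(X0)
    w0 <- .wald_from_fit(f0, "expr")
    sep <- !f0$converged || any(f0$fitted.values > 1 - 1e-8) ||
      any(f0$fitted.values < 1e-8)
    out$p_unadj[i] <- w0$p
    if (adjust == "sex_age") {
      X1 <- cbind(X0, covars)
      f1 <- fit_one(X1)
      w1 <- .wald_from_fit(f1, "expr")
      sep <- sep || !f1$converged
      out$beta[i] <- w1$beta
      out$se[i] <- w1$se
      out$p_adj[i] <- w1$p
    } else {
      out$beta[i] <- w0$beta
      out$se[i] <- w0$se
    }
    if (sep) out$flag[i] <- "separated"
  }
  p_primary <- if (adjust == "sex_age") out$p_adj else out$p_unadj
  out$q <- bh_fdr(ifelse(is.na(p_primary), 1, p_primary))
  out
}

#' Conditional logistic regression for matched case:control pairs
#'
#' For 1:1 matched pairs the conditional likelihood reduces to
#' `L(beta) = prod_i [1 + exp(-beta * d_i)]^-1` with
#' `d_i = x_case - x_control`; this is maximized per gene by Newton
#' iteration. The same maximum is attained by intercept-free logistic
#' regression on the pair differences, an identity exercised by the test
#' suite. Both a Wald p-value (`p_unadj`) and the score-test p-value at
#' beta = 0 (`p_score`) are reported.
#'
#' @param mat [expression_matrix()].
#' @param records sample records carrying `pair_id` (exactly one case and one
#'   control per pair).
#' @param max_iter Newton iteration cap; pairs whose differences are all of
#'   one sign cannot have a finite maximizer and are flagged `separated` at
#'   the cap.
#' @return data.frame: gene, beta, se, p_unadj, p_score, q, flag.
#' @export
paired_gene_association <- function(mat, records, max_iter = 25) {
  records <- .align_records(mat, records)
  if (!"pair_id" %in% names(records) || any(is.na(records$pair_id))) {
    stop("records must carry a complete pair_id column")
  }
  split_rec <- split(records, records$pair_id)
  ok <- vapply(split_rec, function(r) {
    nrow(r) == 2 && sum(r$status == "case") == 1
  }, logical(1))
  if (!all(ok)) {
    stop("malformed pair(s): ", paste(names(split_rec)[!ok], collapse = ", "))
  }
  case_ids <- vapply(split_rec, function(r) r$id[r$status == "case"], "")
  ctrl_ids <- vapply(split_rec, function(r) r$id[r$status == "control"], "")
  d_mat <- unclass(mat)[, case_ids, drop = FALSE] -
    unclass(mat)[, ctrl_ids, drop = FALSE]
  genes <- rownames(mat)
  out <- data.frame(gene = genes, beta = NA_real_, se = NA_real_,
                    p_unadj = NA_real_, p_score = NA_real_, q = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    d <- as.numeric(d_mat[i, ])
    fit <- clogit_1to1(d, max_iter = max_iter)
    out$beta[i] <- fit$beta
    out$se[i] <- fit$se
    out$p_unadj[i] <- fit$p_wald
    out$p_score[i] <- fit$p_score
    out$flag[i] <- fit$flag
  }
  out$q <- bh_fdr(ifelse(is.na(out$p_unadj), 1, out$p_unadj))
  out
}

#' Newton solver for the 1:1 matched-pair conditional likelihood
#'
#' Maximizes `sum_i log plogis(beta * d_i)` over beta for pair differences
#' `d`. Exposed so oracles and callers can exercise the solver directly.
#'
#' @param d numeric vector of case-minus-control differences.
#' @param max_iter Newton iteration cap.
#' @return list: beta, se, p_wald, p_score, flag, loglik.
#' @export
clogit_1to1 <- function(d, max_iter = 25) {
  d <- as.numeric(d)
  if (all(d == 0)) {
    return(list(beta = 0, se = NA_real_, p_wald = 1, p_score = 1,
                flag = "degenerate", loglik = length(d) * log(0.5)))
  }
  separated <- all(d >= 0) || all(d <= 0)
  # score test at beta = 0: U = sum(d)/2, Var(U) = sum(d^2)/4
  z_score <- sum(d) / sqrt(sum(d^2))
  p_score <- 2 * stats::pnorm(-abs(z_score))
  beta <- 0
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(beta * d)
    u <- sum(d * (1 - p))
    info <- sum(d^2 * p * (1 - p))
    if (info < 1e-12) break
    step <- u / info
    step <- max(min(step, 5), -5)   # damp wild Newton steps
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  p <- stats::plogis(beta * d)
  info <- sum(d^2 * p * (1 - p))
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  p_wald <- if (!is.na(se)) 2 * stats::pnorm(-abs(beta / se)) else NA_real_
  list(beta = beta, se = se, p_wald = p_wald, p_score = p_score,
       flag = if (separated) "separated" else "ok",
       loglik = sum(stats::plogis(beta * d, log.p = TRUE)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Validating wrapper around the standard step-up adjustment: q-values are
#' order-preserving, clipped at 1, and invariant to input permutation (up to
#' reordering).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

#' Intersection of significant genes across two discovery cohorts
#'
#' @param res_a,res_b association result data.frames.
#' @param alpha significance level.
#' @param use which p-value column to screen (`"p_unadj"` by default,
#'   matching the discovery screens; `"p_adj"` or `"q"` available).
#' @return character vector of gene ids significant in both.
#' @export
intersect_discovery <- function(res_a, res_b, alpha = 0.05,
                                use = c("p_unadj", "p_adj", "q")) {
  use <- match.arg(use)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sig_a <- res_a$gene[!is.na(res_a[[use]]) & res_a[[use]] < alpha]
  sig_b <- res_b$gene[!is.na(res_b[[use]]) & res_b[[use]] < alpha]
  intersect(sig_a, sig_b)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value per annotation set (P\[overlap >=
#' observed\] drawing `|study|` genes from the universe), with BH correction
#' across sets. Annotation sets are intersected with the universe first.
#'
#' @param study character vector of study genes (must lie in `universe`).
#' @param annotation named list of gene sets.
#' @param universe character vector of all assayed genes.
#' @return data.frame: set, set_size, overlap, p, q.
#' @export
enrich_hypergeometric <- function(study, annotation, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  study <- unique(study)
  if (!all(study %in% universe)) {
    stop("study genes outside the universe: ",
         paste(setdiff(study, universe), collapse = ", "))
  }
  res <- lapply(names(annotation), function(nm) {
    term <- intersect(unique(annotation[[nm]]), universe)
    ov <- length(intersect(study, term))
    p <- stats::phyper(ov - 1, length(term),
                       length(universe) - length(term), length(study),
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(term), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}

#' Clinical and demographic factor association with case status
#'
#' Continuous factors are tested by univariate logistic regression (Wald);
#' categorical factors by Pearson chi-square on the contingency table without
#' continuity correction. Optionally a multivariate logistic model over a
#' chosen factor set is fitted. Zero-variance factors are flagged, not fatal.
#'
#' @param records sample records with `status` plus factor columns.
#' @param factors character vector of column names to test; defaults to all
#'   columns except id/status/pair bookkeeping.
#' @param multivariate optional character vector of factors for a joint
#'   logistic model.
#' @return list with `univariate` (factor, type, estimate, p, flag) and
#'   `multivariate` (term-level coefficients and p, or NULL).
#' @export
clinical_factor_association <- function(records, factors = NULL,
                                        multivariate = NULL) {
  if (!"status" %in% names(records)) stop("records must carry status")
  y <- as.numeric(records$status == "case")
  if (length(unique(y)) < 2) stop("need both cases and controls")
  skip <- c("id", "status", "pair_id", "complete")
  if (is.null(factors)) factors <- setdiff(names(records), skip)
  uni <- lapply(factors, function(f) {
    x <- records[[f]]
    flag <- "ok"
    if (is.numeric(x)) {
      if (stats::sd(x, na.rm = TRUE) == 0) {
        return(data.frame(factor = f, type = "continuous",
                          estimate = 0, p = 1, flag = "degenerate"))
      }
      keep <- !is.na(x)
      fit <- suppressWarnings(stats::glm(y[keep] ~ x[keep],
                                         family = stats::binomial()))
      sm <- summary(fit)$coefficients
      data.frame(factor = f, type = "continuous",
                 estimate = sm[2, 1], p = sm[2, 4], flag = flag,
                 stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      keep <- !is.na(x)
      if (length(unique(x[keep])) < 2) {
        return(data.frame(factor = f, type = "categorical",
                          estimate = NA_real_, p = 1, flag = "degenerate"))
      }
      tab <- table(x[keep], y[keep])
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(factor = f, type = "categorical",
                 estimate = unname(ct$statistic), p = ct$p.value,
                 flag = flag, stringsAsFactors = FALSE)
    }
  })
  uni <- do.call(rbind, uni)
  multi <- NULL
  if (!is.null(multivariate)) {
    df <- records[, multivariate, drop = FALSE]
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    multi <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], p = sm[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
  }
  list(univariate = uni, multivariate = multi)
}

#' Pearson chi-square test on a printed contingency table
#'
#' Convenience wrapper for published count tables (rows = categories,
#' columns = groups), without continuity correction.
#'
#' @param counts numeric matrix of counts.
#' @return list: statistic, df, p.
#' @export
contingency_chisq <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
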