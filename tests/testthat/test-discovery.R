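test_that("trimmed-mean scaling matches the hand-computed oracle", {
  raw <- make_expr(matrix(c(1, 2, 3, 4, 1000), ncol = 1), scale = "linear",
                   platform = "microarray")
  out <- normalize_trimmed_mean(raw, target = 100, trim_fraction = 0.2,
                                offset = 1)
  # 20% two-sided trim drops 1 and 1000: trimmed mean 3, scale 100/3
  expected_scaled <- c(1, 2, 3, 4, 1000) * 100 / 3
  expect_equal(as.numeric(out), log2(expected_scaled + 1), tolerance = 1e-12)
})

test_that("a sample already at the target passes through up to the offset", {
  x <- c(60, 80, 100, 120, 140)  # trimmed mean 100 at 20% trim
  raw <- make_expr(matrix(x, ncol = 1), scale = "linear")
  out <- normalize_trimmed_mean(raw, trim_fraction = 0.2)
  expect_equal(as.numeric(out), log2(x + 1), tolerance = 1e-12)
})

test_that("normalization is invariant to per-sample rescaling and rejects zeros", {
  set.seed(2)
  vals <- matrix(rexp(40, 1 / 100), 10, 4)
  raw <- make_expr(vals, scale = "linear")
  raw10 <- make_expr(sweep(vals, 2, c(10, 1, 0.3, 7), `*`),
                     scale = "linear")
  expect_equal(unclass(normalize_trimmed_mean(raw)),
               unclass(normalize_trimmed_mean(raw10)), tolerance = 1e-12,
               ignore_attr = TRUE)
  vals[, 2] <- 0
  expect_error(normalize_trimmed_mean(make_expr(vals, scale = "linear")),
               "s02")
})

test_that("QC metrics flag exactly the corrupted samples", {
  set.seed(4)
  shared <- rnorm(200, 8, 2)
  vals <- sapply(1:10, function(j) shared + rnorm(200, 0, 0.5))
  vals[, 7] <- rnorm(200, 8, 2)  # decorrelated sample
  m <- make_expr(vals, genes = sprintf("g%03d", 1:200))
  qc <- qc_samples(m, corr_min = 0.5, percent_present_min = 0)
  expect_identical(qc$excluded, "s07")

  two <- make_expr(cbind(shared, shared)[1:50, ])
  qc2 <- qc_samples(two, percent_present_min = 0)
  expect_equal(qc2$metrics$median_pairwise_cor, c(1, 1))
  expect_true(all(qc2$metrics$pass))

  dead <- vals
  dead[, 3] <- -1  # below the detection floor
  qc3 <- qc_samples(make_expr(dead), corr_min = -1, intensity_mad = Inf)
  expect_false(qc3$metrics$pass_percent_present[3])
})

test_that("logistic association matches an independent profile-likelihood oracle", {
  set.seed(6)
  n <- 40
  rec <- make_records(n)
  x <- rnorm(n) + 0.8 * (rec$status == "case")
  m <- make_expr(matrix(x, 1), genes = "g01", samples = rec$id)
  res <- gene_association(m, rec)
  oracle_beta <- logistic_grid_oracle(x, as.numeric(rec$status == "case"))
  expect_equal(res$beta, oracle_beta, tolerance = 1e-6)
})

test_that("degenerate and separated genes are flagged, not fatal", {
  rec <- make_records(20)
  const <- rep(5, 20)
  sep <- ifelse(rec$status == "case", 1, -1)
  m <- make_expr(rbind(const, sep), genes = c("gconst", "gsep"),
                 samples = rec$id)
  res <- gene_association(m, rec)
  expect_identical(res$flag, c("degenerate", "separated"))
  expect_equal(res$beta[1], 0)
  expect_equal(res$p_unadj[1], 1)
  expect_true(is.finite(res$beta[2]))
  rec_onesided <- rec; rec_onesided$status <- "case"
  expect_error(gene_association(m, rec_onesided), "both cases and controls")
  expect_error(gene_association(m, make_records(19)), "id mismatch")
})

test_that("robust estimation resists a gross expression outlier", {
  set.seed(8)
  n <- 80
  rec <- make_records(n)
  x <- rnorm(n) + 1 * (rec$status == "case")
  m_clean <- make_expr(matrix(x, 1), genes = "g01", samples = rec$id)
  beta_clean <- gene_association(m_clean, rec)$beta
  x_dirty <- x
  x_dirty[which(rec$status == "control")[1]] <- 25  # gross outlier
  m_dirty <- make_expr(matrix(x_dirty, 1), genes = "g01", samples = rec$id)
  beta_ml <- gene_association(m_dirty, rec)$beta
  beta_rob <- gene_association(m_dirty, rec, robust = TRUE)$beta
  expect_lt(abs(beta_rob - beta_clean), abs(beta_ml - beta_clean))
})

test_that("conditional logistic estimates match the grid oracle and the
           difference-regression identity", {
  for (s in 1:5) {
    set.seed(100 + s)
    d <- rnorm(20, 0.4, 1)
    fx <- make_paired_fixture(d, seed = s)
    res <- paired_gene_association(fx$expr, fx$records)
    expect_equal(res$beta, clogit_grid_oracle(d), tolerance = 1e-6)
    # identity: intercept-free logistic regression on pair differences
    glm_fit <- suppressWarnings(
      glm(rep(1, length(d)) ~ d - 1, family = binomial()))
    expect_equal(res$beta, unname(coef(glm_fit)), tolerance = 1e-6)
  }
})

test_that("conditional logistic agrees with the survival-package fit", {
  library(survival)
  set.seed(17)
  d <- rnorm(30, 0.2, 1.2)
  fx <- make_paired_fixture(d)
  res <- paired_gene_association(fx$expr, fx$records)
  y <- rep(c(1, 0), 30)
  strat <- rep(seq_len(30), each = 2)
  xval <- as.numeric(rbind(d, 0))
  cl <- survival::clogit(y ~ xval + strata(strat))
  expect_equal(res$beta, unname(coef(cl)), tolerance = 1e-7)
})

test_that("degenerate and separated pair patterns behave as stated", {
  fx0 <- make_paired_fixture(rep(0, 10))
  res0 <- paired_gene_association(fx0$expr, fx0$records)
  expect_equal(res0$beta, 0)
  expect_equal(res0$p_unadj, 1)
  expect_identical(res0$flag, "degenerate")

  fx1 <- make_paired_fixture(abs(rnorm(10)) + 0.1)
  res1 <- paired_gene_association(fx1$expr, fx1$records)
  expect_identical(res1$flag, "separated")

  bad <- fx1$records
  bad$status[bad$pair_id == "P01"] <- "case"
  expect_error(paired_gene_association(fx1$expr, bad), "malformed pair")
})

test_that("BH q-values match the step-up formula and its invariances", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (rep_i in 1:10) {
    p <- runif(25)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))  # monotone in sorted p
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("discovery intersection screens both cohorts at alpha", {
  resA <- data.frame(gene = c("a", "b", "c"), p_unadj = c(0.01, 0.2, 0.03))
  resB <- data.frame(gene = c("a", "b", "c"), p_unadj = c(0.04, 0.01, 0.5))
  expect_identical(intersect_discovery(resA, resB), "a")
  expect_identical(intersect_discovery(resA, resA),
                   resA$gene[resA$p_unadj < 0.05])
  resC <- data.frame(gene = c("a", "b"), p_unadj = c(0.9, 0.9))
  expect_length(intersect_discovery(resA, resC), 0)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  uni <- sprintf("u%02d", 1:20)
  study <- uni[1:5]
  ann <- list(term1 = uni[1:4],       # overlap 3 with study after the draw
              all = uni,              # term = universe
              none = uni[18:20])      # overlap 0
  res <- enrich_hypergeometric(uni[c(1, 2, 3, 19, 20)], ann, uni)
  enum <- hyper_enum_oracle(20, 5, 4, 3)
  expect_equal(res$p[res$set == "term1"], enum, tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1)
  expect_equal(res$p[res$set == "none"],
               phyper(2 - 1, 3, 17, 5, lower.tail = FALSE))
  expect_error(enrich_hypergeometric("x", ann, character(0)),
               "empty universe")
  expect_error(enrich_hypergeometric("zz", ann, uni), "outside")
})

test_that("clinical factor tests reproduce printed and hand-computed values", {
  # published chest-pain contingency: p prints as .0004
  tab <- cbind(controls = c(141, 56, 137, 65), cases = c(90, 29, 47, 61))
  res <- contingency_chisq(tab)
  expect_gt(res$p, 2e-4)
  expect_lt(res$p, 8e-4)

  # hand formula on a 2x2
  t22 <- cbind(c(10, 20), c(20, 10))
  expected <- sum((t22 - outer(rowSums(t22), colSums(t22)) / sum(t22))^2 /
                    (outer(rowSums(t22), colSums(t22)) / sum(t22)))
  expect_equal(contingency_chisq(t22)$statistic, expected, tolerance = 1e-12)

  # identical distribution in cases and controls -> p = 1
  rec <- make_records(40)
  # status alternates case/control, so blocking in twos gives each category
  # the identical 10/10 case:control split
  rec$cp <- rep(c("typical", "typical", "atypical", "atypical"), 10)
  rec$flat <- 1.0
  res2 <- clinical_factor_association(rec, factors = c("cp", "flat", "age"))
  uni <- res2$univariate
  expect_equal(uni$p[uni$factor == "cp"], 1)
  expect_identical(uni$flag[uni$factor == "flat"], "degenerate")
  expect_true(uni$p[uni$factor == "age"] >= 0 &&
                uni$p[uni$factor == "age"] <= 1)
  multi <- clinical_factor_association(rec,
                                       multivariate = c("age", "sex"))
  expect_true(all(c("age", "sexM") %in% multi$multivariate$term))
})
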