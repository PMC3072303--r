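# shared toy terms: two 2-gene meta-genes per term over six genes
.toy_terms <- function() {
  list(
    term_definition("TA",
                    metagene("MA1", c("g01", "g02")),
                    metagene("MA2", c("g03", "g04"))),
    term_definition("TB",
                    metagene("MB1", c("g05", "g06")),
                    metagene("MB2", c("g03", "g04")))
  )
}

test_that("meta-genes and terms match hand arithmetic", {
  vals <- rbind(c(1, 5), c(3, 7), c(2, 2), c(4, 0), c(10, 8), c(0, 2))
  m <- make_expr(vals)
  mg <- metagene("M1", c("g01", "g02"))
  expect_equal(unname(build_metagene(m, mg)), c(2, 6))
  mgw <- metagene("M2", c("g01", "g02"), weights = c(0.25, 0.75))
  expect_equal(unname(build_metagene(m, mgw)), c(2.5, 6.5))
  mgneg <- metagene("M3", "g05", sign = -1)
  expect_equal(unname(build_metagene(m, mgneg)), c(-10, -8))

  tm <- term_definition("T1", metagene("N", c("g01", "g02")),
                        metagene("D", c("g03", "g04")))
  expect_equal(unname(build_term(m, tm)), c(2 - 3, 6 - 1))
  tv <- build_term_matrix(m, .toy_terms())
  expect_identical(colnames(tv), c("TA", "TB"))
  expect_equal(dim(tv), c(2L, 2L))

  expect_error(metagene("bad", sprintf("g%02d", 1:5)), "1 to 4")
  expect_error(metagene("bad", "g01", weights = c(0.4, 0.6)), "length")
  expect_error(metagene("bad", c("g01", "g02"), weights = c(0.7, 0.7)),
               "sum to 1")
  expect_error(term_definition("bad", mg, mg), "must differ")
  expect_error(build_metagene(m, metagene("M", "zz")), "absent")
})

test_that("terms are invariant to constant per-sample shifts and move one
           unit per doubling", {
  set.seed(21)
  vals <- matrix(rnorm(6 * 10, 8, 1), 6, 10)
  m <- make_expr(vals)
  shifted <- make_expr(sweep(vals, 2, rnorm(10), `+`))
  tm <- .toy_terms()[[1]]
  expect_equal(build_term(m, tm), build_term(shifted, tm),
               tolerance = 1e-12)
  # doubling every numerator gene on the linear scale adds exactly 1
  doubled <- vals
  doubled[1:2, ] <- doubled[1:2, ] + 1
  expect_equal(build_term(make_expr(doubled), tm), build_term(m, tm) + 1,
               tolerance = 1e-12)
})

test_that("the design matrix matches a four-person hand fixture", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    status = c("case", "control", "case", "control"),
                    sex = c("M", "M", "F", "F"),
                    age = c(70, 50, 70, 50), stringsAsFactors = FALSE)
  tv <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "T1"))
  d <- make_design(tv, rec, knot = 60)
  expect_identical(colnames(d$x),
                   c("T1", "T1:sexM", "sexM", "age_male", "age_female_hinge"))
  expect_equal(d$x[, "T1:sexM"], c(1, 2, 0, 0))
  expect_equal(d$x[, "age_male"], c(70, 50, 0, 0))
  # hinge: woman at 70 contributes 10, woman at 50 (below knot) contributes 0
  expect_equal(d$x[, "age_female_hinge"], c(0, 0, 10, 0))
  expect_identical(d$penalized, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  d2 <- make_design(tv, rec, sex_interactions = FALSE, sex_main = FALSE)
  expect_identical(colnames(d2$x), c("T1", "age_male", "age_female_hinge"))
  # the hinge is continuous at the knot
  rec_edge <- rec; rec_edge$age <- c(60, 60, 60, 60.25)
  d3 <- make_design(tv, rec_edge, knot = 60)
  expect_equal(unname(d3$x[, "age_female_hinge"]), c(0, 0, 0, 0.25))
  rec_na <- rec; rec_na$age[2] <- NA
  expect_error(make_design(tv, rec_na), "required")
})

test_that("infinite lambda selects nothing; unpenalized columns persist", {
  set.seed(22)
  rec <- make_records(60)
  tv <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("TA", "TB")))
  d <- make_design(tv, rec)
  sel <- lasso_select(d, rec$status == "case", lambda = Inf)
  expect_length(sel$columns, 0)
  expect_length(sel$terms, 0)
  expect_setequal(sel$unpenalized, c("sexM", "age_male", "age_female_hinge"))
})

test_that("LASSO selects nearly nothing on pure-noise terms", {
  n_sel <- integer(20)
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 300
    rec <- make_records(n, seed = 400 + s)
    tv <- matrix(rnorm(n * 9), n, 9,
                 dimnames = list(NULL, sprintf("T%02d", 1:9)))
    d <- make_design(tv, rec)
    sel <- lasso_select(d, rec$status == "case", seed = s)
    n_sel[s] <- length(sel$terms)
  }
  expect_lte(median(n_sel), 1)
})

test_that("ridge shrinkage behaves as the penalty dictates", {
  set.seed(23)
  n <- 120
  rec <- make_records(n)
  y <- as.numeric(rec$status == "case")
  tv <- cbind(TA = rnorm(n) + 0.8 * y, TB = rnorm(n) - 0.5 * y)
  d <- make_design(tv, rec, sex_interactions = FALSE)

  # lambda = 0 equals straight maximum likelihood found by an independent
  # general-purpose optimizer
  fit0 <- ridge_fit(d, y, lambda = 0)
  nll <- function(b) {
    eta <- b[1] + d$x %*% b[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- as.numeric(b[1] + d$x %*% b[-1])
    resid <- plogis(eta) - y
    c(sum(resid), as.numeric(crossprod(d$x, resid)))
  }
  opt <- optim(rep(0, ncol(d$x) + 1), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(fit0$intercept, fit0$coefficients)), unname(opt$par),
               tolerance = 1e-5)

  # penalized-coefficient norm is monotone non-increasing in lambda, and a
  # huge lambda drives the term coefficients to near zero
  lams <- c(0.01, 0.1, 1, 10, 1000)
  norms <- vapply(lams, function(lm) {
    f <- ridge_fit(d, y, lambda = lm)
    sqrt(sum(f$coefficients[c("TA", "TB")]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-8))
  expect_lt(norms[length(norms)], 0.01)

  # singular design at lambda = 0 is refused
  tv_dup <- cbind(tv, TC = tv[, "TA"])
  d_dup <- make_design(tv_dup, rec, sex_interactions = FALSE)
  expect_error(ridge_fit(d_dup, y, lambda = 0), "singular")
})

test_that("classifier serialization round-trips and scoring is linear", {
  set.seed(24)
  n <- 80
  rec <- make_records(n)
  y <- as.numeric(rec$status == "case")
  tv <- cbind(TA = rnorm(n) + y, TB = rnorm(n))
  d <- make_design(tv, rec)
  fit <- ridge_fit(d, y, lambda = 0.05)
  s1 <- predict_score(fit, d)
  expect_equal(s1, as.numeric(fit$intercept +
                                d$x[, fit$columns] %*%
                                fit$coefficients[fit$columns]))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(predict_score(back, d), s1, tolerance = 1e-12)
  expect_s3_class(back, "cad_classifier")
  expect_output(print(fit), "cad_classifier")
  d_short <- list(x = d$x[, 1:2], penalized = d$penalized[1:2], knot = 60)
  expect_error(predict_score(fit, d_short), "lacks model column")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.5, 0.4, 0.3, 0.2, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
              TRUE, FALSE, TRUE, FALSE)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, auc_pair_oracle(scores, labels), tolerance = 1e-12)
  expect_identical(r$method, "bootstrap")  # both classes < 30
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE))$auc, 0)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "required")
  # string labels accepted
  expect_equal(roc_auc(c(1, 2), c("control", "case"))$auc, 1)
})

test_that("LOOCV separates a separable cohort and stays null under
           label permutation", {
  set.seed(25)
  n <- 60
  rec <- make_records(n)
  y <- as.numeric(rec$status == "case")
  vals <- matrix(rnorm(6 * n, 8, 1), 6, n)
  # planted effect of 5 puts the term-level separation near 5/sqrt(2) SDs,
  # i.e. a true AUC around 0.9998
  vals[1:2, ] <- vals[1:2, ] + 5 * rep(y, each = 2)
  m <- make_expr(vals, samples = rec$id)
  res <- loocv_evaluate(m, rec, .toy_terms(), n_folds = 5, seed = 1)
  expect_gte(res$auc, 0.99)
  expect_true("TA" %in% res$selected_terms)
  expect_identical(res$fold_scheme, "loocv")
  expect_length(res$scores, n)

  # permuted labels: out-of-fold AUC must sit at chance
  rec_perm <- rec
  set.seed(26)
  rec_perm$status <- sample(rec$status)
  res_perm <- loocv_evaluate(m, rec_perm, .toy_terms(), n_folds = 5,
                             seed = 2)
  se_null <- sqrt((n / 2 * 2 + 1) / (12 * (n / 2)^2))  # Mann-Whitney null SD
  expect_lt(abs(res_perm$auc - 0.5), 3 * se_null)
})

test_that("pooled LOOCV is never optimistic on pure-noise cohorts", {
  # Pooled LOOCV scores carry a well-known pessimistic artifact at small n:
  # leaving out a case makes the training set control-heavier, so held-out
  # cases are scored by lower-intercept models (and vice versa), pushing the
  # pooled AUC below 0.5 on null data. The property worth guarding is
  # one-sided: the estimate must not come out optimistic.
  make_noise_terms <- function() {
    lapply(1:6, function(k) {
      term_definition(sprintf("T%02d", k),
                      metagene(sprintf("N%02d", k), sprintf("g%02d", k)),
                      metagene(sprintf("D%02d", k), sprintf("g%02d", k + 6)))
    })
  }
  aucs <- numeric(12)
  for (s in 1:12) {
    set.seed(700 + s)
    n <- 40
    rec <- make_records(n, seed = 700 + s)
    vals <- matrix(rnorm(12 * n, 8, 1), 12, n)
    m <- make_expr(vals, genes = sprintf("g%02d", 1:12), samples = rec$id)
    aucs[s] <- loocv_evaluate(m, rec, make_noise_terms(), n_folds = 5,
                              seed = s)$auc
  }
  expect_lt(mean(aucs), 0.5)

  # the fully nested variant (per-fold re-selection, aggressive min-rule
  # shrinkage) runs end to end and is likewise non-optimistic
  set.seed(799)
  n <- 40
  rec <- make_records(n, seed = 799)
  vals <- matrix(rnorm(12 * n, 8, 1), 12, n)
  m <- make_expr(vals, genes = sprintf("g%02d", 1:12), samples = rec$id)
  res_nested <- suppressWarnings(
    loocv_evaluate(m, rec, make_noise_terms(), reselect_terms = TRUE,
                   n_folds = 5, seed = 1, lambda_rule = "min"))
  se_null <- sqrt((20 + 20 + 1) / (12 * 20 * 20))
  expect_lt(res_nested$auc, 0.5 + 3 * se_null)
})
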