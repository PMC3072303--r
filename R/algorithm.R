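# Algorithm development: meta-genes, ratio terms, the sex/age design matrix,
# LASSO variable selection with sex interactions, Ridge final fits, and
# leave-one-out cross-validated ROC evaluation.

#' Define a meta-gene
#'
#' A meta-gene is a small set (1-4) of correlated genes from one cluster,
#' summarized as a weighted mean of log-scale expression. Weights default to
#' equal and must sum to 1.
#'
#' @param id meta-gene identifier.
#' @param genes character vector of 1-4 member genes.
#' @param weights optional weights (recycled to equal if omitted).
#' @param sign orientation multiplier (+1 or -1).
#' @return A `metagene` list.
#' @export
metagene <- function(id, genes, weights = NULL, sign = 1) {
  if (length(genes) < 1 || length(genes) > 4) {
    stop("a meta-gene contains 1 to 4 genes")
  }
  if (is.null(weights)) weights <- rep(1 / length(genes), length(genes))
  if (length(weights) != length(genes)) {
    stop("weights must match genes in length")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(id = id, genes = genes, weights = weights, sign = sign),
            class = "metagene")
}

#' Define a ratio term
#'
#' A ratio term is the difference of two meta-genes on the log scale
#' (equivalently a ratio on the linear scale), optionally restricted to one
#' sex.
#'
#' @param id term identifier.
#' @param numerator,denominator [metagene()] objects.
#' @param sex `"both"`, `"male_only"` or `"female_only"`.
#' @return A `term_definition` list.
#' @export
term_definition <- function(id, numerator, denominator,
                            sex = c("both", "male_only", "female_only")) {
  sex <- match.arg(sex)
  stopifnot(inherits(numerator, "metagene"), inherits(denominator, "metagene"))
  if (identical(numerator$genes, denominator$genes) &&
      identical(numerator$weights, denominator$weights)) {
    stop("numerator and denominator meta-genes must differ")
  }
  structure(list(id = id, numerator = numerator, denominator = denominator,
                 sex = sex), class = "term_definition")
}

#' Evaluate a meta-gene on every sample
#'
#' @param mat log-scale [expression_matrix()].
#' @param mg a [metagene()].
#' @return named numeric vector (one value per sample).
#' @export
build_metagene <- function(mat, mg) {
  missing <- setdiff(mg$genes, rownames(mat))
  if (length(missing)) {
    stop("meta-gene '", mg$id, "' gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  vals <- unclass(mat)[mg$genes, , drop = FALSE]
  out <- mg$sign * as.numeric(crossprod(vals, mg$weights))
  stats::setNames(out, colnames(mat))
}

#' Evaluate a ratio term on every sample
#'
#' @param mat log-scale [expression_matrix()].
#' @param term a [term_definition()].
#' @return named numeric vector: numerator minus denominator meta-gene.
#' @export
build_term <- function(mat, term) {
  build_metagene(mat, term$numerator) - build_metagene(mat, term$denominator)
}

#' Evaluate a list of terms into an n x k matrix
#' @param mat log-scale [expression_matrix()].
#' @param terms list of [term_definition()].
#' @return samples x terms numeric matrix with term ids as column names.
#' @export
build_term_matrix <- function(mat, terms) {
  cols <- lapply(terms, function(tm) build_term(mat, tm))
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(terms, `[[`, "", "id")
  out
}

#' Assemble the model design matrix
#'
#' Deterministic column order: each term, then (optionally) its
#' male-interaction copy (`term x I(male)`), then the male indicator, the
#' male age column (`age x I(male)`), and the female hinge-age column
#' (`max(age - knot, 0) x I(female)`). The hinge encodes separate slopes for
#' women above and below the knot with the below-knot slope fixed at 0, and
#' is continuous at the knot.
#'
#' @param term_values samples x terms matrix (from [build_term_matrix()]).
#' @param records sample records with `sex` and `age` for every sample.
#' @param knot female age hinge knot, years.
#' @param sex_interactions add a `term:sexM` column per term.
#' @param sex_main include the male-indicator main-effect column (drop it
#'   when sex enters only through the age functions, as in the locked
#'   encoding).
#' @return list: `x` (design matrix), `penalized` (logical per column; age
#'   and sex columns are never penalized), `knot`.
#' @export
make_design <- function(term_values, records, knot = 60,
                        sex_interactions = TRUE, sex_main = TRUE) {
  if (any(is.na(records$age)) || any(is.na(records$sex))) {
    stop("age and sex are required for every sample")
  }
  stopifnot(nrow(term_values) == nrow(records))
  male <- as.numeric(records$sex == "M")
  cols <- list()
  pen <- logical(0)
  for (j in seq_len(ncol(term_values))) {
    nm <- colnames(term_values)[j]
    cols[[nm]] <- term_values[, j]
    pen <- c(pen, TRUE)
    if (sex_interactions) {
      cols[[paste0(nm, ":sexM")]] <- term_values[, j] * male
      pen <- c(pen, TRUE)
    }
  }
  if (sex_main) {
    cols[["sexM"]] <- male
    pen <- c(pen, FALSE)
  }
  cols[["age_male"]] <- records$age * male
  cols[["age_female_hinge"]] <- pmax(records$age - knot, 0) * (1 - male)
  pen <- c(pen, FALSE, FALSE)
  x <- do.call(cbind, cols)
  list(x = x, penalized = pen, knot = knot)
}

.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' LASSO variable selection with sex interactions
#'
#' L1-penalized logistic regression over the term and term-by-sex columns,
#' with the age and sex columns left unpenalized. The shrinkage parameter is
#' estimated by 10-fold cross-validated deviance on outcome-stratified
#' folds; by default the one-standard-error rule is applied (`lambda.1se`),
#' which controls the well-known tendency of the deviance minimizer to drag
#' in noise variables, keeping false selections low at a negligible cost in
#' sensitivity. `lambda_rule = "min"` gives the raw deviance minimizer. A
#' term counts as selected when its main or interaction column has a
#' nonzero coefficient.
#'
#' @param design output of [make_design()].
#' @param outcome logical/0-1 case indicator.
#' @param n_folds number of CV folds.
#' @param seed seed for fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param lambda optional fixed lambda overriding CV (use `Inf` to keep only
#'   unpenalized columns).
#' @return list: `columns` (selected penalized column names), `terms`
#'   (selected term ids), `lambda`, `coef`, `cvfit`.
#' @export
lasso_select <- function(design, outcome, n_folds = 10, seed = 1L,
                         lambda_rule = c("1se", "min"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome is degenerate (one class)")
  if (n_folds < 2) stop("n_folds must be >= 2")
  pf <- ifelse(design$penalized, 1, 0)
  x <- design$x
  if (!is.null(lambda) && is.infinite(lambda)) {
    keep <- colnames(x)[!design$penalized]
    return(list(columns = character(0), terms = character(0),
                lambda = Inf, coef = NULL, cvfit = NULL,
                unpenalized = keep))
  }
  if (is.null(lambda)) {
    foldid <- .stratified_folds(y, n_folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               penalty.factor = pf, foldid = foldid,
                               type.measure = "deviance")
    s_choice <- if (lambda_rule == "1se") "lambda.1se" else "lambda.min"
    lambda <- cvfit[[sub("lambda\\.", "lambda.", s_choice)]]
    cf <- as.matrix(stats::coef(cvfit, s = s_choice))
  } else {
    cvfit <- NULL
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          penalty.factor = pf)
    cf <- as.matrix(stats::coef(fit, s = lambda))
  }
  nz <- rownames(cf)[cf[, 1] != 0]
  sel_cols <- intersect(colnames(x)[design$penalized], nz)
  term_of <- sub(":sexM$", "", sel_cols)
  list(columns = sel_cols, terms = unique(term_of), lambda = lambda,
       coef = cf, cvfit = cvfit,
       unpenalized = colnames(x)[!design$penalized])
}

#' Ridge logistic regression final fit
#'
#' L2-penalized logistic regression on the selected columns plus the
#' unpenalized age/sex columns, with lambda chosen at minimum 10-fold
#' cross-validated deviance (or fixed via `lambda`; `lambda = 0` reduces to
#' unpenalized maximum likelihood and is fit by IRLS directly).
#'
#' @param design output of [make_design()].
#' @param outcome case indicator.
#' @param columns penalized columns to keep (e.g. `lasso_select()$columns`);
#'   unpenalized columns are always retained.
#' @param n_folds,seed CV fold controls.
#' @param lambda optional fixed ridge lambda.
#' @return A `cad_classifier`: intercept, named coefficients, knot, lambda.
#' @export
ridge_fit <- function(design, outcome, columns = NULL, n_folds = 10,
                      seed = 1L, lambda = NULL) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome is degenerate (one class)")
  unpen <- colnames(design$x)[!design$penalized]
  if (is.null(columns)) columns <- colnames(design$x)[design$penalized]
  keep <- c(columns, unpen)
  x <- design$x[, keep, drop = FALSE]
  pf <- ifelse(keep %in% unpen, 0, 1)
  # with no penalized columns left (e.g. an empty selection) the penalty is
  # inert, so the fit reduces to plain maximum likelihood
  if (all(pf == 0)) lambda <- 0
  if (!is.null(lambda) && lambda == 0) {
    qrx <- qr(cbind(1, x))
    if (qrx$rank < ncol(x) + 1) {
      stop("singular design with lambda = 0; use lambda > 0")
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                     family = stats::binomial(),
                     control = list(maxit = 100, epsilon = 1e-12)))
    cf <- fit$coefficients
    intercept <- cf[1]
    coefs <- cf[-1]
  } else if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          penalty.factor = pf,
                          lambda = sort(unique(c(lambda * c(100, 10, 3), lambda)),
                                        decreasing = TRUE),
                          thresh = 1e-10)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
    intercept <- cf[1, 1]
    coefs <- stats::setNames(cf[-1, 1], rownames(cf)[-1])
  } else {
    foldid <- .stratified_folds(y, n_folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                               penalty.factor = pf, foldid = foldid,
                               type.measure = "deviance", thresh = 1e-10)
    lambda <- cvfit$lambda.min
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
    intercept <- cf[1, 1]
    coefs <- stats::setNames(cf[-1, 1], rownames(cf)[-1])
  }
  structure(list(intercept = unname(intercept), coefficients = coefs,
                 columns = keep, knot = design$knot, lambda = lambda,
                 seed = seed),
            class = "cad_classifier")
}

#' Score samples with a fitted classifier
#'
#' @param model a `cad_classifier` from [ridge_fit()].
#' @param design a [make_design()] result over the samples to score.
#' @return numeric linear-predictor scores.
#' @export
predict_score <- function(model, design) {
  missing <- setdiff(model$columns, colnames(design$x))
  if (length(missing)) {
    stop("design lacks model column(s): ", paste(missing, collapse = ", "))
  }
  x <- design$x[, model$columns, drop = FALSE]
  as.numeric(model$intercept + x %*% model$coefficients[model$columns])
}

#' @export
print.cad_classifier <- function(x, ...) {
  cat("cad_classifier:", length(x$coefficients), "coefficients, knot",
      x$knot, "yrs, lambda", format(x$lambda, digits = 4), "\n")
  invisible(x)
}

#' Leave-one-out cross-validated evaluation
#'
#' Each sample is scored by a ridge model refit on the remaining samples,
#' at a ridge lambda estimated once on the full data. By default the term
#' set is selected once on the full data and held fixed across iterations
#' (the development-study protocol, which yields an optimistic estimate);
#' `reselect_terms = TRUE` runs the fully nested variant, repeating LASSO
#' selection inside every leave-one-out fold.
#'
#' @param mat log-scale [expression_matrix()].
#' @param records sample records (status, sex, age).
#' @param terms list of [term_definition()].
#' @param reselect_terms nested re-selection per fold.
#' @param knot female hinge knot.
#' @param n_folds CV folds for the inner lambda estimates.
#' @param seed RNG seed for fold assignment.
#' @param lambda_rule LASSO lambda rule, passed to [lasso_select()].
#' @return list: `scores` (per-sample out-of-fold scores), `auc`, `ci`,
#'   `fold_scheme`, `selected_terms`, `lambda_ridge`.
#' @export
loocv_evaluate <- function(mat, records, terms, reselect_terms = FALSE,
                           knot = 60, n_folds = 10, seed = 1L,
                           lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  records <- .align_records(mat, records)
  n <- nrow(records)
  if (n < 20) stop("need at least 20 samples for LOOCV")
  y <- as.numeric(records$status == "case")
  tv <- build_term_matrix(mat, terms)
  design <- make_design(tv, records, knot = knot)
  sel <- lasso_select(design, y, n_folds = n_folds, seed = seed,
                      lambda_rule = lambda_rule)
  full_ridge <- ridge_fit(design, y, columns = sel$columns,
                          n_folds = n_folds, seed = seed)
  lam <- full_ridge$lambda
  scores <- numeric(n)
  for (i in seq_len(n)) {
    sub_design <- list(x = design$x[-i, , drop = FALSE],
                       penalized = design$penalized, knot = knot)
    cols_i <- sel$columns
    if (reselect_terms) {
      sel_i <- lasso_select(sub_design, y[-i], n_folds = n_folds,
                            seed = seed + i, lambda_rule = lambda_rule)
      cols_i <- sel_i$columns
    }
    fit_i <- ridge_fit(sub_design, y[-i], columns = cols_i, lambda = lam,
                       seed = seed)
    xi <- design$x[i, fit_i$columns, drop = FALSE]
    scores[i] <- fit_i$intercept +
      sum(xi * fit_i$coefficients[fit_i$columns])
  }
  roc <- roc_auc(scores, y == 1)
  list(scores = stats::setNames(scores, records$id), auc = roc$auc,
       ci = c(roc$ci_low, roc$ci_high), fold_scheme = "loocv",
       selected_terms = sel$terms, lambda_ridge = lam)
}

#' ROC AUC with confidence interval
#'
#' AUC by the rank statistic (tied scores credited 0.5), equal to the
#' probability that a random case outscores a random control. The CI uses
#' the DeLong asymptotic variance, switching to a seeded 2,000-replicate
#' stratified bootstrap when either class has fewer than 30 samples.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical (TRUE = case) or case/control strings.
#' @param ci_seed seed for the bootstrap branch.
#' @return list: auc, ci_low, ci_high, method.
#' @export
roc_auc <- function(scores, labels, ci_seed = 1L) {
  if (is.character(labels)) labels <- labels == "case"
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both cases and controls are required for ROC analysis")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  small <- min(sum(labels), sum(!labels)) < 30
  ci <- if (small) {
    set.seed(ci_seed)
    suppressWarnings(pROC::ci.auc(r, method = "bootstrap",
                                  boot.n = 2000, progress = "none"))
  } else {
    pROC::ci.auc(r, method = "delong")
  }
  list(auc = auc, ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
       method = if (small) "bootstrap" else "delong")
}

#' Serialize a fitted classifier to a human-readable file
#'
#' Everything needed to reproduce scoring from the file alone: column names,
#' coefficients, intercept, knot, lambda, and seed, as pretty-printed JSON.
#'
#' @param model a `cad_classifier`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         columns = model$columns, knot = model$knot,
         lambda = model$lambda, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#' @param path file written by [write_model()].
#' @return A `cad_classifier`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 columns = obj$columns, knot = obj$knot,
                 lambda = obj$lambda, seed = obj$seed),
            class = "cad_classifier")
}
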