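# Synthetic cohort generation
#
# The generator emulates the statistical structure the downstream analysis
# assumes in a whole-blood CAD case:control study: cluster-structured
# co-expression driven by latent neutrophil/lymphocyte abundance, disease
# effects that are sex-antagonistic for neutrophil genes and sex-independent
# (down) for lymphocyte genes, an age/sex-dependent case probability, optional
# diabetic attenuation of disease effects, and triplicate PCR wells aggregated
# by median. It makes no attempt to reproduce probe-level microarray
# artifacts, batch effects, or the marginals of any real deposited data set.

.CELL_DRIVERS <- c("neutrophil", "lymphocyte_T", "lymphocyte_B", "NK",
                   "eosinophil", "none")

.check_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a proportion in [0, 1]")
  }
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the algorithm-development study conditions: 640
#' non-diabetic subjects, roughly 36% cases, 58% male, ages around 60,
#' case odds increasing with age and male sex, and a 113-gene RT-PCR-sized
#' panel organized into cell-type-driven co-expression clusters. The
#' neutrophil cluster carries a sex-antagonistic disease shift (up in male
#' cases, down in female cases); lymphocyte clusters are shifted down in
#' cases of both sexes.
#'
#' @param n_samples cohort size.
#' @param case_fraction target marginal case proportion.
#' @param male_fraction proportion of men.
#' @param age_mean,age_sd age distribution (years).
#' @param age_or_per_decade odds ratio linking a 10-year age increase to case
#'   status.
#' @param male_or odds ratio for male sex.
#' @param n_genes panel size.
#' @param cluster_spec data.frame with columns `cluster`, `size`, `driver`
#'   (one of `r paste(.CELL_DRIVERS, collapse = ", ")`), `loading`.
#' @param effect_spec data.frame with columns `cluster`, `shift` (log2 units
#'   added to cases), `sex_interaction` (0 = same shift in both sexes,
#'   1 = antagonistic: `+shift` in male cases, `-shift` in female cases).
#' @param diabetic_fraction proportion of diabetics.
#' @param diabetic_effect_multiplier scalar applied to disease shifts in
#'   diabetics (0 abolishes the association).
#' @param noise_sd residual expression noise, log2 units.
#' @param pcr_replicate_sd triplicate well noise, Ct-like units.
#' @param outlier_rate per-well probability of a +10-unit outlier replicate.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 640,
                              case_fraction = 0.36,
                              male_fraction = 0.58,
                              age_mean = 60, age_sd = 12,
                              age_or_per_decade = 1.7,
                              male_or = 4,
                              n_genes = 113,
                              cluster_spec = default_cluster_spec(),
                              effect_spec = default_effect_spec(),
                              diabetic_fraction = 0,
                              diabetic_effect_multiplier = 0,
                              noise_sd = 1.0,
                              pcr_replicate_sd = 0.15,
                              outlier_rate = 0.01,
                              seed = 1L) {
  .check_prop(case_fraction, "case_fraction")
  .check_prop(male_fraction, "male_fraction")
  .check_prop(diabetic_fraction, "diabetic_fraction")
  .check_prop(outlier_rate, "outlier_rate")
  stopifnot(n_samples >= 2, n_genes >= 1, age_sd > 0, noise_sd >= 0,
            pcr_replicate_sd >= 0, age_or_per_decade > 0, male_or > 0)
  req <- c("cluster", "size", "driver", "loading")
  if (!all(req %in% names(cluster_spec))) {
    stop("cluster_spec needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(cluster_spec$driver %in% .CELL_DRIVERS)) {
    stop("unknown cell-type driver in cluster_spec")
  }
  if (sum(cluster_spec$size) > n_genes) {
    stop("cluster sizes sum to ", sum(cluster_spec$size),
         " which exceeds n_genes = ", n_genes)
  }
  if (!all(c("cluster", "shift", "sex_interaction") %in% names(effect_spec))) {
    stop("effect_spec needs columns: cluster, shift, sex_interaction")
  }
  if (!all(effect_spec$cluster %in% cluster_spec$cluster)) {
    stop("effect_spec refers to unknown cluster id(s)")
  }
  structure(list(
    n_samples = as.integer(n_samples), case_fraction = case_fraction,
    male_fraction = male_fraction, age_mean = age_mean, age_sd = age_sd,
    age_or_per_decade = age_or_per_decade, male_or = male_or,
    n_genes = as.integer(n_genes), cluster_spec = cluster_spec,
    effect_spec = effect_spec, diabetic_fraction = diabetic_fraction,
    diabetic_effect_multiplier = diabetic_effect_multiplier,
    noise_sd = noise_sd, pcr_replicate_sd = pcr_replicate_sd,
    outlier_rate = outlier_rate, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default co-expression cluster layout
#'
#' One large neutrophil block, T/B/NK lymphocyte blocks, a small eosinophil
#' block, and unclustered remainder genes, sized for a 113-gene panel.
#' @return data.frame usable as `cluster_spec`.
#' @export
default_cluster_spec <- function() {
  data.frame(
    cluster = 1:5,
    size = c(30L, 15L, 8L, 8L, 4L),
    driver = c("neutrophil", "lymphocyte_T", "lymphocyte_B", "NK",
               "eosinophil"),
    loading = 0.7,
    stringsAsFactors = FALSE
  )
}

#' Default planted disease effects
#'
#' Neutrophil genes: 0.5 log2-unit shift, antagonistic by sex (up in male
#' cases, down in female cases). Lymphocyte T/B/NK genes: 0.5 log2 units down
#' in cases of both sexes.
#' @return data.frame usable as `effect_spec`.
#' @export
default_effect_spec <- function() {
  data.frame(
    cluster = 1:4,
    shift = c(0.5, -0.5, -0.5, -0.5),
    sex_interaction = c(1L, 0L, 0L, 0L)
  )
}

# Intercept of the case-status logistic model solved so the expected marginal
# case fraction matches the target given the drawn ages and sexes.
.solve_intercept <- function(lp_no_intercept, target) {
  f <- function(b0) mean(stats::plogis(b0 + lp_no_intercept)) - target
  stats::uniroot(f, c(-30, 30))$root
}

#' Generate a synthetic cohort
#'
#' Case status is drawn from a logistic model in age and sex; expression is
#' cluster loading x latent cell-type activity, plus the planted disease
#' shift (sex-resolved, attenuated in diabetics), plus Gaussian noise.
#' Neutrophil and lymphocyte counts are emitted consistent with the latent
#' fractions so count-correlation analyses see the planted structure.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` ([expression_matrix()], log2-scale),
#'   `samples` (sample records), `latent` (per-sample latent profile),
#'   `truth` (per-gene planted cluster, driver, loading and sex-resolved
#'   case shifts).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  age <- pmax(25, pmin(90, stats::rnorm(n, config$age_mean, config$age_sd)))
  lp0 <- log(config$age_or_per_decade) * (age - config$age_mean) / 10 +
    log(config$male_or) * (sex == "M")
  b0 <- .solve_intercept(lp0, config$case_fraction)
  status <- ifelse(stats::runif(n) < stats::plogis(b0 + lp0),
                   "case", "control")
  diabetic <- stats::runif(n) < config$diabetic_fraction

  # Latent cell-type activities: neutrophil and lymphocyte abundance z-scores,
  # with T/B/NK activity sharing the lymphocyte axis (r = 0.7) and eosinophil
  # activity independent.
  z_neut <- stats::rnorm(n)
  z_lym <- stats::rnorm(n)
  mix <- sqrt(1 - 0.7^2)
  activity <- cbind(
    neutrophil = z_neut,
    lymphocyte_T = 0.7 * z_lym + mix * stats::rnorm(n),
    lymphocyte_B = 0.7 * z_lym + mix * stats::rnorm(n),
    NK = 0.7 * z_lym + mix * stats::rnorm(n),
    eosinophil = stats::rnorm(n),
    none = 0
  )
  neut_count <- pmax(0.5, 4.0 + 1.2 * z_neut + stats::rnorm(n, 0, 0.2))
  lym_count <- pmax(0.3, 1.9 + 0.6 * z_lym + stats::rnorm(n, 0, 0.1))

  cs <- config$cluster_spec
  gene_cluster <- rep(NA_integer_, config$n_genes)
  idx <- 1L
  for (k in seq_len(nrow(cs))) {
    gene_cluster[idx:(idx + cs$size[k] - 1L)] <- cs$cluster[k]
    idx <- idx + cs$size[k]
  }
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  driver <- rep("none", config$n_genes)
  loading <- rep(0, config$n_genes)
  in_cl <- !is.na(gene_cluster)
  driver[in_cl] <- cs$driver[match(gene_cluster[in_cl], cs$cluster)]
  loading[in_cl] <- cs$loading[match(gene_cluster[in_cl], cs$cluster)]

  es <- config$effect_spec
  eff_row <- match(gene_cluster, es$cluster)
  shift <- ifelse(is.na(eff_row), 0, es$shift[eff_row])
  inter <- ifelse(is.na(eff_row), 0L, es$sex_interaction[eff_row])
  effect_male <- shift
  effect_female <- ifelse(inter == 1L, -shift, shift)

  baseline <- stats::rnorm(config$n_genes, 8, 1)
  struct <- loading * t(activity[, driver, drop = FALSE])
  case_ind <- as.numeric(status == "case")
  dia_mult <- ifelse(diabetic, config$diabetic_effect_multiplier, 1)
  eff_by_sex <- outer(effect_male, rep(1, n))
  eff_by_sex[, sex == "F"] <- effect_female
  disease <- eff_by_sex * rep(case_ind * dia_mult, each = config$n_genes)
  noise <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                  config$n_genes, n)
  vals <- baseline + struct + disease + noise
  dimnames(vals) <- list(genes, ids)

  samples <- data.frame(
    id = ids, status = status, sex = sex, age = age,
    diabetic = diabetic,
    neutrophil_count = neut_count, lymphocyte_count = lym_count,
    stringsAsFactors = FALSE
  )
  latent <- data.frame(id = ids,
                       neutrophil_z = z_neut, lymphocyte_z = z_lym,
                       activity[, .CELL_DRIVERS[.CELL_DRIVERS != "none"]])
  truth <- data.frame(
    gene = genes, cluster = gene_cluster, driver = driver, loading = loading,
    baseline = baseline,
    effect_male = effect_male, effect_female = effect_female,
    stringsAsFactors = FALSE
  )
  list(expr = expression_matrix(vals, scale = "log2", platform = "rtpcr"),
       samples = samples, latent = latent, truth = truth,
       intercept = b0, config = config)
}

#' Simulate a triplicate RT-PCR panel read
#'
#' Each gene x sample well is measured three times with Gaussian replicate
#' noise; with probability `outlier_rate` a replicate is contaminated by a
#' fixed +10-unit shift. Replicates are aggregated by their median, the
#' standard robust choice for triplicate qPCR.
#'
#' @param truth_expr the underlying [expression_matrix()].
#' @param replicate_sd replicate noise SD (>= 0).
#' @param outlier_rate per-replicate contamination probability.
#' @param seed RNG seed.
#' @param aggregate `"median"` (default) or `"mean"` (for comparison).
#' @return An [expression_matrix()] of aggregated well values.
#' @export
simulate_pcr_panel <- function(truth_expr, replicate_sd = 0.15,
                               outlier_rate = 0.01, seed = 1L,
                               aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  .check_prop(outlier_rate, "outlier_rate")
  set.seed(seed)
  nw <- length(truth_expr)
  reps <- array(stats::rnorm(3L * nw, mean = rep(as.numeric(truth_expr), each = 3L),
                             sd = replicate_sd), dim = c(3L, nw))
  contam <- matrix(stats::runif(3L * nw) < outlier_rate, 3L, nw)
  reps <- reps + 10 * contam
  agg <- if (aggregate == "median") apply(reps, 2, stats::median)
         else colMeans(reps)
  out <- matrix(agg, nrow(truth_expr), ncol(truth_expr),
                dimnames = dimnames(truth_expr))
  expression_matrix(out, scale = attr(truth_expr, "scale"),
                    platform = "rtpcr")
}

#' Greedy age/sex matching of cases to controls
#'
#' Within each sex, cases are taken in ascending age order and each is
#' paired with the youngest unused control whose age lies within
#' `age_tolerance` years (ties broken by sample id). Taking the youngest
#' feasible control rather than the nearest is the earliest-deadline-first
#' rule, which attains the maximum possible number of pairs for this
#' interval-constrained matching (each control's usable window is an age
#' interval on a line). Each sample is used at most once; if no feasible
#' partner exists a case is left unpaired and a warning is raised.
#'
#' @param records sample records with `id`, `status`, `sex`, `age`.
#' @param age_tolerance maximum |age difference| in years.
#' @return data.frame with columns `case_id`, `control_id`, `pair_id`.
#' @export
match_pairs <- function(records, age_tolerance = 5) {
  if (age_tolerance < 0) stop("age_tolerance must be >= 0")
  if (!any(records$status == "case") || !any(records$status == "control")) {
    stop("records must contain both cases and controls")
  }
  pairs <- list()
  for (sx in unique(records$sex)) {
    cases <- records[records$status == "case" & records$sex == sx, ]
    ctrls <- records[records$status == "control" & records$sex == sx, ]
    cases <- cases[order(cases$age, cases$id), ]
    used <- logical(nrow(ctrls))
    for (i in seq_len(nrow(cases))) {
      if (!nrow(ctrls)) break
      feasible <- !used & abs(ctrls$age - cases$age[i]) <= age_tolerance
      j <- which(feasible)
      if (!length(j)) next
      j <- j[order(ctrls$age[j], ctrls$id[j])][1]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        case_id = cases$id[i], control_id = ctrls$id[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(), control_id = character())
  n_possible <- min(sum(records$status == "case"),
                    sum(records$status == "control"))
  if (nrow(out) < n_possible) {
    warning(sprintf("matched %d of %d possible pairs within tolerance",
                    nrow(out), n_possible))
  }
  if (nrow(out)) out$pair_id <- sprintf("P%03d", seq_len(nrow(out)))
  out
}

#' Monte-Carlo Bayes-optimal AUC of a generative configuration
#'
#' Under the generator, expression given status is multivariate normal with a
#' sex-resolved mean shift and factor-structured covariance, and status has
#' an age/sex-dependent prior; the posterior log-odds of case status given
#' expression, age, and sex is therefore linear in expression. This function
#' draws a large fresh cohort, scores it with that optimal discriminant, and
#' returns the resulting AUC — the ceiling any fitted classifier can approach
#' under the same configuration.
#'
#' @param config a [simulation_config()] with `diabetic_fraction = 0`.
#' @param n_mc Monte-Carlo cohort size.
#' @param seed RNG seed for the fresh cohort.
#' @return AUC of the Bayes-optimal score (numeric scalar).
#' @export
bayes_auc <- function(config, n_mc = 20000, seed = 9999L) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$diabetic_fraction > 0) {
    stop("bayes_auc assumes a non-diabetic cohort (diabetic_fraction = 0)")
  }
  big <- config
  big$n_samples <- as.integer(n_mc)
  big$seed <- as.integer(seed)
  class(big) <- "simulation_config"
  sim <- generate_cohort(big)

  # Gene x factor loading matrix over the base latent factors
  # (z_neut, z_lym, and one idiosyncratic factor per lymphoid subtype).
  tr <- sim$truth
  p <- nrow(tr)
  mix <- sqrt(1 - 0.7^2)
  fac <- matrix(0, p, 6,
                dimnames = list(tr$gene,
                                c("z_neut", "z_lym", "eT", "eB", "eNK",
                                  "eEos")))
  fac[tr$driver == "neutrophil", "z_neut"] <-
    tr$loading[tr$driver == "neutrophil"]
  for (dv in c("lymphocyte_T", "lymphocyte_B", "NK")) {
    idio <- c(lymphocyte_T = "eT", lymphocyte_B = "eB", NK = "eNK")[dv]
    fac[tr$driver == dv, "z_lym"] <- 0.7 * tr$loading[tr$driver == dv]
    fac[tr$driver == dv, idio] <- mix * tr$loading[tr$driver == dv]
  }
  fac[tr$driver == "eosinophil", "eEos"] <-
    tr$loading[tr$driver == "eosinophil"]
  sigma <- fac %*% t(fac) + diag(config$noise_sd^2, p)
  sigma_inv <- solve(sigma)

  x <- t(unclass(sim$expr))
  rec <- sim$samples
  prior_lp <- sim$intercept +
    log(config$age_or_per_decade) * (rec$age - config$age_mean) / 10 +
    log(config$male_or) * (rec$sex == "M")
  score <- numeric(nrow(rec))
  for (sx in c("M", "F")) {
    delta <- if (sx == "M") tr$effect_male else tr$effect_female
    w <- sigma_inv %*% delta
    offset <- as.numeric(crossprod(w, tr$baseline + delta / 2))
    rows <- rec$sex == sx
    score[rows] <- x[rows, , drop = FALSE] %*% w - offset
  }
  score <- score + prior_lp
  as.numeric(roc_auc(score, rec$status == "case")$auc)
}

#' Null study configuration (no planted effects)
#'
#' All disease shifts zero; used to measure empirical type-I error of the
#' association tests at nominal alpha.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param seed RNG seed.
#' @return A [simulation_config()].
#' @export
null_simulation_config <- function(n_samples = 400, n_genes = 1000,
                                   seed = 1L) {
  cs <- data.frame(cluster = 1L, size = 0L, driver = "none", loading = 0)
  es <- data.frame(cluster = 1L, shift = 0, sex_interaction = 0L)
  simulation_config(n_samples = n_samples, n_genes = n_genes,
                    cluster_spec = cs, effect_spec = es, seed = seed)
}

#' Recovery study configuration: 15 candidate terms, 6 planted
#'
#' Forty-eight genes in fifteen 3-gene clusters plus a 3-gene unclustered
#' normalization block; disease shifts of +/- `shift` log2 units planted on
#' the first six clusters (sex-independent), residual noise 1.0. These are
#' the conditions under which selection sensitivity/specificity and
#' LOOCV-vs-oracle agreement are assessed.
#'
#' @param seed RNG seed.
#' @param shift planted |shift| in log2 units.
#' @param n_samples cohort size.
#' @return A [simulation_config()].
#' @export
recovery_simulation_config <- function(seed = 1L, shift = 0.5,
                                       n_samples = 600) {
  cs <- data.frame(
    cluster = 1:16, size = c(rep(3L, 15), 3L),
    driver = c(rep(c("neutrophil", "lymphocyte_T", "NK"), 5), "none"),
    loading = c(rep(0.5, 15), 0), stringsAsFactors = FALSE)
  es <- data.frame(cluster = 1:6,
                   shift = shift * c(1, -1, 1, -1, 1, -1),
                   sex_interaction = 0L)
  simulation_config(n_samples = n_samples, n_genes = 48L,
                    cluster_spec = cs, effect_spec = es, noise_sd = 1.0,
                    seed = seed)
}

#' Candidate ratio terms for a recovery cohort
#'
#' One term per 3-gene cluster, each normalized to the unclustered 3-gene
#' block, mirroring meta-gene/normalization-gene ratio construction.
#'
#' @param truth truth table from [generate_cohort()] under
#'   [recovery_simulation_config()].
#' @return list of [term_definition()] (`T01` ... `T15`).
#' @export
recovery_terms <- function(truth) {
  norm_genes <- truth$gene[truth$driver == "none"]
  norm_mg <- metagene("Mnorm", norm_genes)
  lapply(1:15, function(k) {
    gs <- truth$gene[!is.na(truth$cluster) & truth$cluster == k]
    term_definition(sprintf("T%02d", k), metagene(sprintf("M%02d", k), gs),
                    norm_mg)
  })
}
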