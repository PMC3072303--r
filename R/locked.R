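# The locked algorithm: six ratio terms over 23 genes (20 informative, 3
# normalization), with sex-resolved Term 2 normalization (RPL28 for men,
# AQP9/NCF4 for women), a male-only Term 6, a linear male age slope, and a
# female hinge-age slope active above the knot.
#
# Expression input convention: higher value = higher transcript abundance
# (-dCt-like). Raw RT-PCR Ct values are inversely related to abundance and
# must be negated/normalized before scoring.

#' Load the packaged 113-gene RT-PCR panel reference table
#'
#' The published panel annotation: gene symbol (plus accession alias where
#' the assay targets an unnamed transcript), microarray evidence source,
#' cell-type codes (opaque supplied tags), correlation cluster, meta-gene id,
#' and algorithm term component.
#'
#' @param path override the packaged table location.
#' @return data.frame with one row per panel gene.
#' @export
load_panel_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rtpcr_panel.tsv", package = "cadscore")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                          na.strings = NULL)
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]][is.na(df[[nm]])] <- ""
  }
  df$cluster_id <- as.integer(sub("\\..*$", "", df$cluster))
  df
}

.LOCKED_TERM_MAP <- list(
  T1 = list(num = "1a", den = "1b", sex = "both"),
  T2 = list(num = "2a", den = c(M = "2b", F = "2c"), sex = "both"),
  T3 = list(num = "3a", den = "3b", sex = "both"),
  T4 = list(num = "4a", den = "4b", sex = "both"),
  T5 = list(num = "5a", den = "5b", sex = "both"),
  T6 = list(num = "6a", den = "6b", sex = "male_only")
)

.NORMALIZATION_GENES <- c("RPL28", "HNRNPF", "TFCP2")

#' The locked term structure
#'
#' Builds the component-code -> gene-list registry from the packaged panel
#' table (column `algorithm_term`) together with the fixed term map:
#' T1 = 1a - 1b and T3/T4/T5 analogously for both sexes; T2 = 2a normalized
#' to 2b (RPL28) in men and to 2c (AQP9, NCF4) in women; T6 = 6a - 6b in men
#' only. Structural invariants (23 unique genes, 20 informative, 3
#' normalization, 6 terms) are validated at load.
#'
#' @param panel optional pre-loaded [load_panel_table()] result.
#' @return list: `components` (code -> genes), `term_map`, `genes`,
#'   `informative_genes`, `normalization_genes`, `aliases`.
#' @export
locked_term_definitions <- function(panel = load_panel_table()) {
  rows <- panel[nzchar(panel$algorithm_term), , drop = FALSE]
  comp <- list()
  for (i in seq_len(nrow(rows))) {
    for (code in strsplit(rows$algorithm_term[i], ",", fixed = TRUE)[[1]]) {
      code <- trimws(code)
      comp[[code]] <- sort(c(comp[[code]], rows$gene[i]))
    }
  }
  comp <- comp[order(names(comp))]
  genes <- sort(unique(unlist(comp)))
  norm <- intersect(genes, .NORMALIZATION_GENES)
  informative <- setdiff(genes, norm)
  aliases <- stats::setNames(rows$gene[nzchar(rows$alias)],
                             rows$alias[nzchar(rows$alias)])
  structure_ok <- length(genes) == 23 && length(norm) == 3 &&
    length(informative) == 20 && length(.LOCKED_TERM_MAP) == 6 &&
    all(unlist(lapply(.LOCKED_TERM_MAP, function(t) c(t$num, t$den))) %in%
          names(comp))
  if (!structure_ok) {
    stop("locked structure registry failed invariant validation ",
         sprintf("(genes %d, normalization %d, informative %d, terms %d)",
                 length(genes), length(norm), length(informative),
                 length(.LOCKED_TERM_MAP)))
  }
  list(components = comp, term_map = .LOCKED_TERM_MAP, genes = genes,
       informative_genes = informative, normalization_genes = norm,
       aliases = aliases)
}

#' Coefficients of the locked score
#'
#' The published report does not print the numeric score coefficients; they
#' are configurable here, with package defaults derived from a synthetic
#' reference fit (see [locked_default_coefficients()]) and clearly
#' non-clinical. Term weights may be scalars or sex-resolved as
#' `c(M = ..., F = ...)`.
#'
#' @param intercept model intercept.
#' @param weights named list/vector of term weights (`T1` ... `T6`).
#' @param beta_m male age slope, per year.
#' @param beta_f female hinge slope, per year above the knot.
#' @param knot female age knot, years.
#' @param transform optional monotone affine output transform `c(a, b)`
#'   applied as `a * score + b`, with `a > 0`.
#' @return A validated `locked_coefficients` list.
#' @export
locked_coefficients <- function(intercept = 0,
                                weights = list(T1 = 1, T2 = 1, T3 = 1,
                                               T4 = 1, T5 = 1, T6 = 1),
                                beta_m = 0, beta_f = 0, knot = 60,
                                transform = c(a = 1, b = 0)) {
  need <- names(.LOCKED_TERM_MAP)
  if (!all(need %in% names(weights))) {
    stop("weights must name every term: ", paste(need, collapse = ", "))
  }
  vals <- unlist(weights)
  if (!all(is.finite(c(vals, intercept, beta_m, beta_f, knot, transform)))) {
    stop("all coefficients must be finite")
  }
  if (transform[["a"]] <= 0) stop("transform slope a must be > 0")
  structure(list(intercept = intercept, weights = weights, beta_m = beta_m,
                 beta_f = beta_f, knot = knot, transform = transform),
            class = "locked_coefficients")
}

.resolve_weight <- function(w, sex) {
  if (length(w) == 1) return(as.numeric(w))
  as.numeric(w[[sex]])
}

# Map required gene ids onto the matrix rows, resolving accession/symbol
# aliases by exact match on either name.
.resolve_genes <- function(available, needed, aliases) {
  out <- stats::setNames(rep(NA_character_, length(needed)), needed)
  for (g in needed) {
    if (g %in% available) {
      out[g] <- g
    } else {
      alt <- c(names(aliases)[aliases == g], unname(aliases[g]))
      hit <- alt[alt %in% available]
      if (length(hit)) out[g] <- hit[1]
    }
  }
  out
}

#' Per-sample locked term values
#'
#' @param mat log-scale [expression_matrix()] containing the 23 locked genes
#'   (accession/symbol aliases resolve by exact match on either).
#' @param sex character vector (`"M"`/`"F"`) per sample.
#' @param structure a [locked_term_definitions()] registry.
#' @return samples x 6 matrix of term values; T6 is 0 for women, and T2 uses
#'   the male (RPL28) or female (AQP9/NCF4) denominator per sample.
#' @export
locked_term_values <- function(mat, sex, structure = locked_term_definitions()) {
  map <- .resolve_genes(rownames(mat), structure$genes, structure$aliases)
  if (any(is.na(map))) {
    stop("missing locked gene(s): ",
         paste(names(map)[is.na(map)], collapse = ", "))
  }
  if (!all(sex %in% c("M", "F"))) {
    stop("unknown sex code(s): ",
         paste(unique(sex[!sex %in% c("M", "F")]), collapse = ", "))
  }
  vals <- unclass(mat)
  comp_mean <- function(code) {
    rows <- map[structure$components[[code]]]
    colMeans(vals[rows, , drop = FALSE])
  }
  n <- ncol(vals)
  male <- sex == "M"
  out <- matrix(0, n, length(structure$term_map),
                dimnames = list(colnames(vals), names(structure$term_map)))
  for (tm in names(structure$term_map)) {
    def <- structure$term_map[[tm]]
    num <- comp_mean(def$num)
    den <- if (length(def$den) == 1) comp_mean(def$den) else
      ifelse(male, comp_mean(def$den[["M"]]), comp_mean(def$den[["F"]]))
    v <- num - den
    if (def$sex == "male_only") v[!male] <- 0
    if (def$sex == "female_only") v[male] <- 0
    out[, tm] <- v
  }
  out
}

#' Compute the locked algorithm score
#'
#' `score = intercept + sum_t w_t * term_t + beta_m * age * I(male) +
#' beta_f * max(age - knot, 0) * I(female)`, optionally affine-transformed.
#' The female age contribution is 0 below the knot; Term 6 contributes only
#' for men; Term 2 is normalized to RPL28 for men and to AQP9/NCF4 for
#' women.
#'
#' @param expr [expression_matrix()] of the 23 locked genes (or a superset),
#'   or a named numeric vector for a single sample.
#' @param sex `"M"`/`"F"`, length 1 or one per sample.
#' @param age positive ages in years.
#' @param coeffs a [locked_coefficients()].
#' @param structure a [locked_term_definitions()] registry.
#' @return numeric score(s).
#' @export
compute_locked_score <- function(expr, sex, age,
                                 coeffs = locked_default_coefficients(),
                                 structure = locked_term_definitions()) {
  if (is.vector(expr)) {
    expr <- expression_matrix(matrix(expr, ncol = 1,
                                     dimnames = list(names(expr), "s1")),
                              scale = "log2", platform = "rtpcr")
  }
  n <- ncol(expr)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
  tv <- locked_term_values(expr, sex, structure)
  male <- sex == "M"
  score <- rep(coeffs$intercept, n)
  for (tm in colnames(tv)) {
    w <- vapply(seq_len(n), function(i) {
      .resolve_weight(coeffs$weights[[tm]], sex[i])
    }, numeric(1))
    score <- score + w * tv[, tm]
  }
  score <- score + coeffs$beta_m * age * male +
    coeffs$beta_f * pmax(age - coeffs$knot, 0) * (!male)
  as.numeric(coeffs$transform[["a"]] * score + coeffs$transform[["b"]])
}

#' Score a cohort with the locked algorithm
#'
#' Vectorized application of [compute_locked_score()]; identical to
#' per-sample calls. When `status` is present in the records, ROC analysis
#' of the scores against status is attached.
#'
#' @param mat [expression_matrix()] covering the locked genes.
#' @param records sample records with `sex`, `age` (and optionally `status`).
#' @param coeffs a [locked_coefficients()].
#' @param structure a [locked_term_definitions()] registry.
#' @return data.frame (id, score, sex, age, term values), with a `roc`
#'   attribute when status is available.
#' @export
score_batch <- function(mat, records, coeffs = locked_default_coefficients(),
                        structure = locked_term_definitions()) {
  records <- .align_records(mat, records)
  tv <- locked_term_values(mat, records$sex, structure)
  scores <- compute_locked_score(mat, records$sex, records$age, coeffs,
                                 structure)
  out <- data.frame(id = records$id, score = scores, sex = records$sex,
                    age = records$age, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tv))
  if ("status" %in% names(records) &&
      length(unique(records$status)) == 2) {
    attr(out, "roc") <- roc_auc(scores, records$status == "case")
  }
  out
}

#' Synthetic reference cohort over the locked gene panel
#'
#' Generates a cohort whose 23 gene ids are the locked panel genes, with
#' cluster/driver structure and planted case shifts that mirror the locked
#' term design: the Term 1 numerator genes up-regulated and denominator
#' genes down-regulated in cases (neutrophil-driven), Term 2 numerator genes
#' up-regulated with CAD-insensitive neutrophil normalizers, lymphoid T/B/NK
#' blocks shifted down, and the three normalization genes flat. Used to
#' derive the package's default (non-clinical) coefficients and as a
#' self-consistent scoring fixture.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @return As [generate_cohort()], with rows renamed to the locked genes.
#' @export
locked_reference_cohort <- function(n = 640, seed = 20260L) {
  structure_ <- locked_term_definitions()
  comp <- structure_$components
  gene_order <- c(comp$`1a`, comp$`1b`, comp$`2a`, comp$`2c`, "RPL28",
                  comp$`3a`, comp$`3b`, comp$`4a`, comp$`5a`, comp$`6a`,
                  comp$`5b`)
  stopifnot(length(gene_order) == 23, !anyDuplicated(gene_order))
  sizes <- c(length(comp$`1a`), length(comp$`1b`), length(comp$`2a`),
             length(comp$`2c`), 1L,
             length(comp$`3a`), length(comp$`3b`), length(comp$`4a`),
             1L, 1L, length(comp$`5b`))
  cs <- data.frame(
    cluster = seq_along(sizes), size = sizes,
    driver = c("neutrophil", "neutrophil", "neutrophil", "neutrophil",
               "lymphocyte_T", "NK", "lymphocyte_T", "lymphocyte_B",
               "none", "none", "none"),
    loading = c(rep(0.7, 8), 0, 0, 0.3),
    stringsAsFactors = FALSE)
  es <- data.frame(
    cluster = seq_along(sizes),
    shift = c(0.4, -0.4, 0.5, 0, 0, -0.3, -0.1, 0.3, 0.3, 0.3, 0),
    sex_interaction = 0L)
  cfg <- simulation_config(n_samples = n, n_genes = 23L,
                           cluster_spec = cs, effect_spec = es,
                           noise_sd = 0.6, seed = seed)
  sim <- generate_cohort(cfg)
  rownames(sim$expr) <- gene_order
  sim$truth$gene <- gene_order
  sim
}

.locked_default_cache <- new.env(parent = emptyenv())

#' Default (non-clinical) locked coefficients
#'
#' The published report does not print the locked score's numeric
#' coefficients, so the package derives defaults by Ridge-fitting the locked
#' term structure (plus sex-specific age terms) on the packaged synthetic
#' reference cohort at a recorded seed. These defaults make the locked score
#' fully runnable and self-consistent but carry no clinical meaning; any
#' user-supplied [locked_coefficients()] overrides them.
#'
#' @param seed recorded seed of the reference cohort.
#' @return A `locked_coefficients` object.
#' @export
locked_default_coefficients <- function(seed = 20260L) {
  key <- as.character(seed)
  if (!is.null(.locked_default_cache[[key]])) {
    return(.locked_default_cache[[key]])
  }
  sim <- locked_reference_cohort(seed = seed)
  structure_ <- locked_term_definitions()
  tv <- locked_term_values(sim$expr, sim$samples$sex, structure_)
  # sex enters only through the sex-resolved terms and the age functions,
  # matching the locked encoding
  design <- make_design(tv, sim$samples, knot = 60,
                        sex_interactions = FALSE, sex_main = FALSE)
  y <- as.numeric(sim$samples$status == "case")
  model <- ridge_fit(design, y, n_folds = 10, seed = seed)
  cf <- model$coefficients
  out <- locked_coefficients(
    intercept = model$intercept,
    weights = as.list(cf[names(.LOCKED_TERM_MAP)]),
    beta_m = unname(cf["age_male"]),
    beta_f = unname(cf["age_female_hinge"]),
    knot = 60)
  .locked_default_cache[[key]] <- out
  out
}

#' Structural counts of the locked algorithm and panel
#'
#' Recomputed by parsing the packaged panel table: panel genes, correlation
#' clusters, meta-genes, algorithm terms, and unique/informative/
#' normalization gene counts of the locked structure.
#'
#' @param panel optional pre-loaded [load_panel_table()] result.
#' @return named list of counts.
#' @export
locked_structure_counts <- function(panel = load_panel_table()) {
  structure_ <- locked_term_definitions(panel)
  mg <- panel$metagene[nzchar(panel$metagene) & panel$metagene != "Norm"]
  list(
    n_panel_genes = nrow(panel),
    n_clusters = length(unique(panel$cluster_id)),
    n_metagenes = length(unique(mg)),
    n_terms = length(structure_$term_map),
    n_algorithm_genes = length(structure_$genes),
    n_informative_genes = length(structure_$informative_genes),
    n_normalization_genes = length(structure_$normalization_genes)
  )
}
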