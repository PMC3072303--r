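# Panel selection: correlation clustering of candidate genes, cell-type
# annotation from count/marker correlations, normalization-gene screening,
# sex-stratified direction summaries, and greedy RT-PCR panel assembly.

#' Agglomerative correlation clustering of genes
#'
#' Distance is `1 - Pearson r` across all samples (cases and controls
#' pooled), average linkage, with the tree cut at height `1 - corr_cutoff`.
#' Cluster labels are invariant to gene input order and to per-gene positive
#' affine transforms. Constant genes, whose correlation is undefined, are
#' returned as singletons with a warning.
#'
#' @param mat log-scale [expression_matrix()] (genes x samples).
#' @param corr_cutoff correlation cutoff in (0, 1); genes whose average
#'   linkage correlation exceeds it end up in one cluster.
#' @return data.frame: cluster, gene, medoid, mean_intra_cor.
#' @export
cluster_genes <- function(mat, corr_cutoff = 0.7) {
  if (corr_cutoff <= 0 || corr_cutoff >= 1) {
    stop("corr_cutoff must be in (0, 1)")
  }
  if (nrow(mat) < 2) stop("need at least 2 genes")
  vals <- unclass(mat)
  sds <- apply(vals, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("constant gene(s) assigned to singleton clusters: ",
            paste(rownames(vals)[const], collapse = ", "))
  }
  live <- vals[!const, , drop = FALSE]
  memb <- integer(0)
  if (nrow(live) >= 2) {
    cc <- stats::cor(t(live))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    memb <- stats::cutree(hc, h = 1 - corr_cutoff)
  } else if (nrow(live) == 1) {
    memb <- stats::setNames(1L, rownames(live))
  }
  # stable relabeling: clusters numbered by first gene occurrence in the
  # sorted gene-id order, so labels do not depend on input order
  genes_sorted <- sort(rownames(vals))
  lab <- stats::setNames(rep(NA_integer_, nrow(vals)), rownames(vals))
  lab[names(memb)] <- memb
  next_id <- max(c(0L, memb))
  for (g in genes_sorted[const[match(genes_sorted, rownames(vals))]]) {
    next_id <- next_id + 1L
    lab[g] <- next_id
  }
  first_seen <- lab[genes_sorted]
  relab <- stats::setNames(seq_along(unique(first_seen)), unique(first_seen))
  lab <- as.integer(relab[as.character(lab)])
  names(lab) <- rownames(vals)

  out <- lapply(sort(unique(lab)), function(k) {
    members <- sort(names(lab)[lab == k])
    if (length(members) >= 2) {
      sub <- stats::cor(t(vals[members, , drop = FALSE]))
      mean_r <- vapply(seq_along(members), function(j) {
        mean(sub[j, -j])
      }, numeric(1))
      medoid <- members[which.max(mean_r)]
      intra <- mean(sub[upper.tri(sub)])
    } else {
      medoid <- members
      intra <- NA_real_
    }
    data.frame(cluster = k, gene = members, medoid = medoid,
               mean_intra_cor = intra, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cell-type annotation of genes by count and marker correlation
#'
#' A gene is tagged with a cell type when the absolute Pearson correlation of
#' its expression with the corresponding blood count (neutrophil or
#' lymphocyte) or with a supplied marker gene of that type reaches
#' `corr_threshold`; the sign of the correlation is recorded. Tags supplied
#' directly through `supplied` are passed through with evidence `supplied`.
#'
#' @param mat [expression_matrix()].
#' @param records sample records with `neutrophil_count` and
#'   `lymphocyte_count` (missing counts skip count evidence with a warning).
#' @param marker_map optional named character vector: marker gene id -> tag.
#' @param corr_threshold absolute correlation threshold.
#' @param supplied optional named character vector gene -> tag.
#' @return data.frame: gene, tag, evidence, r (NA for supplied tags).
#' @export
assign_cell_types <- function(mat, records, marker_map = NULL,
                              corr_threshold = 0.3, supplied = NULL) {
  records <- .align_records(mat, records)
  vals <- unclass(mat)
  rows <- list()
  add <- function(gene, tag, evidence, r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, tag = tag, evidence = evidence, r = r,
      stringsAsFactors = FALSE)
  }
  counts <- list(neutrophil = records$neutrophil_count,
                 lymphocyte = records$lymphocyte_count)
  for (ct in names(counts)) {
    if (is.null(counts[[ct]]) || all(is.na(counts[[ct]]))) {
      warning("missing ", ct, " counts: count-correlation evidence skipped")
      next
    }
    r <- suppressWarnings(
      as.numeric(stats::cor(t(vals), counts[[ct]],
                            use = "pairwise.complete.obs")))
    hit <- which(!is.na(r) & abs(r) >= corr_threshold)
    for (i in hit) add(rownames(vals)[i], ct, "count-correlation", r[i])
  }
  for (mk in names(marker_map)) {
    if (!mk %in% rownames(vals)) next
    r <- suppressWarnings(
      as.numeric(stats::cor(t(vals), vals[mk, ],
                            use = "pairwise.complete.obs")))
    hit <- setdiff(which(!is.na(r) & abs(r) >= corr_threshold),
                   match(mk, rownames(vals)))
    for (i in hit) {
      add(rownames(vals)[i], unname(marker_map[mk]), "marker-correlation",
          r[i])
    }
  }
  for (g in names(supplied)) add(g, unname(supplied[g]), "supplied", NA_real_)
  tagged <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), tag = character(),
               evidence = character(), r = numeric())
  untagged <- setdiff(rownames(vals), tagged$gene)
  if (length(untagged)) {
    tagged <- rbind(tagged, data.frame(gene = untagged, tag = "none",
                                       evidence = "none", r = NA_real_))
  }
  tagged[order(tagged$gene, tagged$tag), , drop = FALSE]
}

#' Screen and rank normalization-gene candidates
#'
#' Keeps genes with low variance (at or below the `var_quantile_max`
#' variance quantile), moderate-to-high expression (mean within the
#' `expr_quantile_range` quantile band), and no significant association (at
#' level `alpha`) with case status, sex, age, or either cell count. Survivors
#' are ranked by variance, ascending.
#'
#' @param mat [expression_matrix()].
#' @param records sample records.
#' @param var_quantile_max variance quantile cutoff (default 0.25).
#' @param expr_quantile_range mean-expression quantile band (default
#'   c(0.25, 0.95)).
#' @param alpha screening level for the association tests.
#' @return data.frame of candidates ranked by variance, with a `diagnostics`
#'   attribute counting exclusions per filter.
#' @export
select_normalization_candidates <- function(mat, records,
                                            var_quantile_max = 0.25,
                                            expr_quantile_range = c(0.25, 0.95),
                                            alpha = 0.05) {
  stopifnot(var_quantile_max > 0, var_quantile_max <= 1,
            length(expr_quantile_range) == 2)
  records <- .align_records(mat, records)
  vals <- unclass(mat)
  v <- apply(vals, 1, stats::var)
  m <- rowMeans(vals)
  pass_var <- v <= stats::quantile(v, var_quantile_max)
  qr_ <- stats::quantile(m, expr_quantile_range)
  pass_expr <- m >= qr_[1] & m <= qr_[2]

  y_status <- as.numeric(records$status == "case")
  y_sex <- as.numeric(records$sex == "M")
  screens <- list(status = y_status, sex = y_sex, age = records$age,
                  neutrophil_count = records$neutrophil_count,
                  lymphocyte_count = records$lymphocyte_count)
  p_assoc <- matrix(1, nrow(vals), length(screens),
                    dimnames = list(rownames(vals), names(screens)))
  for (s in names(screens)) {
    yv <- screens[[s]]
    if (is.null(yv) || all(is.na(yv))) next
    for (i in seq_len(nrow(vals))) {
      x <- vals[i, ]
      if (stats::sd(x) == 0) next
      if (s %in% c("status", "sex")) {
        X <- cbind(1, x)
        fit <- suppressWarnings(
          stats::glm.fit(X, yv, family = stats::binomial(),
                         control = list(maxit = 25)))
        names(fit$coefficients) <- c("(Intercept)", "expr")
        p_assoc[i, s] <- .wald_from_fit(fit, "expr")$p
      } else {
        p_assoc[i, s] <- stats::cor.test(x, yv)$p.value
      }
    }
  }
  pass_assoc <- apply(p_assoc >= alpha, 1, all)
  keep <- pass_var & pass_expr & pass_assoc
  out <- data.frame(gene = rownames(vals), variance = v, mean_expr = m,
                    min_assoc_p = apply(p_assoc, 1, min),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$variance, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  excl <- c(variance = sum(!pass_var), expression = sum(!pass_expr),
            association = sum(!pass_assoc))
  attr(out, "diagnostics") <- excl
  if (!nrow(out)) {
    warning("no candidates passed; most exclusions by filter '",
            names(excl)[which.max(excl)], "'")
  }
  out
}

#' Sex-stratified case-vs-control direction tally
#'
#' Within each sex, the sign of the case-minus-control mean expression
#' difference is recorded per gene and tallied as up/down counts. Absent
#' strata are reported as missing.
#'
#' @param mat [expression_matrix()].
#' @param records sample records.
#' @param genes gene subset (default: all).
#' @return list with `per_gene` (gene, sex, diff, direction) and `tally`
#'   (sex, n_up, n_down).
#' @export
sex_stratified_direction <- function(mat, records, genes = rownames(mat)) {
  records <- .align_records(mat, records)
  vals <- unclass(mat)[genes, , drop = FALSE]
  per <- list()
  for (sx in c("M", "F")) {
    in_sex <- records$sex == sx
    if (!any(in_sex)) {
      warning("no samples of sex ", sx, "; stratum reported missing")
      next
    }
    cases <- in_sex & records$status == "case"
    ctrls <- in_sex & records$status == "control"
    if (!any(cases) || !any(ctrls)) {
      warning("sex ", sx, " lacks a case or control group; stratum missing")
      next
    }
    dd <- rowMeans(vals[, cases, drop = FALSE]) -
      rowMeans(vals[, ctrls, drop = FALSE])
    per[[sx]] <- data.frame(gene = genes, sex = sx, diff = dd,
                            direction = ifelse(dd > 0, "up",
                                               ifelse(dd < 0, "down", "none")),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, per)
  tally <- do.call(rbind, lapply(per, function(df) {
    data.frame(sex = df$sex[1], n_up = sum(df$direction == "up"),
               n_down = sum(df$direction == "down"))
  }))
  rownames(tally) <- NULL
  list(per_gene = per_gene, tally = tally)
}

#' Greedy RT-PCR panel assembly
#'
#' First the smallest-p gene of every cluster is taken (cluster coverage),
#' then remaining slots are filled by priority flag and then by ascending p,
#' with lexicographic gene-id tie-breaks throughout, until `panel_size`.
#'
#' @param assoc association results (gene, p_unadj at minimum).
#' @param clusters output of [cluster_genes()].
#' @param priority optional character vector of literature-flagged genes.
#' @param panel_size target panel size.
#' @return character vector of selected genes, cluster representatives first.
#' @export
select_panel <- function(assoc, clusters, priority = character(0),
                         panel_size) {
  df <- merge(clusters[, c("cluster", "gene")],
              assoc[, c("gene", "p_unadj")], by = "gene", all.x = TRUE)
  df$p_unadj[is.na(df$p_unadj)] <- 1
  df <- df[order(df$p_unadj, df$gene), , drop = FALSE]
  reps <- df[!duplicated(df$cluster), , drop = FALSE]
  reps <- reps[order(reps$p_unadj, reps$gene), , drop = FALSE]
  n_cl <- length(unique(df$cluster))
  if (panel_size < n_cl) {
    warning("panel_size ", panel_size, " < ", n_cl,
            " clusters; truncating cluster coverage by best-gene p")
    return(reps$gene[seq_len(panel_size)])
  }
  selected <- reps$gene
  rest <- df[!df$gene %in% selected, , drop = FALSE]
  rest$prio <- as.integer(!rest$gene %in% priority)  # 0 = flagged first
  rest <- rest[order(rest$prio, rest$p_unadj, rest$gene), , drop = FALSE]
  c(selected, rest$gene)[seq_len(min(panel_size, nrow(df)))]
}
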