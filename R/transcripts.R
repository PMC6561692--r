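#' CPM-normalize a count matrix
#'
#' Counts per million: `cpm = 1e6 * count / library size`, with the
#' library size defaulting to the sample column sum.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups factor or character vector of group labels per sample
#'   (must contain `"sham"` for downstream contrasts).
#' @param lib_sizes optional positive library sizes per sample.
#' @return object of class `expression_matrix`: `cpm`, `groups`,
#'   `lib_sizes`.
#' @export
cpm_normalize <- function(counts, groups, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (length(groups) != ncol(counts))
    stopf("`groups` must have one label per sample column")
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stopf("library sizes must be positive")
  cpm <- sweep(counts, 2, lib_sizes, `/`) * 1e6
  structure(list(cpm = cpm,
                 groups = if (is.factor(groups)) groups
                          else factor(groups, levels = unique(groups)),
                 lib_sizes = lib_sizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, groups: %s\n",
              nrow(x$cpm), ncol(x$cpm),
              paste(levels(x$groups), collapse = ", ")))
  invisible(x)
}

#' Drop low-expression genes
#'
#' Genes with an aggregate expression level of at most `min_cpm` are
#' excluded to avoid technical artifacts; the boundary is exclusive-keep
#' (aggregate CPM of exactly `min_cpm` is dropped). Aggregation is the
#' mean CPM over all samples by default.
#'
#' @param em an `expression_matrix`.
#' @param min_cpm exclusion level (default 5).
#' @param aggregate `"mean"` (default) or `"max"` across samples.
#' @return filtered `expression_matrix`; attributes `n_kept` / `n_dropped`
#'   report the filtering.
#' @export
filter_low_expression <- function(em, min_cpm = 5,
                                  aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  agg <- switch(aggregate, mean = rowMeans(em$cpm),
                max = apply(em$cpm, 1, max))
  keep <- agg > min_cpm
  out <- em
  out$cpm <- em$cpm[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-gene fold changes of each post-stroke group versus sham
#'
#' Fold change is the average CPM of a group divided by the average CPM of
#' the sham group, with a pseudocount added to both means to keep zero
#' means defined (`fc = (mean_g + eps) / (mean_sham + eps)`).
#'
#' @param em an `expression_matrix` whose groups contain `"sham"`.
#' @param pseudocount `eps` in CPM units (default 0.5).
#' @return list of gene x group matrices `fc` and `log2_fc` over the
#'   non-sham groups.
#' @export
fold_changes <- function(em, pseudocount = 0.5) {
  if (!"sham" %in% em$groups) stopf("sham group missing")
  post <- setdiff(levels(droplevels(em$groups)), "sham")
  sham_mean <- rowMeans(em$cpm[, em$groups == "sham", drop = FALSE])
  fc <- sapply(post, function(g) {
    gm <- rowMeans(em$cpm[, em$groups == g, drop = FALSE])
    (gm + pseudocount) / (sham_mean + pseudocount)
  })
  fc <- matrix(fc, nrow = nrow(em$cpm),
               dimnames = list(rownames(em$cpm), post))
  list(fc = fc, log2_fc = log2(fc))
}

## vectorized Welch two-sample t-test on the rows of two matrices;
## returns two-sided p-values. Rows where both groups are constant get
## p = 1 on equal means and NA otherwise (caller falls back).
row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- NA_real_
  p
}

## exact (or sampled) two-sided permutation test on a mean difference
perm_test <- function(a, b, max_exact = 20000, n_mc = 10000) {
  obs <- abs(mean(a) - mean(b))
  v <- c(a, b); n1 <- length(a); n <- length(v)
  if (choose(n, n1) <= max_exact) {
    cmb <- utils::combn(n, n1)
    stat <- apply(cmb, 2, function(i)
      abs(mean(v[i]) - mean(v[-i])))
    mean(stat >= obs - 1e-12)
  } else {
    stat <- replicate(n_mc, {
      i <- sample(n, n1)
      abs(mean(v[i]) - mean(v[-i]))
    })
    (1 + sum(stat >= obs - 1e-12)) / (1 + n_mc)
  }
}

#' Call significantly differentially expressed genes over the time course
#'
#' For every post-stroke group, each gene is tested against sham with a
#' pluggable two-group test on `log2(CPM + 0.5)`, p-values are adjusted
#' per group comparison with the Benjamini-Hochberg step-up procedure,
#' and a gene is an SDEG in a group when `fdr < fdr_alpha` and
#' `|log2 FC| >= lfc_min`. The default test is the empirical-Bayes
#' moderated t of limma, the standard choice at the few-samples-per-group
#' scale of such studies (per-gene Welch variances are too unstable at
#' n = 5 and cost substantial power after BH); a plain Welch t-test and an
#' exact permutation test are shipped alternatives. Genes with degenerate
#' within-group variance under `"welch"` fall back to the permutation
#' test.
#'
#' @param em an `expression_matrix` (typically after
#'   [filter_low_expression()]).
#' @param test `"moderated"` (limma eBayes), `"welch"`, `"permutation"`,
#'   or a function `f(group_matrix, sham_matrix)` returning per-row
#'   p-values.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1.5).
#' @param pseudocount CPM pseudocount for logs and fold changes.
#' @return object of class `sdeg_table`: a data.frame with per-group
#'   columns `fc_<g>`, `log2_fc_<g>`, `p_<g>`, `fdr_<g>`, `sdeg_<g>` and a
#'   per-gene `sdeg` flag (SDEG in at least one group).
#' @export
call_sdegs <- function(em, test = c("moderated", "welch", "permutation"),
                       fdr_alpha = 0.05, lfc_min = 1.5,
                       pseudocount = 0.5) {
  testfun <- NULL
  if (is.function(test)) testfun <- test
  else test <- match.arg(test)
  post <- setdiff(levels(droplevels(em$groups)), "sham")
  n_sham <- sum(em$groups == "sham")
  if (n_sham < 2) stopf("at least 2 sham samples required")
  lg <- log2(em$cpm + pseudocount)
  sham_m <- lg[, em$groups == "sham", drop = FALSE]
  fcs <- fold_changes(em, pseudocount)
  out <- data.frame(gene = rownames(em$cpm) %||%
                      paste0("g", seq_len(nrow(em$cpm))),
                    stringsAsFactors = FALSE)
  any_sdeg <- rep(FALSE, nrow(out))
  for (g in post) {
    if (sum(em$groups == g) < 2)
      stopf("at least 2 samples required in group %s", g)
    gm <- lg[, em$groups == g, drop = FALSE]
    p <- if (!is.null(testfun)) {
      testfun(gm, sham_m)
    } else if (test == "moderated") {
      design <- cbind(baseline = 1,
                      grp = rep(1:0, c(ncol(gm), ncol(sham_m))))
      fit <- limma::eBayes(limma::lmFit(cbind(gm, sham_m), design))
      unname(fit$p.value[, "grp"])
    } else if (test == "welch") {
      pw <- row_welch(gm, sham_m)
      for (i in which(is.na(pw)))          # degenerate variance fallback
        pw[i] <- perm_test(gm[i, ], sham_m[i, ])
      pw
    } else {
      vapply(seq_len(nrow(gm)), function(i)
        perm_test(gm[i, ], sham_m[i, ]), numeric(1))
    }
    fdr <- p.adjust(p, method = "BH")
    l2 <- fcs$log2_fc[, g]
    flag <- fdr < fdr_alpha & abs(l2) >= lfc_min
    out[[paste0("fc_", g)]] <- fcs$fc[, g]
    out[[paste0("log2_fc_", g)]] <- l2
    out[[paste0("p_", g)]] <- p
    out[[paste0("fdr_", g)]] <- fdr
    out[[paste0("sdeg_", g)]] <- flag
    any_sdeg <- any_sdeg | flag
  }
  out$sdeg <- any_sdeg
  attr(out, "groups") <- post
  attr(out, "fdr_alpha") <- fdr_alpha
  attr(out, "lfc_min") <- lfc_min
  class(out) <- c("sdeg_table", "data.frame")
  out
}

#' Group-mean expression profiles
#'
#' @param em an `expression_matrix`.
#' @param log2_scale take `log2(CPM + pseudocount)` first (default TRUE).
#' @param pseudocount CPM pseudocount.
#' @return gene x group matrix of group means, groups in factor order.
#' @export
group_profiles <- function(em, log2_scale = TRUE, pseudocount = 0.5) {
  m <- if (log2_scale) log2(em$cpm + pseudocount) else em$cpm
  gs <- levels(droplevels(em$groups))
  prof <- sapply(gs, function(g)
    rowMeans(m[, em$groups == g, drop = FALSE]))
  matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), gs))
}

#' Cluster SDEG expression profiles into temporal patterns
#'
#' Row-standardizes each gene's group-mean profile (z-score across
#' groups), clusters with agglomerative hierarchical clustering (Euclidean
#' distance, complete linkage by default), cuts the tree into `k`
#' clusters, and labels every cluster from its centroid: with `s` the sham
#' value, `e` the mean over 4 and 7 dpi minus `s` and `l` the mean over 28
#' and 42 dpi minus `s`, a centroid is `persistent-down` (e and l both
#' below `-tau`), `late-up` (l above `tau`, e not), `late-down` (l below
#' `-tau`, e not), `early-up` (e above `tau`, l not), otherwise `other`.
#'
#' @param profiles gene x group matrix of group-mean expression (e.g.
#'   [group_profiles()] restricted to SDEGs); column names must include
#'   `"sham"` and the dpi labels.
#' @param k number of clusters (default 4).
#' @param linkage hclust agglomeration method (default `"complete"`).
#' @param tau centroid labeling threshold in z-score units (default 0.5).
#' @return list with `cluster` (integer per gene), `pattern` (label per
#'   gene), `cluster_labels`, `centroids` and the `hclust` tree.
#' @export
cluster_patterns <- function(profiles, k = 4, linkage = "complete",
                             tau = 0.5) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k)
    stopf("fewer SDEG profiles (%d) than clusters (%d)", nrow(profiles), k)
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0))
    stopf("%d profile(s) are constant across groups and cannot be standardized",
          sum(sds == 0))
  z <- (profiles - rowMeans(profiles)) / sds
  if (nrow(unique(z)) < k)
    stopf("fewer than %d distinct standardized profiles", k)
  tree <- hclust(dist(z), method = linkage)
  cl <- cutree(tree, k = k)
  centroids <- t(sapply(seq_len(k), function(i)
    colMeans(z[cl == i, , drop = FALSE])))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  labels <- apply(centroids, 1, label_centroid, tau = tau)
  list(cluster = cl, pattern = unname(labels[cl]),
       cluster_labels = labels, centroids = centroids, tree = tree)
}

label_centroid <- function(cen, tau = 0.5) {
  gs <- names(cen)
  s <- cen[["sham"]]
  e <- mean(cen[gs %in% c("4", "7")]) - s
  l <- mean(cen[gs %in% c("28", "42")]) - s
  if (e < -tau && l < -tau) "persistent-down"
  else if (l > tau && e <= tau) "late-up"
  else if (l < -tau && e >= -tau) "late-down"
  else if (e > tau && l <= tau) "early-up"
  else "other"
}

#' Read a count matrix with its sample sheet
#'
#' Counts as TSV (genes in rows, first column gene ids) and a sample sheet
#' CSV with columns `sample, group`.
#'
#' @param counts_path TSV path.
#' @param samples_path CSV path.
#' @return list with `counts` matrix and `groups` factor aligned to its
#'   columns.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  ss <- read.csv(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(ss)))
    stopf("sample sheet must have columns sample, group")
  miss <- setdiff(colnames(counts), ss$sample)
  if (length(miss))
    stopf("samples missing from sheet: %s", paste(miss, collapse = ", "))
  groups <- ss$group[match(colnames(counts), ss$sample)]
  list(counts = counts, groups = factor(groups, levels = unique(ss$group)))
}
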