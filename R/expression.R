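#' Coefficient of variation, in percent
#'
#' Sample (n-1) standard deviation divided by the mean, times 100.
#' Genes with non-positive mean expression get the `NA` marker.
#'
#' @param values numeric vector of expression values (length >= 2).
#' @return CV in percent, or `NA`.
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
#' @export
cv_percent <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Log2 fold-change screen between two sample groups
#'
#' Computes `log2(mean_b + pc) - log2(mean_a + pc)` per gene and flags
#' genes whose absolute log2 ratio reaches the cutoff.  With
#' `floor_exclusion` on, genes whose group means are both below `floor`
#' are excluded from calling (low-expression filter).
#'
#' @param values numeric matrix, genes x samples.
#' @param group_a,group_b disjoint character vectors of sample columns.
#' @param log2_cutoff absolute log2 fold-change cutoff (default 1).
#' @param floor_exclusion exclude genes with both group means < `floor`.
#' @param floor expression floor for the exclusion rule (default 1).
#' @param pseudocount added before log2 (default 1; use 0 for
#'   already-logged data).
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `log2fc`,
#'   `excluded`, `direction` (`"up"`/`"down"`/`"none"`), `flag`.
#' @export
fold_change_screen <- function(values, group_a, group_b, log2_cutoff = 1,
                               floor_exclusion = TRUE, floor = 1,
                               pseudocount = 1) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  ma <- rowMeans(values[, group_a, drop = FALSE])
  mb <- rowMeans(values[, group_b, drop = FALSE])
  lfc <- log2(mb + pseudocount) - log2(ma + pseudocount)
  excluded <- floor_exclusion & ma < floor & mb < floor
  flag <- !excluded & abs(lfc) >= log2_cutoff
  data.frame(gene = rownames(values), mean_a = ma, mean_b = mb,
             log2fc = lfc, excluded = excluded,
             direction = ifelse(!flag, "none",
                                ifelse(lfc > 0, "up", "down")),
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

# Two-class unpaired SAM d-statistic for every gene at once.
sam_d_stat <- function(values, is_b, s0) {
  na <- sum(!is_b); nb <- sum(is_b)
  ma <- rowMeans(values[, !is_b, drop = FALSE])
  mb <- rowMeans(values[, is_b, drop = FALSE])
  ssa <- rowSums((values[, !is_b, drop = FALSE] - ma)^2)
  ssb <- rowSums((values[, is_b, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(d = (mb - ma) / (s + s0), s = s)
}

#' SAM-style permutation screen for differential expression
#'
#' Two-class unpaired moderated statistic
#' `d = (mean_b - mean_a) / (s + s0)` with pooled per-gene standard error
#' `s` and the fudge constant `s0 = median(s)`.  False-discovery
#' q-values are estimated by label permutation: at each observed |d|
#' threshold the expected number of null genes beyond it (mean over
#' permutations) is divided by the observed count, and the resulting
#' rates are made monotone non-increasing in |d|.
#'
#' @param values numeric matrix, genes x samples.
#' @param labels two-level factor (or vector) of group membership, one
#'   per sample column.
#' @param n_permutations number of label permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @param q_cutoff flagging cutoff on q (default 0.01).
#' @return data.frame with `gene`, `d`, `s`, `q`, `flag`, sorted as the
#'   input genes.
#' @export
sam_test <- function(values, labels, n_permutations = 200, seed = 1,
                     q_cutoff = 0.01) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (any(table(labels) < 2)) stop("need >= 2 samples per group")
  is_b <- labels == levels(labels)[2]
  n <- ncol(values)
  if (choose(n, sum(is_b)) < 2) stop("fewer than 2 permutable arrangements")
  s_raw <- sam_d_stat(values, is_b, 0)$s
  s0 <- stats::median(s_raw)
  d_obs <- sam_d_stat(values, is_b, s0)$d

  # relabelings identical to the original grouping (or its complement)
  # carry the signal and cannot estimate the null; resample them away
  perm_counts <- with_seed(seed, {
    sapply(seq_len(n_permutations), function(k) {
      pb <- sample(is_b)
      tries <- 0
      while ((all(pb == is_b) || all(pb == !is_b)) && tries < 100) {
        pb <- sample(is_b); tries <- tries + 1
      }
      abs(sam_d_stat(values, pb, s0)$d)
    })
  })
  ord <- order(-abs(d_obs))
  thresholds <- abs(d_obs)[ord]
  # expected null counts and observed counts beyond each threshold
  expected <- vapply(thresholds, function(t) mean(colSums(perm_counts >= t)),
                     0)
  observed <- seq_along(thresholds)
  fdr <- pmin(1, expected / observed)
  q_sorted <- rev(cummin(rev(fdr)))  # monotone non-increasing in |d|
  q <- numeric(length(d_obs))
  q[ord] <- q_sorted
  data.frame(gene = rownames(values) %||% seq_along(d_obs),
             d = d_obs, s = s_raw, q = q, flag = q < q_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-way ANOVA with interaction
#'
#' Fixed-effects two-way analysis of variance with interaction for every
#' gene of a complete, balanced design with replicates, followed by
#' Benjamini-Hochberg adjustment of each effect's p-values across genes.
#'
#' @param values numeric matrix, genes x samples.
#' @param factor_a,factor_b factors (or vectors), one level per sample
#'   column.
#' @param adjust multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return data.frame with per-gene F statistics, raw p-values and
#'   adjusted p-values for factor A, factor B and the interaction.
#' @export
two_way_anova <- function(values, factor_a, factor_b, adjust = "BH") {
  fa <- as.factor(factor_a); fb <- as.factor(factor_b)
  counts <- table(fa, fb)
  if (any(counts == 0)) stop("incomplete design: empty cell(s)")
  if (length(unique(as.vector(counts))) != 1)
    stop("unbalanced design: unequal cell counts")
  if (counts[1] < 2) stop("design without replicates")
  res <- t(apply(values, 1, function(y) {
    a <- stats::anova(stats::aov(y ~ fa * fb))
    c(a[["F value"]][1:3], a[["Pr(>F)"]][1:3])
  }))
  out <- data.frame(gene = rownames(values) %||% seq_len(nrow(values)),
                    F_a = res[, 1], F_b = res[, 2], F_ab = res[, 3],
                    p_a = res[, 4], p_b = res[, 5], p_ab = res[, 6],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$padj_a <- stats::p.adjust(out$p_a, adjust)
  out$padj_b <- stats::p.adjust(out$p_b, adjust)
  out$padj_ab <- stats::p.adjust(out$p_ab, adjust)
  out
}

#' Expression correlation of duplicated gene pairs
#'
#' Pearson correlation of the two genes' expression profiles over the
#' shared samples; pairs with a gene absent from the matrix, or with a
#' zero-variance profile, get the `NA` marker.
#'
#' @param values numeric matrix, genes x samples (>= 3 samples).
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return the input pairs with an added `pcc` column.
#' @export
duplicate_pair_pcc <- function(values, pairs) {
  stopifnot(ncol(values) >= 3)
  pairs$pcc <- vapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(values)) || !(gb %in% rownames(values)))
      return(NA_real_)
    xa <- values[ga, ]; xb <- values[gb, ]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
    stats::cor(xa, xb)
  }, 0)
  pairs
}

#' Per-condition log2 ratio between two splice isoforms
#'
#' For each (isoform-1, isoform-2) transcript pair and each condition,
#' computes `log2(mean(isoform1) + pc) - log2(mean(isoform2) + pc)` over
#' the condition's samples.
#'
#' @param values numeric matrix, transcripts x samples.
#' @param pairs data.frame with columns `t1`, `t2` (transcript ids).
#' @param conditions factor (or vector) of condition labels, one per
#'   sample column.
#' @param pseudocount added before log2 (default 1).
#' @return numeric matrix, pairs x conditions, of log2 ratios.
#' @export
isoform_fold_change <- function(values, pairs, conditions, pseudocount = 1) {
  conditions <- as.factor(conditions)
  out <- matrix(NA_real_, nrow(pairs), nlevels(conditions),
                dimnames = list(paste(pairs$t1, pairs$t2, sep = "/"),
                                levels(conditions)))
  for (i in seq_len(nrow(pairs))) {
    for (cond in levels(conditions)) {
      sel <- conditions == cond
      m1 <- mean(values[pairs$t1[i], sel])
      m2 <- mean(values[pairs$t2[i], sel])
      out[i, cond] <- log2(m1 + pseudocount) - log2(m2 + pseudocount)
    }
  }
  out
}
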