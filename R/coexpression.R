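#' Gene-by-gene Pearson correlation matrix
#'
#' @param values numeric matrix, genes x samples (>= 3 samples).
#'   Zero-variance genes are dropped with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(values) {
  stopifnot(ncol(values) >= 3)
  v <- apply(values, 1, stats::sd)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(values)[v == 0], collapse = ", "))
    values <- values[v > 0, , drop = FALSE]
  }
  if (nrow(values) < 2) stop("fewer than 2 genes with variance")
  stats::cor(t(values))
}

#' Mutual Rank matrix from a correlation matrix
#'
#' For each gene i, partners are ranked by descending correlation (self
#' excluded, rank 1 = most correlated; ties broken by ascending gene
#' id), and `MR(i, j)` is the geometric mean of the two reciprocal
#' ranks.  Low MR means strong, mutual co-expression.
#'
#' @param pcc square symmetric correlation matrix with gene ids as
#'   dimnames.
#' @return list with `mr` (symmetric MR matrix, `NA` diagonal) and
#'   `ranks` (rank of column gene j among row gene i's partners).
#' @export
mutual_rank <- function(pcc) {
  n <- nrow(pcc)
  if (n < 2) stop("need at least 2 genes")
  stopifnot(isSymmetric(unname(as.matrix(pcc)), tol = 1e-8))
  ids <- rownames(pcc) %||% paste0("g", seq_len(n))
  ranks <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    partners <- setdiff(seq_len(n), i)
    ord <- partners[order(-pcc[i, partners], ids[partners])]
    ranks[i, ord] <- seq_along(ord)
  }
  mr <- sqrt(ranks * t(ranks))
  list(mr = mr, ranks = ranks)
}

#' Threshold a Mutual Rank matrix into an edge table
#'
#' Retains undirected edges with `MR < cutoff` (strict; low MR = strong
#' co-expression), each listed once with genes in lexicographic order.
#'
#' @param mr symmetric MR matrix (from [mutual_rank()]).
#' @param cutoff MR cutoff (default 1500).
#' @return data.frame with `gene_a`, `gene_b`, `mr`, sorted by
#'   (gene_a, gene_b).
#' @export
build_network <- function(mr, cutoff = 1500) {
  if (is.list(mr)) mr <- mr$mr
  ids <- rownames(mr)
  idx <- which(upper.tri(mr) & mr < cutoff, arr.ind = TRUE)
  out <- data.frame(
    gene_a = pmin(ids[idx[, 1]], ids[idx[, 2]]),
    gene_b = pmax(ids[idx[, 1]], ids[idx[, 2]]),
    mr = mr[idx], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict colocalised MAPKKK-MKK-MPK cascade triads
#'
#' Enumerates every (MAPKKK, MKK, MPK) triple for which both the
#' MAPKKK-MKK and the MKK-MPK co-expression edges are present and all
#' three genes share the same subcellular localization.  A MAPKKK-MPK
#' edge is not required: cascades may share MKK hubs.
#'
#' @param edges edge table from [build_network()].
#' @param families named vector assigning each gene one of `"MAPKKK"`,
#'   `"MKK"`, `"MPK"`, `"other"`.
#' @param localizations named vector of subcellular localization labels.
#' @return data.frame with `mapkkk`, `mkk`, `mpk`, `localization`,
#'   `mr_kkk_kk`, `mr_kk_k`, sorted by (mapkkk, mkk, mpk).
#' @export
predict_cascades <- function(edges, families, localizations) {
  genes <- unique(c(edges$gene_a, edges$gene_b))
  miss <- setdiff(genes, names(families))
  if (length(miss))
    stop("gene(s) without family label: ", paste(miss, collapse = ", "))
  miss <- setdiff(genes, names(localizations))
  if (length(miss))
    stop("gene(s) without localization: ", paste(miss, collapse = ", "))
  # adjacency with MR lookup in both directions
  nbr <- rbind(edges[, c("gene_a", "gene_b", "mr")],
               stats::setNames(edges[, c("gene_b", "gene_a", "mr")],
                               c("gene_a", "gene_b", "mr")))
  out <- list()
  for (kk in genes[families[genes] == "MKK"]) {
    part <- nbr[nbr$gene_a == kk, ]
    kkk <- part$gene_b[families[part$gene_b] == "MAPKKK"]
    mpk <- part$gene_b[families[part$gene_b] == "MPK"]
    for (a in kkk) for (p in mpk) {
      loc <- localizations[[a]]
      if (loc == localizations[[kk]] && loc == localizations[[p]]) {
        out[[length(out) + 1L]] <- data.frame(
          mapkkk = a, mkk = kk, mpk = p, localization = loc,
          mr_kkk_kk = part$mr[part$gene_b == a][1],
          mr_kk_k = part$mr[part$gene_b == p][1],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(out, list(data.frame(
    mapkkk = character(), mkk = character(), mpk = character(),
    localization = character(), mr_kkk_kk = numeric(),
    mr_kk_k = numeric(), stringsAsFactors = FALSE))))
  res <- res[order(res$mapkkk, res$mkk, res$mpk), , drop = FALSE]
  rownames(res) <- NULL
  res
}
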