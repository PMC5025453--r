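#' Curated duplicate-pair statistics for the Brachypodium MAPKKK family
#'
#' The published statistics of the 15 duplicated BdMAPKKK gene pairs
#' (12 chromosomal-segment duplicates, 3 tandem duplicates): percent
#' protein identity, Ka, Ks, Ka/Ks, divergence time in Myr, duplication
#' type and the expression correlation (PCC; `NA` where no expression
#' was available).  Shipped as reference input for the clock and ratio
#' arithmetic and for the identity-vs-expression meta-statistic.
#'
#' @return data.frame with columns `locus1`, `chr1`, `locus2`, `chr2`,
#'   `identity_pct`, `ka`, `ks`, `kaks`, `t_myr`, `dup_type`, `expr_pcc`.
#' @export
bd_duplicate_pairs <- function() {
  data.frame(
    locus1 = c("BdMAPKKK21", "BdMAPKKK22", "BdMAPKKK23", "BdMAPKKK2",
               "BdMAPKKK26", "BdMAPKKK57", "BdMAPKKK52", "BdMAPKKK38",
               "BdMAPKKK39", "BdMAPKKK56", "BdMAPKKK49", "BdMAPKKK11",
               "BdMAPKKK8", "BdMAPKKK10", "BdMAPKKK26"),
    chr1 = c(4, 5, 5, 1, 1, 3, 3, 2, 2, 3, 3, 2, 2, 2, 1),
    locus2 = c("BdMAPKKK16", "BdMAPKKK17", "BdMAPKKK18", "BdMAPKKK6",
               "BdMAPKKK59", "BdMAPKKK33", "BdMAPKKK35", "BdMAPKKK40",
               "BdMAPKKK42", "BdMAPKKK44", "BdMAPKKK67", "BdMAPKKK7",
               "BdMAPKKK7", "BdMAPKKK7", "BdMAPKKK27"),
    chr2 = c(3, 3, 3, 1, 4, 1, 1, 2, 2, 2, 5, 2, 2, 2, 1),
    identity_pct = c(65.53, 61.15, 73.52, 68.34, 67.59, 67.82, 61.84,
                     83.06, 56.54, 59.33, 51.04, 67.05, 73.56, 88.19,
                     98.14),
    ka = c(0.1927, 0.2864, 0.1511, 0.3325, 0.2313, 0.1978, 0.267,
           0.0954, 0.2911, 0.3391, 0.4184, 0.4393, 0.1977, 0.1085,
           0.0091),
    ks = c(1.2025, 0.8544, 0.7296, 1.9176, 1.4031, 0.8084, 0.8802,
           0.676, 1.3928, 1.519, 1.1184, 1.0533, 0.6532, 0.3825,
           0.1896),
    kaks = c(0.160249, 0.335206, 0.2071, 0.173394, 0.164849, 0.244681,
             0.30334, 0.141124, 0.209003, 0.223239, 0.374106, 0.41707,
             0.302664, 0.28366, 0.047996),
    t_myr = c(98.57, 70.03, 59.80, 157.18, 115.01, 66.26, 72.15, 55.41,
              114.16, 124.51, 91.67, 86.34, 53.54, 31.35, 15.54),
    dup_type = c(rep("CSD", 12), rep("TD", 3)),
    expr_pcc = c(0.94, 0.61, 0.74, NA, NA, 0.75, 0.76, 0.40, 0.45,
                 0.31, NA, 0.09, 0.51, 0.56, 0.81),
    stringsAsFactors = FALSE)
}
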