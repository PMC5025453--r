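test_that("PCC matrix is symmetric with unit diagonal and matches the formula", {
  set.seed(30)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  p <- pcc_matrix(vals)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(1, 20))
  # pairwise-formula oracle
  for (k in 1:15) {
    i <- sample(20, 1); j <- sample(20, 1)
    x <- vals[i, ]; y <- vals[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(p[i, j], r, tolerance = 1e-12)
  }
  vals2 <- rbind(vals, dupA = vals[1, ], negA = -vals[1, ])
  p2 <- pcc_matrix(vals2)
  expect_equal(p2["g01", "dupA"], 1)
  expect_equal(p2["g01", "negA"], -1)
  vals3 <- rbind(vals, flat = rep(2, 10))
  expect_warning(p3 <- pcc_matrix(vals3), "zero-variance.*flat")
  expect_false("flat" %in% rownames(p3))
})

test_that("mutual rank reproduces the hand-ranked 3-gene example", {
  pcc <- matrix(c(1, 0.9, 0.5,
                  0.9, 1, 0.8,
                  0.5, 0.8, 1), 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  mr <- mutual_rank(pcc)$mr
  expect_equal(mr["g1", "g2"], 1)
  expect_equal(mr["g2", "g3"], sqrt(2))
  expect_equal(mr["g1", "g3"], 2)
  expect_true(is.na(mr["g1", "g1"]))
})

test_that("mutual rank equals the pairwise-counting oracle on random matrices", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    vals <- matrix(rnorm(n * 8), n, 8)
    rownames(vals) <- colnames(vals) <- NULL
    rownames(vals) <- sprintf("g%02d", sample(n))
    colnames(vals) <- paste0("s", 1:8)
    pcc <- cor(t(vals))
    mr <- mutual_rank(pcc)$mr
    expect_equal(mr, mr_oracle(pcc))
    # MR properties: symmetric, >= 1 off-diagonal
    expect_equal(mr, t(mr))
    expect_true(all(mr[!is.na(mr)] >= 1))
    # rank rows are permutations of 1..n-1
    ranks <- mutual_rank(pcc)$ranks
    for (i in seq_len(n))
      expect_setequal(ranks[i, -i], seq_len(n - 1))
  }
})

test_that("network thresholding retains MR strictly below the cutoff", {
  set.seed(32)
  vals <- matrix(rnorm(80), 10, 8,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  mr <- mutual_rank(cor(t(vals)))$mr
  expect_equal(nrow(build_network(mr, cutoff = 1)), 0L)       # MR >= 1
  expect_equal(nrow(build_network(mr, cutoff = Inf)), 45L)    # complete
  edges <- build_network(mr, cutoff = 4)
  expect_true(all(edges$mr < 4))
  expect_true(all(edges$gene_a < edges$gene_b))
  # permutation invariance of the edge set (up to relabeling)
  perm <- sample(10)
  mr_p <- mutual_rank(cor(t(vals[perm, ])))$mr
  e2 <- build_network(mr_p, cutoff = 4)
  expect_equal(e2[order(e2$gene_a, e2$gene_b), ],
               edges[order(edges$gene_a, edges$gene_b), ],
               ignore_attr = TRUE)
})

test_that("planted triads have tight MR and survive a cutoff of 5", {
  genes <- sprintf("g%02d", 1:50)
  triad <- c("g05", "g21", "g40")
  sim <- simulate_expression(genes,
                             coexpr = list(triads = list(triad),
                                           triad_cor = 0.95,
                                           n_samples = 30),
                             seed = 11)
  mr <- mutual_rank(pcc_matrix(sim$values))$mr
  expect_lte(mr[triad[1], triad[2]], 5)
  expect_lte(mr[triad[1], triad[3]], 5)
  expect_lte(mr[triad[2], triad[3]], 5)
  edges <- build_network(mr, cutoff = 5)
  pairkeys <- paste(edges$gene_a, edges$gene_b)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- sort(triad[pr])
    expect_true(paste(a[1], a[2]) %in% pairkeys)
  }
})

test_that("cascade prediction matches the triple-loop oracle and Table-4-like fixtures", {
  # fixture shaped like a published cytoplasmic cascade row
  edges <- data.frame(gene_a = c("BdMAPKKK25", "BdMKK3-3", "BdMKK3-3"),
                      gene_b = c("BdMKK3-3", "BdMPK17", "BdMPK9"),
                      mr = c(12, 40, 100))
  fam <- c(BdMAPKKK25 = "MAPKKK", `BdMKK3-3` = "MKK",
           BdMPK17 = "MPK", BdMPK9 = "MPK")
  loc <- c(BdMAPKKK25 = "Cytoplasm", `BdMKK3-3` = "Cytoplasm",
           BdMPK17 = "Cytoplasm", BdMPK9 = "Nucleus")
  tri <- predict_cascades(edges, fam, loc)
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$mapkkk, "BdMAPKKK25")
  expect_equal(tri$mpk, "BdMPK17")   # the nuclear MPK is filtered out
  expect_equal(tri$localization, "Cytoplasm")

  # an MKK hub with 2 MAPKKKs and 2 MPKs, all colocalised -> 4 triads
  edges2 <- data.frame(gene_a = c("A1", "A2", "K", "K"),
                       gene_b = c("K", "K", "P1", "P2"),
                       mr = c(1, 2, 3, 4))
  fam2 <- c(A1 = "MAPKKK", A2 = "MAPKKK", K = "MKK", P1 = "MPK", P2 = "MPK")
  loc2 <- stats::setNames(rep("Cytoplasm", 5), names(fam2))
  expect_equal(nrow(predict_cascades(edges2, fam2, loc2)), 4L)

  expect_error(predict_cascades(edges2, fam2[-1], loc2), "family label")

  # random labelled graphs against the enumeration oracle
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    ids <- sprintf("n%02d", 1:n)
    fams <- stats::setNames(sample(c("MAPKKK", "MKK", "MPK", "other"),
                                   n, TRUE), ids)
    locs <- stats::setNames(sample(c("Cytoplasm", "Nucleus", "Chloroplast"),
                                   n, TRUE), ids)
    all_pairs <- t(combn(ids, 2))
    keep <- runif(nrow(all_pairs)) < 0.3
    edg <- data.frame(gene_a = all_pairs[keep, 1],
                      gene_b = all_pairs[keep, 2],
                      mr = runif(sum(keep), 1, 10))
    got <- predict_cascades(edg, fams, locs)
    want <- triads_oracle(edg, fams, locs)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wantdf <- do.call(rbind, lapply(want, function(x)
        data.frame(mapkkk = x[1], mkk = x[2], mpk = x[3])))
      wantdf <- wantdf[order(wantdf$mapkkk, wantdf$mkk, wantdf$mpk), ]
      expect_equal(got[, c("mapkkk", "mkk", "mpk")], wantdf,
                   ignore_attr = TRUE)
    }
  }
})
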