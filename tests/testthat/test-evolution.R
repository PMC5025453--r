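test_that("global alignment matches brute-force enumeration on tiny inputs", {
  a <- global_align("ACGT", "ACT", align_params())
  expect_equal(a$score, brute_force_align_score("ACGT", "ACT"))
  expect_equal(nchar(a$aligned_a), nchar(a$aligned_b))
  expect_equal(gsub("-", "", a$aligned_a), "ACGT")
  expect_equal(gsub("-", "", a$aligned_b), "ACT")
  # exactly one gap column
  cols_b <- strsplit(a$aligned_b, "")[[1]]
  expect_equal(sum(cols_b == "-"), 1L)

  set.seed(5)
  for (i in 1:25) {
    x <- random_nt(sample(2:6, 1)); y <- random_nt(sample(2:6, 1))
    expect_equal(global_align(x, y, align_params())$score,
                 brute_force_align_score(x, y))
  }
})

test_that("alignment score is symmetric and agrees with an external aligner", {
  set.seed(6)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:100) {
    x <- random_nt(sample(5:40, 1)); y <- random_nt(sample(5:40, 1))
    sxy <- global_align(x, y, align_params())$score
    syx <- global_align(y, x, align_params())$score
    expect_equal(sxy, syx)
    if (i <= 30) {
      # independent route: Biostrings charges open+ext at a gap start,
      # ours open at the start and ext afterwards
      ref <- Biostrings::pairwiseAlignment(
        x, y, type = "global", substitutionMatrix = mat,
        gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
      expect_equal(sxy, ref)
    }
  }
})

test_that("identity and coverage are column-counting statistics", {
  a <- global_align("ACGTACGTAC", "ACGTACGTAC", align_params())
  ic <- pair_identity_coverage(a)
  expect_equal(ic$identity_pct, 100)
  expect_equal(ic$coverage_frac, 1)

  ic2 <- pair_identity_coverage(list(aligned_a = "ACGTACGTAC",
                                     aligned_b = "ACGAACGAAA"))
  expect_equal(ic2$identity_pct, 70)
  expect_equal(ic2$coverage_frac, 1)

  # column-by-column oracle on random alignments
  set.seed(8)
  for (i in 1:20) {
    x <- random_nt(sample(10:50, 1)); y <- random_nt(sample(10:50, 1))
    al <- global_align(x, y, align_params())
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    matches <- sum(ca == cb & ca != "-")
    both <- sum(ca != "-" & cb != "-")
    ic <- pair_identity_coverage(al)
    expect_equal(ic$identity_pct, 100 * matches / length(ca))
    expect_equal(ic$coverage_frac, both / max(nchar(x), nchar(y)))
  }
})

test_that("tandem classification applies thresholds, adjacency and clustering", {
  coords <- data.frame(
    gene = c("k7", "k8", "k9", "k10", "far", "otherchr"),
    chrom = c("2", "2", "2", "2", "2", "3"),
    start = c(100, 200, 300, 400, 9000, 100))
  pairs <- data.frame(
    gene_a = c("k8", "k8", "k7", "k7"),
    gene_b = c("k7", "k9", "far", "otherchr"),
    identity_pct = c(73.56, 65, 90, 95),
    coverage_frac = c(0.9, 0.9, 0.95, 0.95))
  res <- classify_tandem(pairs, coords)
  # only the first pair qualifies: 65% identity fails, "far" is not
  # tightly linked, "otherchr" is on another chromosome
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$gene_a, "k8")
  expect_equal(res$n_events, 1L)

  # three-gene cluster: both qualifying pairs listed, one event counted
  pairs3 <- data.frame(
    gene_a = c("k8", "k8"), gene_b = c("k7", "k9"),
    identity_pct = c(80, 85), coverage_frac = c(0.9, 0.8))
  res3 <- classify_tandem(pairs3, coords)
  expect_equal(nrow(res3$pairs), 2L)
  expect_equal(res3$n_events, 1L)
  expect_equal(unique(res3$pairs$cluster), 1L)

  expect_error(classify_tandem(data.frame(gene_a = "nope", gene_b = "k7",
                                          identity_pct = 99,
                                          coverage_frac = 1),
                               coords), "unknown gene")
})

test_that("codon alignment threads CDS through the protein alignment", {
  cds_a <- "ATGAAATTTGGG"   # MKFG
  cds_b <- "ATGAAAGGG"      # MKG
  aln <- global_align(translate_cds_pub(cds_a), translate_cds_pub(cds_b))
  ca <- codon_align(aln, cds_a, cds_b)
  expect_equal(nchar(ca$codon_a), nchar(ca$codon_b))
  expect_equal(gsub("-", "", ca$codon_a), cds_a)
  expect_equal(gsub("-", "", ca$codon_b), cds_b)
  # the protein gap became one --- codon triplet
  expect_equal(lengths(regmatches(ca$codon_b, gregexpr("---", ca$codon_b))),
               1L)

  # gapless alignment leaves codons unchanged
  aln2 <- global_align("MKF", "MKF")
  ca2 <- codon_align(aln2, "ATGAAATTT", "ATGAAGTTC")
  expect_equal(ca2$codon_a, "ATGAAATTT")
  expect_equal(ca2$codon_b, "ATGAAGTTC")

  # translation mismatch errors with a position
  expect_error(codon_align(aln2, "ATGAAATTT", "ATGCCCTTC"), "residue 2")

  # back-translation consistency on random simulated pairs
  set.seed(9)
  for (i in 1:10) {
    anc <- random_cds(40)
    pair <- simulate_duplicate_pair(anc, 0.15, seed = i)
    pa <- translate_cds_pub(pair$cds_a); pb <- translate_cds_pub(pair$cds_b)
    al <- global_align(pa, pb)
    cal <- codon_align(al, pair$cds_a, pair$cds_b)
    expect_equal(translate_cds_pub(gsub("-", "", cal$codon_a)), pa)
    expect_equal(translate_cds_pub(gsub("-", "", cal$codon_b)), pb)
  }
})

test_that("NG86 reproduces the hand-counted example and its edge cases", {
  same <- strrep("ATGAAA", 5)
  k <- ng86_kaks(same, same)
  expect_equal(k$ka, 0)
  expect_equal(k$ks, 0)
  expect_true(is.na(k$ratio))

  # 10xTTT vs 9xTTT + TTC: S = 10/3, Sd = 1, pS = 0.3
  k2 <- ng86_kaks(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
  expect_equal(k2$ka, 0)
  expect_equal(k2$S, 10 / 3)
  expect_equal(k2$Sd, 1)
  expect_equal(k2$ks, -0.75 * log(0.6), tolerance = 1e-10)
  expect_equal(round(k2$ks, 4), 0.3831)

  expect_error(ng86_kaks("ATGTAAAAA", "ATGTAAAAA"), "stop codon")
  expect_error(ng86_kaks("ATGA", "ATGA"), "divisible")
})

test_that("Ka/Ks ratio and clock dating reproduce the published table", {
  tab <- bd_duplicate_pairs()
  # every printed ratio from printed Ka and Ks, to printed precision
  for (i in seq_len(nrow(tab))) {
    got <- kaks_ratio(tab$ka[i], tab$ks[i])
    digits <- nchar(sub("^[^.]*\\.", "", as.character(tab$kaks[i])))
    expect_equal(round(got, digits), tab$kaks[i])
  }
  # every printed divergence time from printed Ks at lambda = 6.1e-9
  for (i in seq_len(nrow(tab)))
    expect_equal(round(divergence_time(tab$ks[i]), 2), tab$t_myr[i])

  expect_true(is.na(kaks_ratio(0.1, 0)))
  expect_equal(kaks_ratio(0, 0.5), 0)
  # scale invariance
  expect_equal(kaks_ratio(0.12, 0.48), kaks_ratio(1.2, 4.8))
  # linearity in Ks
  expect_equal(divergence_time(0.4), 2 * divergence_time(0.2))
  expect_equal(divergence_time(0), 0)
})

test_that("neighbor joining recovers additive trees exactly", {
  expect_equal(nj_tree(matrix(c(0, 1, 1, 0), 2,
                              dimnames = list(c("A", "B"), c("A", "B")))),
               "(A:0.5,B:0.5);")

  # 4-taxon case against the least-squares topology oracle
  set.seed(12)
  for (rep in 1:20) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.2, 2))
    tr$tip.label <- c("A", "B", "C", "D")[as.integer(sub("t", "",
                                                         tr$tip.label))]
    d <- ape::cophenetic.phylo(tr)[c("A", "B", "C", "D"),
                                   c("A", "B", "C", "D")]
    fits <- c(AB = ls_fit_quartet(d, c("A", "B")),
              AC = ls_fit_quartet(d, c("A", "C")),
              AD = ls_fit_quartet(d, c("A", "D")))
    best_split <- names(which.min(fits))
    out <- ape::read.tree(text = nj_tree(d))
    topo_eq <- function(t1, t2)
      as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0
    got_split <- if (topo_eq(out, ape::read.tree(text = "((A,B),C,D);")))
      "AB" else if (topo_eq(out, ape::read.tree(text = "((A,C),B,D);")))
      "AC" else "AD"
    expect_equal(got_split, best_split)
    # patristic distances reproduce the additive input
    expect_equal(ape::cophenetic.phylo(out)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }

  # n <= 8 random additive trees: exact topology + branch-length recovery
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    out <- ape::read.tree(text = nj_tree(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(out))), 0)
    expect_equal(ape::cophenetic.phylo(out)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }

  dbad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(dbad), "asymmetric")
})

test_that("neutral synonymous simulation gives Ka = 0 and unbiased NG86 Ks", {
  anc <- with_seed_pub(100, random_cds(300))
  ks_hat <- vapply(1:200, function(i) {
    pair <- simulate_duplicate_pair(anc, 0.2, seed = i)
    al <- list(aligned_a = translate_cds_pub(pair$cds_a),
               aligned_b = translate_cds_pub(pair$cds_b))
    ca <- codon_align(al, pair$cds_a, pair$cds_b)
    k <- ng86_kaks(ca$codon_a, ca$codon_b)
    expect_equal(k$ka, 0)
    k$ks
  }, 0)
  expect_gte(mean(ks_hat), 0.17)
  expect_lte(mean(ks_hat), 0.23)
})
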