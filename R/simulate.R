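# Concretize a degenerate signature pattern: pick one residue per
# position (uniformly for alternations / wildcards).
realize_signature <- function(pattern) {
  sets <- parse_signature(pattern)
  paste(vapply(sets, function(s) if (length(s) == 1) s
               else sample(s, 1), ""), collapse = "")
}

random_protein <- function(len) paste(sample(AA_ALPHABET, len, TRUE),
                                      collapse = "")

# Uniform synonymous back-translation of a protein (plus a stop codon).
back_translate <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(aa) {
    opts <- names(GENCODE)[GENCODE == aa]
    if (length(opts) == 0) stop("no codon for residue ", aa)
    sample(opts, 1)
  }, "")
  paste(c(codons, sample(c("TAA", "TGA", "TAG"), 1)), collapse = "")
}

#' Simulate a MAPKKK-like gene family with known truth
#'
#' Generates proteins that each embed exactly one subfamily signature at
#' a position consistent with that subfamily's kinase-domain placement
#' (ZIK: N-terminal domain; Raf: C-terminal domain behind a long
#' N-terminal regulatory region; MEKK: any position), coding sequences
#' that translate to them, multi-exon gene models whose intron counts
#' are drawn from the subfamily's characteristic range (MEKK 0-24,
#' Raf 1-16, ZIK 1-8), and a truth table recording subfamily, domain
#' span and intron phases.
#'
#' @param n_genes number of genes (default 73, the family size the
#'   pipeline was designed around).
#' @param mix named proportions over MEKK/Raf/ZIK (default 24/43/6 of
#'   73); must sum to 1.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param domain_len range of kinase-domain lengths in residues.
#' @param intron_range named list of intron-count ranges per subfamily.
#' @return list with `proteins`, `cds` (named character vectors),
#'   `models` (list of [gene_model()]), and `truth` (data.frame with
#'   gene, subfamily, domain_start, domain_end, length, intron_count).
#' @export
simulate_gene_family <- function(n_genes = 73,
                                 mix = c(MEKK = 24, Raf = 43, ZIK = 6) / 73,
                                 seed = 1,
                                 domain_len = c(250, 262),
                                 intron_range = list(MEKK = c(0, 24),
                                                     Raf = c(1, 16),
                                                     ZIK = c(1, 8))) {
  stopifnot(n_genes >= 1, abs(sum(mix) - 1) < 1e-8,
            setequal(names(mix), c("MEKK", "Raf", "ZIK")))
  sigs <- kinase_signatures()
  with_seed(seed, {
    fams <- sample(names(mix), n_genes, TRUE, prob = mix)
    fams <- sort(fams)  # stable ordering, then shuffled ids below
    proteins <- character(n_genes); cds <- character(n_genes)
    models <- list(); truth <- list()
    gpos <- 1000L
    for (g in seq_len(n_genes)) {
      fam <- fams[g]
      dlen <- sample(domain_len[1]:domain_len[2], 1)
      if (fam == "ZIK") {
        n_ter <- sample(0:40, 1)
        c_ter <- sample(10:400, 1)
      } else if (fam == "Raf") {
        c_ter <- sample(0:60, 1)
        n_ter <- sample(150:1000, 1)
        # guarantee the long-N-terminal rule holds
        len0 <- n_ter + dlen + c_ter
        while (n_ter < 0.3 * len0) { n_ter <- n_ter + 100L
          len0 <- n_ter + dlen + c_ter }
      } else {
        n_ter <- sample(0:600, 1)
        c_ter <- sample(0:600, 1)
      }
      len <- n_ter + dlen + c_ter
      prot <- random_protein(len)
      # plant the signature inside the domain, near its 3' end (the
      # activation-loop/APE region sits late in kinase domains)
      sig <- realize_signature(sigs[[fam]])
      off <- n_ter + floor(dlen * 0.7)
      substr(prot, off + 1, off + nchar(sig)) <- sig
      # reject accidental extra hits of *other* signatures that would
      # change the classification (rare); resample background if so
      tries <- 0
      repeat {
        hits <- scan_kinase_signature(prot)
        lbl <- classify_subfamily(list(sequence = prot,
                                       kinase_domain = c(n_ter, n_ter + dlen)),
                                  hits)
        if (lbl == fam || tries >= 20) break
        prot <- random_protein(len)
        substr(prot, off + 1, off + nchar(sig)) <- sig
        tries <- tries + 1
      }
      id <- sprintf("SimMAPKKK%02d", g)
      proteins[g] <- prot
      names(proteins)[g] <- id
      cds[g] <- back_translate(prot)
      names(cds)[g] <- id

      # gene structure: cut the spliced length into exons
      n_intr <- sample(intron_range[[fam]][1]:intron_range[[fam]][2], 1)
      utr5 <- sample(0:300, 1); utr3 <- sample(0:500, 1)
      cds_len <- nchar(cds[g])
      spliced <- utr5 + cds_len + utr3
      n_intr <- min(n_intr, spliced - 1L)
      cuts <- if (n_intr > 0) sort(sample(seq_len(spliced - 1L), n_intr))
              else integer()
      bounds <- c(0L, cuts, spliced)
      widths <- diff(bounds)
      introns <- if (n_intr > 0) sample(50:500, n_intr, TRUE) else integer()
      strand <- sample(c("+", "-"), 1)
      gstart <- gpos
      exons <- matrix(0L, n_intr + 1L, 2)
      at <- gstart
      for (e in seq_len(n_intr + 1L)) {
        exons[e, ] <- c(at, at + widths[e])
        at <- at + widths[e] + if (e <= n_intr) introns[e] else 0L
      }
      gpos <- at + 2000L
      # spliced-coordinate CDS interval -> genomic spans
      sp2gen <- function(lo, hi) {  # [lo, hi) in spliced coords (plus sense)
        out <- NULL
        acc <- 0L
        for (e in seq_len(nrow(exons))) {
          w <- exons[e, 2] - exons[e, 1]
          s <- max(lo, acc); t <- min(hi, acc + w)
          if (s < t) out <- rbind(out, c(exons[e, 1] + (s - acc),
                                         exons[e, 1] + (t - acc)))
          acc <- acc + w
        }
        out
      }
      # on the minus strand the 5' UTR sits at the high-coordinate end
      cds_lo <- if (strand == "+") utr5 else utr3
      cds_spans <- sp2gen(cds_lo, cds_lo + cds_len)
      tx <- list(exons = exons, cds = cds_spans)
      tid <- paste0(id, ".1")
      models[[id]] <- gene_model(id, "chrSim1", strand,
                                 stats::setNames(list(tx), tid))
      phases <- intron_phases(models[[id]], tid)
      truth[[g]] <- data.frame(
        gene = id, subfamily = fam, domain_start = n_ter,
        domain_end = n_ter + dlen, length = len,
        intron_count = n_intr,
        phases = paste(ifelse(is.na(phases), "U", phases), collapse = ","),
        stringsAsFactors = FALSE)
    }
    list(proteins = proteins, cds = cds, models = models,
         truth = do.call(rbind, truth))
  })
}

#' Simulate a duplicate pair with a target synonymous divergence
#'
#' Derives a diverged copy of an ancestral CDS by planting synonymous
#' single-nucleotide substitutions only, so the nonsynonymous distance
#' is exactly zero.  Each codon is mutated with probability
#' `p* x S_c`, where `S_c` is the codon's synonymous-site content and
#' `p*` the Jukes-Cantor-inverted target proportion, which centres the
#' NG86 Ks estimate on `target_ks` without further calibration.
#'
#' @param cds ancestral coding sequence; length divisible by 3, no
#'   internal stop codons (a terminal stop is left untouched).
#' @param target_ks target synonymous substitutions per synonymous site.
#' @param seed RNG seed.
#' @return list with `cds_a` (the ancestor) and `cds_b` (the derived
#'   copy).
#' @export
simulate_duplicate_pair <- function(cds, target_ks, seed = 1) {
  if (target_ks < 0) stop("'target_ks' must be >= 0")
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  n_cod <- nchar(cds) / 3
  starts <- seq(1, by = 3, length.out = n_cod)
  codons <- substring(cds, starts, starts + 2)
  aa <- GENCODE[codons]
  if (any(aa[-length(aa)] == "*")) stop("internal stop codon")
  coding <- which(aa != "*")
  if (target_ks == 0) return(list(cds_a = cds, cds_b = cds))
  p_star <- 0.75 * (1 - exp(-4 * target_ks / 3))
  with_seed(seed, {
    out <- codons
    for (i in coding) {
      sc <- syn_sites(codons[i])
      if (sc == 0) next
      if (runif(1) >= min(1, p_star * sc)) next
      fr <- codon_syn_fractions(codons[i])
      pos <- sample(1:3, 1, prob = fr / sum(fr))
      chars <- strsplit(codons[i], "")[[1]]
      alts <- setdiff(NUC, chars[pos])
      syn_alts <- alts[vapply(alts, function(nt) {
        x <- chars; x[pos] <- nt
        GENCODE[[paste(x, collapse = "")]] == GENCODE[[codons[i]]]
      }, TRUE)]
      if (length(syn_alts) == 0) next
      chars[pos] <- if (length(syn_alts) == 1) syn_alts
                    else sample(syn_alts, 1)
      out[i] <- paste(chars, collapse = "")
    }
    list(cds_a = cds, cds_b = paste(out, collapse = ""))
  })
}

#' Simulate an expression compendium with planted signals
#'
#' Builds a genes x samples matrix out of up to three blocks, each with
#' its own samples and metadata: a two-group differential-expression
#' block with planted log2 effects, a multi-condition diurnal block in
#' which chosen genes follow `amplitude * cos(2*pi*(t - phase)/period) +
#' baseline` plus Gaussian noise, and a co-expression block in which
#' planted triads share a latent factor giving a within-triad
#' correlation of `triad_cor`.  Every planted signal is recorded in the
#' truth tables.
#'
#' @param gene_ids gene identifiers (rows).
#' @param de `NULL`, or a list with `effects` (named log2 effect sizes for
#'   the planted genes), `n_per_group` (default 3), `baseline` (default 8)
#'   and `noise_sd` (default 0.5).
#' @param circadian `NULL`, or a list with `plan` (logical genes x
#'   conditions matrix: which gene cycles where), `conditions` (default
#'   LDHH/LDHC/LLHC), `interval`/`duration` in hours (default 4/48),
#'   `period` (24), `amplitude` (5), `noise_sd` (1), `baseline` (10).
#'   Phases are drawn per gene and recorded.
#' @param coexpr `NULL`, or a list with `triads` (list of gene-id
#'   triples), `n_samples` (default 30), `triad_cor` (default 0.95),
#'   `baseline` (10), `scale` (default 2).
#' @param seed RNG seed.
#' @return list with `values`, `samples` (data.frame: sample, block,
#'   condition, time), and `truth` (per-block truth tables).
#' @export
simulate_expression <- function(gene_ids, de = NULL, circadian = NULL,
                                coexpr = NULL, seed = 1) {
  n <- length(gene_ids)
  with_seed(seed, {
    blocks <- list(); meta <- list(); truth <- list()

    if (!is.null(de)) {
      npg <- de$n_per_group %||% 3
      base <- de$baseline %||% 8
      nsd <- de$noise_sd %||% 0.5
      eff <- stats::setNames(rep(0, n), gene_ids)
      eff[names(de$effects)] <- de$effects
      mat <- cbind(
        matrix(base, n, npg) ,
        matrix(base * 2^eff, n, npg))
      mat <- mat + matrix(rnorm(n * 2 * npg, 0, nsd), n)
      colnames(mat) <- c(paste0("de_A_", seq_len(npg)),
                         paste0("de_B_", seq_len(npg)))
      blocks$de <- mat
      meta$de <- data.frame(sample = colnames(mat), block = "de",
                            condition = rep(c("A", "B"), each = npg),
                            time = NA_real_, stringsAsFactors = FALSE)
      truth$de <- data.frame(gene = names(de$effects),
                             log2fc = unname(de$effects),
                             stringsAsFactors = FALSE)
    }

    if (!is.null(circadian)) {
      conds <- circadian$conditions %||% c("LDHH", "LDHC", "LLHC")
      interval <- circadian$interval %||% 4
      duration <- circadian$duration %||% 48
      if (duration %% interval != 0)
        stop("sampling interval must divide duration")
      period <- circadian$period %||% 24
      amp <- circadian$amplitude %||% 5
      nsd <- circadian$noise_sd %||% 1
      base <- circadian$baseline %||% 10
      plan <- circadian$plan
      if (is.null(plan)) plan <- matrix(TRUE, n, length(conds),
                                        dimnames = list(gene_ids, conds))
      tp <- seq(0, duration, by = interval)
      phases <- stats::setNames(sample(0:(period - 1), n, TRUE), gene_ids)
      ctruth <- list()
      for (cond in conds) {
        mat <- matrix(base, n, length(tp))
        for (g in seq_len(n)) {
          if (plan[gene_ids[g], cond])
            mat[g, ] <- mat[g, ] +
              amp * cos(2 * pi * (tp - phases[g]) / period)
        }
        mat <- mat + matrix(rnorm(n * length(tp), 0, nsd), n)
        colnames(mat) <- paste0("circ_", cond, "_t", tp)
        blocks[[paste0("circ_", cond)]] <- mat
        meta[[paste0("circ_", cond)]] <- data.frame(
          sample = colnames(mat), block = "circadian", condition = cond,
          time = tp, stringsAsFactors = FALSE)
        ctruth[[cond]] <- data.frame(
          gene = gene_ids, condition = cond,
          cycling = plan[gene_ids, cond],
          phase = unname(phases), period = period,
          stringsAsFactors = FALSE)
      }
      truth$circadian <- do.call(rbind, ctruth)
    }

    if (!is.null(coexpr)) {
      ns <- coexpr$n_samples %||% 30
      rho <- coexpr$triad_cor %||% 0.95
      base <- coexpr$baseline %||% 10
      scale <- coexpr$scale %||% 2
      z <- matrix(rnorm(n * ns), n)  # independent gene noise
      for (tr in coexpr$triads) {
        f <- rnorm(ns)               # shared latent factor
        for (g in tr)
          z[match(g, gene_ids), ] <- sqrt(rho) * f +
            sqrt(1 - rho) * rnorm(ns)
      }
      mat <- base + scale * z
      colnames(mat) <- paste0("coex_", seq_len(ns))
      blocks$coexpr <- mat
      meta$coexpr <- data.frame(sample = colnames(mat), block = "coexpr",
                                condition = "coexpr", time = NA_real_,
                                stringsAsFactors = FALSE)
      truth$coexpr <- data.frame(
        triad = rep(seq_along(coexpr$triads),
                    lengths(coexpr$triads)),
        gene = unlist(coexpr$triads), cor = rho,
        stringsAsFactors = FALSE)
    }

    values <- do.call(cbind, blocks)
    rownames(values) <- gene_ids
    samples <- do.call(rbind, meta)
    rownames(samples) <- samples$sample
    list(values = values, samples = samples, truth = truth)
  })
}

#' Simulate promoters with planted cis-elements
#'
#' Generates i.i.d. uniform-ACGT background sequences and inserts the
#' requested number of concretized element instances at random
#' non-overlapping positions and strands, recording every insertion.
#'
#' @param n_seqs number of promoter sequences.
#' @param len sequence length in bases (default 2000).
#' @param elements named integer vector: how many instances of each
#'   dictionary element to insert per sequence.
#' @param motifs IUPAC dictionary, see [default_motifs()].
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame: seq_id, motif, start (0-based), strand, instance).
#' @export
simulate_promoters <- function(n_seqs, len = 2000,
                               elements = integer(),
                               motifs = default_motifs(), seed = 1) {
  motifs <- validate_motifs(motifs)
  stopifnot(all(names(elements) %in% names(motifs)))
  with_seed(seed, {
    seqs <- character(n_seqs)
    truth <- list()
    for (i in seq_len(n_seqs)) {
      id <- sprintf("prom%03d", i)
      s <- paste(sample(NUC, len, TRUE), collapse = "")
      used <- matrix(numeric(), ncol = 2)
      for (nm in names(elements)) {
        k <- nchar(motifs[[nm]])
        for (j in seq_len(elements[[nm]])) {
          repeat {
            start <- sample(0:(len - k), 1)
            if (!any(start < used[, 2] & start + k > used[, 1])) break
          }
          used <- rbind(used, c(start, start + k))
          inst <- paste(vapply(strsplit(motifs[[nm]], "")[[1]],
                               function(ch) {
                                 set <- IUPAC_SETS[[ch]]
                                 if (length(set) == 1) set else sample(set, 1)
                               }, ""), collapse = "")
          strand <- sample(c("+", "-"), 1)
          planted <- if (strand == "+") inst else revcomp(inst)
          substr(s, start + 1, start + k) <- planted
          truth[[length(truth) + 1L]] <- data.frame(
            seq_id = id, motif = nm, start = start, strand = strand,
            instance = inst, stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- s
      names(seqs)[i] <- id
    }
    list(sequences = seqs,
         truth = do.call(rbind, c(truth, list(data.frame(
           seq_id = character(), motif = character(), start = integer(),
           strand = character(), instance = character(),
           stringsAsFactors = FALSE)))))
  })
}
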