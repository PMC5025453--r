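#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list:
#' the alignment thresholds used for duplicate classification, the
#' Mutual-Rank network cutoff, the circadian correlation cutoff, the
#' significance cutoffs of the expression screens, the synonymous
#' molecular-clock rate, and the promoter window length.  Defaults are the
#' values the analyses in this package were designed around.
#'
#' @param identity_pct minimum percent identity for a tandem duplicate pair.
#' @param coverage_frac minimum alignment coverage of the longer gene,
#'   as a fraction in (0, 1].
#' @param mr_cutoff Mutual-Rank cutoff; edges with MR strictly below this
#'   value are retained in co-expression networks.
#' @param circadian_r_cutoff Pearson correlation cutoff for calling a gene
#'   diurnally cycling.
#' @param q_cutoff SAM q-value cutoff.
#' @param p_adj_cutoff adjusted-p cutoff for the two-way ANOVA screen.
#' @param log2fc_cutoffs named numeric vector of absolute log2 fold-change
#'   cutoffs per screen.
#' @param clock_rate_lambda synonymous substitution rate, substitutions per
#'   synonymous site per year, used to date duplications as T = Ks/(2*lambda).
#' @param promoter_len_bp length of the upstream promoter window in bases.
#' @param blast_identity_pct,blast_evalue constants retained for filtering a
#'   user-provided homology-search result (the search itself is out of scope).
#' @param pseudocount value added before log2 in ratio screens; set 0 for
#'   data that is already log-scaled.
#' @param max_intervening maximum number of intervening genes allowed
#'   between members of a tandem duplicate pair.
#' @param motifs named IUPAC consensus dictionary, see [default_motifs()].
#' @param signatures kinase-domain signature set, see [kinase_signatures()].
#' @param seed integer seed from which all randomness is derived.
#' @return a list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$mr_cutoff
#' @export
pipeline_config <- function(identity_pct = 70,
                            coverage_frac = 0.7,
                            mr_cutoff = 1500,
                            circadian_r_cutoff = 0.8,
                            q_cutoff = 0.01,
                            p_adj_cutoff = 0.01,
                            log2fc_cutoffs = c(development = 1, virus = 1,
                                               drought = 1, heat = 0.5),
                            clock_rate_lambda = 6.1e-9,
                            promoter_len_bp = 2000,
                            blast_identity_pct = 50,
                            blast_evalue = 1e-5,
                            pseudocount = 1,
                            max_intervening = 1,
                            motifs = default_motifs(),
                            signatures = kinase_signatures(),
                            seed = 1L) {
  cfg <- list(identity_pct = identity_pct, coverage_frac = coverage_frac,
              mr_cutoff = mr_cutoff, circadian_r_cutoff = circadian_r_cutoff,
              q_cutoff = q_cutoff, p_adj_cutoff = p_adj_cutoff,
              log2fc_cutoffs = log2fc_cutoffs,
              clock_rate_lambda = clock_rate_lambda,
              promoter_len_bp = promoter_len_bp,
              blast_identity_pct = blast_identity_pct,
              blast_evalue = blast_evalue,
              pseudocount = pseudocount,
              max_intervening = max_intervening,
              motifs = motifs, signatures = signatures,
              seed = as.integer(seed))
  for (p in c("q_cutoff", "p_adj_cutoff"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", p))
  if (coverage_frac <= 0 || coverage_frac > 1)
    stop("'coverage_frac' must lie in (0, 1]")
  if (identity_pct < 0 || identity_pct > 100)
    stop("'identity_pct' must lie in [0, 100]")
  if (abs(circadian_r_cutoff) > 1)
    stop("'circadian_r_cutoff' must lie in [-1, 1]")
  if (clock_rate_lambda <= 0) stop("'clock_rate_lambda' must be > 0")
  if (promoter_len_bp <= 0) stop("'promoter_len_bp' must be > 0")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  structure(cfg, class = "pipeline_config")
}
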