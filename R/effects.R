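# Functional-variant selection and per-allele effect sizes.
#
# Coding variants of a selected gene that PolyPhen-2 rates deleterious, and
# non-coding variants within a flanking window of the gene that are eQTLs for
# it, are declared "functional". Coding effect sizes follow
#   beta = percentile(PP2S) * PP2S^2 * rho_g * k * l
# where rho_g is the genetic correlation between the gene's expression and the
# blood-pressure trait, k an overall constant and l a gene-specific constant.
# Non-coding effects are proportional to the observed mRNA-trait correlation:
# beta = corr * k * l.

#' Effect-model configuration
#'
#' @param k Overall constant scaling all effects.
#' @param l_by_gene Named numeric vector of gene-specific constants; genes
#'   absent from it default to `l = 1`.
#' @param window_bp Flanking distance (bp) within which a non-coding eQTL
#'   variant is eligible; must be positive. Default 5000.
#' @param pp2s_deleterious PP2S cutoff at or above which a coding variant
#'   counts as deleterious. Default 0.85.
#' @return A list of class `effect_model_config`.
#' @export
effect_model_config <- function(k = 1, l_by_gene = numeric(), window_bp = 5000,
                                pp2s_deleterious = 0.85) {
  if (window_bp <= 0) stop("window_bp must be positive")
  structure(list(k = k, l_by_gene = l_by_gene, window_bp = window_bp,
                 pp2s_deleterious = pp2s_deleterious),
            class = "effect_model_config")
}

gene_l <- function(cfg, gene) {
  if (gene %in% names(cfg$l_by_gene)) unname(cfg$l_by_gene[[gene]]) else 1
}

#' Select functional variants
#'
#' Returns exactly (a) non-coding variants flagged as eQTLs that lie within
#' `cfg$window_bp` of a listed gene's boundaries, and (b) coding
#' (non-synonymous or highly deleterious) variants of listed genes whose PP2S
#' is at or above the deleterious cutoff. All other variants are silently
#' excluded.
#'
#' @param variants Variant table (`chrom`, `pos`, `gene`, `annotation`,
#'   `pp2s`).
#' @param gene_table Data frame of selected genes: `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive gene boundaries).
#' @param eqtl_flags Logical vector, one per variant: is the variant associated
#'   with its gene's expression level.
#' @param cfg An [effect_model_config()].
#' @return The selected subset of `variants`, with a `functional_class` column
#'   (`"coding"` / `"noncoding"`) and row indices into the input in
#'   `orig_index`.
#' @export
select_functional_variants <- function(variants, gene_table, eqtl_flags, cfg) {
  stopifnot(nrow(variants) == length(eqtl_flags))
  coding_ann <- c("synonymous", "nonsynonymous", "highly_deleterious")
  is_coding <- variants$annotation %in% coding_ann
  listed <- !is.na(variants$gene) & variants$gene %in% gene_table$gene

  coding_sel <- is_coding & listed &
    variants$annotation %in% c("nonsynonymous", "highly_deleterious") &
    !is.na(variants$pp2s) & variants$pp2s >= cfg$pp2s_deleterious

  gi <- match(variants$gene, gene_table$gene)
  in_window <- !is.na(gi) &
    variants$chrom == gene_table$chrom[gi] &
    variants$pos >= gene_table$start[gi] - cfg$window_bp &
    variants$pos <= gene_table$end[gi] + cfg$window_bp
  noncoding_sel <- !is_coding & listed & eqtl_flags & in_window

  out <- variants[coding_sel | noncoding_sel, , drop = FALSE]
  out$functional_class <- ifelse(coding_sel[coding_sel | noncoding_sel],
                                 "coding", "noncoding")
  out$orig_index <- which(coding_sel | noncoding_sel)
  out
}

#' Percentiles of ranked PolyPhen-2 scores
#'
#' `rank / n` with average ranks for ties, so values lie in `(0, 1]` and a
#' single score gets percentile 1.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @return Percentiles aligned with `scores`.
#' @export
#' @examples
#' pp2s_percentile(c(0.1, 0.5, 0.9))   # 1/3, 2/3, 1
pp2s_percentile <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  stopifnot(all(scores >= 0 & scores <= 1))
  rank(scores, ties.method = "average") / length(scores)
}

#' Per-allele effect size of a deleterious coding variant
#'
#' `beta = percentile * pp2s^2 * rho_g * k * l`; the sign is carried by
#' `rho_g`, the genetic correlation between the gene's expression and the
#' trait.
#'
#' @param pp2s PolyPhen-2 score in `[0, 1]`.
#' @param percentile Rank percentile of the score in `(0, 1]`.
#' @param rho_g Genetic correlation in `[-1, 1]`.
#' @param k,l Overall and gene-specific constants.
#' @return Per-allele effect in trait units.
#' @export
coding_effect_size <- function(pp2s, percentile, rho_g, k, l) {
  stopifnot(all(pp2s >= 0 & pp2s <= 1), all(abs(rho_g) <= 1))
  percentile * pp2s^2 * rho_g * k * l
}

#' Per-allele effect size of a non-coding (eQTL) variant
#'
#' Linear in the observed mRNA-trait correlation: `beta = corr * k * l`.
#'
#' @param expr_bp_corr Observed correlation between the gene's mRNA level and
#'   the blood-pressure trait, in `[-1, 1]`.
#' @param k,l Overall and gene-specific constants.
#' @return Per-allele effect in trait units.
#' @export
noncoding_effect_size <- function(expr_bp_corr, k, l) {
  stopifnot(all(abs(expr_bp_corr) <= 1))
  expr_bp_corr * k * l
}

#' Phenotypic variance explained by a biallelic additive variant
#'
#' Under Hardy-Weinberg proportions an additive variant with allele frequency
#' `p` and per-allele effect `beta` contributes variance `2 p (1 - p) beta^2`;
#' the returned value is that contribution as a fraction of the total
#' phenotypic variance `sigma2_p`.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @param beta Per-allele effect (trait units per allele).
#' @param sigma2_p Total phenotypic variance (> 0).
#' @return Fraction of variance explained (not a percentage).
#' @export
#' @examples
#' variance_explained(0.34354, -3.93, 88.4)   # ~0.0788
variance_explained <- function(p, beta, sigma2_p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (any(sigma2_p <= 0)) stop("sigma2_p must be positive")
  2 * p * (1 - p) * beta^2 / sigma2_p
}

#' Calibrate a gene-specific constant to a target variance explained
#'
#' Given raw per-allele effects (computed with `l = 1`), finds the scalar `l`
#' such that the gene's summed single-variant variance explained (assuming
#' linkage equilibrium between its variants) equals `target_gene_ve`. Since
#' each variant's contribution scales as `l^2`,
#' `l = sqrt(target / sum_j 2 p_j (1 - p_j) beta_raw_j^2 / sigma2_p)`.
#'
#' @param target_gene_ve Target total fraction of variance explained (>= 0).
#' @param p Allele frequencies of the gene's functional variants.
#' @param beta_raw Raw per-allele effects at `l = 1`.
#' @param sigma2_p Total phenotypic variance.
#' @return The gene constant `l`.
#' @export
calibrate_gene_constant <- function(target_gene_ve, p, beta_raw, sigma2_p) {
  stopifnot(target_gene_ve >= 0, length(p) == length(beta_raw))
  base <- sum(variance_explained(p, beta_raw, sigma2_p))
  if (target_gene_ve == 0) return(0)
  if (base == 0) stop("all raw effects are zero; no gene constant can reach the target")
  sqrt(target_gene_ve / base)
}

#' Build a per-variant effect table
#'
#' Combines selected functional variants with allele frequencies and per-gene
#' expression correlations into per-allele effects for SBP and DBP, plus the
#' variance explained by each variant, mirroring the columns CHROM, POS, GENE,
#' FREQ, BETA_DBP, BETA_SBP, VE_DBP_PCT, VE_SBP_PCT.
#'
#' Coding percentiles are computed by ranking PP2S across all selected coding
#' variants.
#'
#' @param functional Output of [select_functional_variants()].
#' @param freqs Allele frequencies aligned with `functional` rows.
#' @param gene_corr Data frame per gene: `gene`, `rho_g_sbp`, `rho_g_dbp`
#'   (genetic correlations used for coding effects) and `expr_corr_sbp`,
#'   `expr_corr_dbp` (observed mRNA-trait correlations used for non-coding
#'   effects).
#' @param cfg An [effect_model_config()].
#' @param sigma2_sbp,sigma2_dbp Total phenotypic variances used for the VE
#'   columns.
#' @return Data frame with one row per functional variant.
#' @export
build_effect_table <- function(functional, freqs, gene_corr, cfg,
                               sigma2_sbp, sigma2_dbp) {
  stopifnot(nrow(functional) == length(freqs))
  gi <- match(functional$gene, gene_corr$gene)
  if (anyNA(gi)) {
    stop("missing gene correlations for: ",
         paste(unique(functional$gene[is.na(gi)]), collapse = ", "))
  }
  l <- vapply(functional$gene, gene_l, numeric(1L), cfg = cfg)
  coding <- functional$functional_class == "coding"
  pct <- rep(NA_real_, nrow(functional))
  if (any(coding)) pct[coding] <- pp2s_percentile(functional$pp2s[coding])

  beta_for <- function(rho_col, corr_col) {
    b <- numeric(nrow(functional))
    if (any(coding)) {
      b[coding] <- coding_effect_size(functional$pp2s[coding], pct[coding],
                                      gene_corr[[rho_col]][gi[coding]],
                                      cfg$k, l[coding])
    }
    if (any(!coding)) {
      b[!coding] <- noncoding_effect_size(gene_corr[[corr_col]][gi[!coding]],
                                          cfg$k, l[!coding])
    }
    b
  }
  beta_sbp <- beta_for("rho_g_sbp", "expr_corr_sbp")
  beta_dbp <- beta_for("rho_g_dbp", "expr_corr_dbp")
  data.frame(chrom = functional$chrom, pos = functional$pos,
             gene = functional$gene, freq = freqs,
             functional_class = functional$functional_class,
             pp2s = functional$pp2s, pp2s_percentile = pct,
             beta_dbp = beta_dbp, beta_sbp = beta_sbp,
             ve_dbp_pct = 100 * variance_explained(freqs, beta_dbp, sigma2_dbp),
             ve_sbp_pct = 100 * variance_explained(freqs, beta_sbp, sigma2_sbp),
             orig_index = functional$orig_index,
             stringsAsFactors = FALSE)
}

#' Write an effect table as TSV
#'
#' @param effects Output of [build_effect_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  out <- effects[, c("chrom", "pos", "gene", "freq", "beta_dbp", "beta_sbp",
                     "ve_dbp_pct", "ve_sbp_pct")]
  names(out) <- c("CHROM", "POS", "GENE", "FREQ", "BETA_DBP", "BETA_SBP",
                  "VE_DBP_PCT", "VE_SBP_PCT")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
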