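# Bundled reference table of large-effect variants.

#' Published top-20 effect variants for the unrelated-sample simulation
#'
#' The distributed table of the twenty variants with the largest effects on
#' simulated blood pressure in the unrelated exome sample: chromosome,
#' position, gene, non-reference allele frequency, per-allele effects (mmHg
#' per allele) and percent of phenotypic variance explained, for DBP and SBP.
#' A zero beta means the variant was functional for the other trait only.
#'
#' This table is useful as a realistic effect-model input and as an internal
#' consistency check: with total variances of about 88.4 (DBP) and 238.6
#' (SBP) mmHg^2 — derivable from the MAP4 row by inverting
#' `VE = 2 p (1 - p) beta^2 / sigma2` — every row's printed VE is reproduced
#' by [variance_explained()] to within 0.02 percentage points.
#'
#' @return Data frame with columns `chrom`, `pos`, `gene`, `freq`, `beta_dbp`,
#'   `beta_sbp`, `ve_dbp_pct`, `ve_sbp_pct`.
#' @export
#' @examples
#' top <- top_effect_variants()
#' map4 <- top[1, ]
#' s2_dbp <- 2 * map4$freq * (1 - map4$freq) * map4$beta_dbp^2 /
#'   (map4$ve_dbp_pct / 100)
#' round(s2_dbp, 1)   # ~88.4 mmHg^2
top_effect_variants <- function() {
  path <- system.file("extdata", "unrelated_top20_effects.tsv",
                      package = "bpsimr", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(CHROM = "character"))
  names(tab) <- c("chrom", "pos", "gene", "freq", "beta_dbp", "beta_sbp",
                  "ve_dbp_pct", "ve_sbp_pct")
  tab
}

#' Phenotypic variances implied by the bundled effect table
#'
#' Inverts `VE = 2 p (1 - p) beta^2 / sigma2` on the table's first (MAP4) row
#' to recover the total phenotypic variances the printed
#' variance-explained percentages imply.
#'
#' @return Named numeric vector with elements `sigma2_dbp` and `sigma2_sbp`.
#' @export
implied_trait_variances <- function() {
  r <- top_effect_variants()[1L, ]
  w <- 2 * r$freq * (1 - r$freq)
  c(sigma2_dbp = w * r$beta_dbp^2 / (r$ve_dbp_pct / 100),
    sigma2_sbp = w * r$beta_sbp^2 / (r$ve_sbp_pct / 100))
}
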