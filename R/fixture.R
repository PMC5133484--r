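# Synthetic fixture generation: a self-consistent bundle of pedigree,
# genotypes, annotations, gene table, covariates and expression data that
# every command in the package can load. This is the study-conditions
# generator used throughout the test-suite and the worked examples.

#' Generate a synthetic study fixture
#'
#' Builds a multi-family, two-generation cohort: each family has two unrelated
#' founders and `n_children` offspring. Founder genotypes are drawn in
#' Hardy-Weinberg proportions at allele frequencies sampled uniformly from
#' `maf_range` and dropped through the pedigree; variants are laid out across
#' `n_genes` 10-kb genes (plus flanking non-coding variants), with coding
#' variants given PolyPhen-2-like scores (highly deleterious variants score in
#' `[0.9, 1]`) and non-coding variants eQTL flags. Ages are drawn around 45
#' years (clamped to 20-80) and fixed thereafter; expression signals are
#' log-normal with a configurable per-probe detection rate.
#'
#' @param n_families Number of families (default 10).
#' @param n_children Offspring per family (default 4).
#' @param n_variants Number of variants (default 60).
#' @param n_genes Number of genes (default 6).
#' @param maf_range Founder allele-frequency range (default `c(0.05, 0.5)`).
#' @param n_probes Expression probes (default 50); one probe per gene is named
#'   after it so the expression data map onto the gene table.
#' @param detect_rate Probability a probe/sample pair is "detected" (detection
#'   p <= 0.05); default 0.8.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, all components are written as
#'   plain-text files (`fixture.ped`, `fixture.vcf`, `annotations.tsv`,
#'   `gene_table.tsv`, `covariates.tsv`, `expression_signals.tsv`,
#'   `expression_detection.tsv`) and the paths returned.
#' @return List with components `pedigree`, `genotypes`, `annotations`,
#'   `gene_table`, `gene_corr`, `eqtl_flags`, `covariates`, `expression`, and
#'   (when `dir` is given) `paths`.
#' @export
make_fixture <- function(n_families = 10, n_children = 4, n_variants = 60,
                         n_genes = 6, maf_range = c(0.05, 0.5),
                         n_probes = 50, detect_rate = 0.8, seed = 1L,
                         dir = NULL) {
  stopifnot(n_families >= 1, n_children >= 1, n_variants >= n_genes)

  fam <- sprintf("FAM%02d", seq_len(n_families))
  ids <- character(0); fat <- character(0); mot <- character(0)
  sex <- character(0); famv <- character(0)
  child_sex <- with_seed(derive_seed(seed, 21L),
                         sample(c("M", "F"), n_families * n_children,
                                replace = TRUE))
  k <- 0L
  for (f in fam) {
    ids <- c(ids, paste0(f, "_F"), paste0(f, "_M"))
    fat <- c(fat, NA, NA); mot <- c(mot, NA, NA)
    sex <- c(sex, "M", "F"); famv <- c(famv, f, f)
    for (j in seq_len(n_children)) {
      k <- k + 1L
      ids <- c(ids, sprintf("%s_C%d", f, j))
      fat <- c(fat, paste0(f, "_F")); mot <- c(mot, paste0(f, "_M"))
      sex <- c(sex, child_sex[k]); famv <- c(famv, f)
    }
  }
  ped <- pedigree(ids, fat, mot, sex, famv)
  n <- nrow(ped)

  # gene layout on chromosome 1: 10-kb genes every 50 kb
  genes <- sprintf("GENE%d", seq_len(n_genes))
  gene_table <- data.frame(gene = genes, chrom = "1",
                           start = 100000L + 50000L * (seq_len(n_genes) - 1L),
                           end = 110000L + 50000L * (seq_len(n_genes) - 1L),
                           stringsAsFactors = FALSE)

  ann_levels <- c("synonymous", "nonsynonymous", "highly_deleterious",
                  "utr5", "utr3", "other_noncoding")
  vmeta <- with_seed(derive_seed(seed, 22L), {
    gene_of <- rep(genes, length.out = n_variants)
    annotation <- sample(ann_levels, n_variants, replace = TRUE,
                         prob = c(0.25, 0.25, 0.1, 0.1, 0.1, 0.2))
    gi <- match(gene_of, gene_table$gene)
    pos <- integer(n_variants)
    coding <- annotation %in% c("synonymous", "nonsynonymous", "highly_deleterious")
    pos[coding] <- gene_table$start[gi[coding]] +
      sample.int(10000L, sum(coding), replace = TRUE)
    # non-coding variants scattered inside the gene or its 5-kb flanks
    pos[!coding] <- gene_table$start[gi[!coding]] +
      sample(seq(-4999L, 14999L), sum(!coding), replace = TRUE)
    pp2s <- rep(NA_real_, n_variants)
    pp2s[annotation == "nonsynonymous"] <- stats::runif(sum(annotation == "nonsynonymous"))
    pp2s[annotation == "highly_deleterious"] <-
      stats::runif(sum(annotation == "highly_deleterious"), 0.9, 1)
    eqtl <- !coding & stats::runif(n_variants) < 0.5
    data.frame(chrom = "1", pos = pos, ref = "A", alt = "G", gene = gene_of,
               annotation = annotation, pp2s = pp2s, eqtl = eqtl,
               stringsAsFactors = FALSE)
  })
  ord <- order(vmeta$pos)
  vmeta <- vmeta[ord, ]
  rownames(vmeta) <- NULL

  freqs <- with_seed(derive_seed(seed, 23L),
                     stats::runif(n_variants, maf_range[1L], maf_range[2L]))
  gm <- gene_drop(ped, freqs, seed = derive_seed(seed, 24L),
                  variants = vmeta[, c("chrom", "pos", "ref", "alt", "gene",
                                       "annotation", "pp2s")])

  covariates <- with_seed(derive_seed(seed, 25L), {
    age <- pmin(pmax(round(stats::rnorm(n, 45, 12)), 20), 80)
    data.frame(id = ped$id, age = age, sex = ped$sex, stringsAsFactors = FALSE)
  })

  # per-gene expression-trait correlations (inputs to the effect model)
  gene_corr <- with_seed(derive_seed(seed, 26L), {
    rg <- stats::runif(n_genes, -0.6, 0.6)
    data.frame(gene = genes,
               rho_g_sbp = rg, rho_g_dbp = rg * stats::runif(n_genes, 0.7, 1),
               expr_corr_sbp = rg * stats::runif(n_genes, 0.5, 1),
               expr_corr_dbp = rg * stats::runif(n_genes, 0.5, 1),
               stringsAsFactors = FALSE)
  })

  probes <- c(genes, sprintf("PROBE%d", seq_len(max(0L, n_probes - n_genes))))
  expr <- with_seed(derive_seed(seed, 27L), {
    base <- stats::rlnorm(n_probes, meanlog = 6, sdlog = 1)
    sig <- matrix(stats::rlnorm(n_probes * n, meanlog = 0, sdlog = 0.3),
                  n_probes, n) * base
    det <- matrix(ifelse(stats::runif(n_probes * n) < detect_rate,
                         stats::runif(n_probes * n, 0, 0.05),
                         stats::runif(n_probes * n)),
                  n_probes, n)
    dimnames(sig) <- dimnames(det) <- list(probes, ped$id)
    expression_matrix(sig, det)
  })

  out <- list(pedigree = ped, genotypes = gm,
              annotations = vmeta[, c("chrom", "pos", "ref", "alt", "gene",
                                      "annotation", "pp2s")],
              gene_table = gene_table, gene_corr = gene_corr,
              eqtl_flags = vmeta$eqtl, covariates = covariates,
              expression = expr)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      pedigree = file.path(dir, "fixture.ped"),
      vcf = file.path(dir, "fixture.vcf"),
      annotations = file.path(dir, "annotations.tsv"),
      gene_table = file.path(dir, "gene_table.tsv"),
      covariates = file.path(dir, "covariates.tsv"),
      signals = file.path(dir, "expression_signals.tsv"),
      detection = file.path(dir, "expression_detection.tsv"))
    write_pedigree(ped, paths$pedigree)
    write_vcf(gm, paths$vcf)
    ann_out <- out$annotations
    names(ann_out) <- toupper(names(ann_out))
    utils::write.table(ann_out, paths$annotations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(gene_table, paths$gene_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(covariates, paths$covariates, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_expression(expr$signals, paths$signals)
    write_expression(expr$detection_p, paths$detection)
    out$paths <- paths
  }
  out
}
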