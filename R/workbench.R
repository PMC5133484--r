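# End-to-end drivers for the two study designs, YAML configuration, and
# provenance-stamped output.

# FNV-1a 32-bit hash of a character string, reported as 8 hex digits.
# Used only for provenance stamps, not for anything cryptographic.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(h) %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

config_hash <- function(cfg) fnv1a32(yaml::as.yaml(cfg))

#' Read a run configuration from YAML
#'
#' A run configuration has a `design` (`"family"` or `"unrelated"`), a `paths`
#' section (pedigree, vcf, annotations, gene_table, gene_corr, covariates),
#' optional `trait_model` and `effect_model` sections overriding
#' [trait_model()] / [effect_model_config()] defaults, a `seed` and
#' `n_replicates`, and for the unrelated design a `kinship` choice
#' (`"empirical"` or `"identity"`).
#'
#' @param path YAML file path.
#' @return The configuration list, with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$design) || !cfg$design %in% c("family", "unrelated")) {
    stop("config needs design: family or unrelated")
  }
  if (cfg$design == "family" && is.null(cfg$paths$pedigree)) {
    stop("family design requires a pedigree path")
  }
  if (cfg$design == "unrelated" &&
      is.null(cfg$kinship) && is.null(cfg$paths$pedigree)) {
    cfg$kinship <- "identity"
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- c("run_config", "list")
  cfg
}

cfg_trait_model <- function(cfg) {
  do.call(trait_model, if (is.null(cfg$trait_model)) list() else cfg$trait_model)
}

cfg_effect_config <- function(cfg) {
  args <- if (is.null(cfg$effect_model)) list() else cfg$effect_model
  if (!is.null(args$l_by_gene)) args$l_by_gene <- unlist(args$l_by_gene)
  do.call(effect_model_config, args)
}

# shared input assembly for both designs
load_run_inputs <- function(cfg) {
  model <- cfg_trait_model(cfg)
  gm <- NULL
  if (!is.null(cfg$paths$vcf)) {
    gm <- read_vcf(cfg$paths$vcf, field = if (is.null(cfg$vcf_field)) "GT" else cfg$vcf_field)
    if (!is.null(cfg$paths$annotations)) {
      gm <- attach_annotations(gm, read_annotations(cfg$paths$annotations))
    }
  }
  effects <- NULL
  if (!is.null(gm) && !is.null(cfg$paths$gene_table) &&
      !is.null(cfg$paths$gene_corr)) {
    ecfg <- cfg_effect_config(cfg)
    gene_table <- utils::read.table(cfg$paths$gene_table, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE,
                                    colClasses = c(chrom = "character"))
    gene_corr <- utils::read.table(cfg$paths$gene_corr, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
    eqtl <- if (!is.null(cfg$paths$eqtl_flags)) {
      scan(cfg$paths$eqtl_flags, what = logical(), quiet = TRUE)
    } else rep(FALSE, nrow(gm$variants))
    fv <- select_functional_variants(gm$variants, gene_table, eqtl, ecfg)
    freqs <- allele_frequency(gm)[fv$orig_index]
    effects <- build_effect_table(fv, freqs, gene_corr, ecfg,
                                  model$sigma2_sbp, model$sigma2_dbp)
  }
  covariates <- utils::read.table(cfg$paths$covariates, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
  list(model = model, genotypes = gm, effects = effects,
       covariates = covariates)
}

run_design <- function(cfg, out, design) {
  cfg <- validate_run_config(cfg)
  inp <- load_run_inputs(cfg)
  if (design == "family") {
    ped <- read_pedigree(cfg$paths$pedigree)
    kin <- pedigree_kinship(ped)
  } else {
    kin <- if (identical(cfg$kinship, "empirical")) {
      empirical_kinship(inp$genotypes,
                        min_maf = if (is.null(cfg$kinship_min_maf)) 0.01 else cfg$kinship_min_maf)
    } else identity_kinship(inp$covariates$id)
  }
  covariates <- inp$covariates[match(kin$ids, inp$covariates$id), , drop = FALSE]
  if (anyNA(covariates$id)) stop("covariates missing for some individuals")
  n_rep <- if (is.null(cfg$n_replicates)) inp$model$n_replicates else cfg$n_replicates
  message(sprintf("stage simulate: %d individuals, %d replicates, design %s",
                  length(kin$ids), n_rep, design))
  reps <- run_replicates(inp$model, kin, covariates,
                         genotypes = inp$genotypes, effects = inp$effects,
                         n_replicates = n_rep, seed = cfg$seed,
                         design = design)
  write_phenotypes(reps, out, cfg = cfg,
                   per_replicate = isTRUE(cfg$one_file_per_replicate))
}

#' Run the family (longitudinal) study design end to end
#'
#' Loads the configured pedigree, genotypes, annotations and covariates,
#' derives pedigree kinship, builds the effect table, simulates
#' `n_replicates` longitudinal replicates and writes them with a provenance
#' header.
#'
#' @param cfg A configuration list or [read_run_config()] result.
#' @param out Output path (long-format TSV), or a directory when
#'   `one_file_per_replicate` is set in the config.
#' @return The written path(s), invisibly.
#' @export
run_family_design <- function(cfg, out) run_design(cfg, out, "family")

#' Run the unrelated (single-exam) study design end to end
#'
#' As [run_family_design()] but with a single exam, kinship either empirical
#' (from the genotypes) or identity, and medication assigned at random per
#' replicate.
#'
#' @inheritParams run_family_design
#' @return The written path(s), invisibly.
#' @export
run_unrelated_design <- function(cfg, out) run_design(cfg, out, "unrelated")

#' Write simulated phenotype replicates
#'
#' Long-format TSV with columns REP, IID, EXAM, AGE, SEX, SBP, DBP, MED, HTN,
#' Q1, preceded by `#`-prefixed provenance lines that include the
#' configuration hash. With `per_replicate = TRUE`, `path` is treated as a
#' directory and one `replicate_<r>.tsv` is written per replicate.
#'
#' @param replicates List of replicate data frames from [run_replicates()].
#' @param path Output file (or directory).
#' @param cfg Optional configuration echoed into the header.
#' @param per_replicate One file per replicate?
#' @return The written path(s), invisibly.
#' @export
write_phenotypes <- function(replicates, path, cfg = NULL,
                             per_replicate = FALSE) {
  header <- c("# bpsimr simulated phenotypes",
              if (!is.null(cfg)) paste0("# config_hash: ", config_hash(cfg)))
  fmt <- function(d) {
    out <- data.frame(REP = d$rep, IID = d$id, EXAM = d$exam, AGE = d$age,
                      SEX = d$sex, SBP = sprintf("%.6f", d$sbp),
                      DBP = sprintf("%.6f", d$dbp),
                      MED = as.integer(d$med), HTN = as.integer(d$htn),
                      Q1 = sprintf("%.6f", d$q1), stringsAsFactors = FALSE)
    c(paste(names(out), collapse = "\t"),
      do.call(paste, c(out, sep = "\t")))
  }
  if (per_replicate) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- vapply(replicates, function(d) {
      f <- file.path(path, sprintf("replicate_%03d.tsv", d$rep[1L]))
      writeLines(c(header, fmt(d)), f)
      f
    }, character(1L))
    return(invisible(files))
  }
  all <- do.call(rbind, replicates)
  writeLines(c(header, fmt(all)), path)
  invisible(path)
}

#' Read simulated phenotypes written by [write_phenotypes()]
#'
#' @param path TSV path.
#' @return Data frame with lower-case column names.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  names(d)[names(d) == "iid"] <- "id"
  d$med <- d$med == 1L
  d$htn <- d$htn == 1L
  d
}
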