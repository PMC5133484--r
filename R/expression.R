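# Expression-array processing: sample QC, per-probe detection testing, FDR
# filtering, min-shift/log2/quantile normalization, and the functional-gene
# screen.

#' Construct an expression matrix
#'
#' Raw per-probe "average signals" (arbitrary fluorescence units) with a
#' parallel matrix of per-probe, per-sample detection p-values.
#'
#' @param signals Numeric probes x samples matrix.
#' @param detection_p Matching matrix of detection p-values in `[0, 1]`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(signals, detection_p) {
  signals <- as.matrix(signals)
  detection_p <- as.matrix(detection_p)
  if (!all(dim(signals) == dim(detection_p))) {
    stop("signals and detection_p must have matching dimensions")
  }
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0, 1]")
  }
  structure(list(signals = signals, detection_p = detection_p),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probes x %d samples\n",
              nrow(x$signals), ncol(x$signals)))
  invisible(x)
}

#' Expression sample quality control
#'
#' A sample is kept iff its number of probes with detection p <= `detect_p`
#' is at least `min_detected`, its mean raw signal is at least
#' `min_mean_signal`, and its mean correlation with all other samples (in raw
#' signals) is at least `min_mean_corr`. A constant-signal sample has
#' undefined correlations; these are treated as 0, which drops the sample for
#' any positive correlation threshold.
#'
#' @param em An [expression_matrix()].
#' @param min_detected Minimum count of detected probes.
#' @param min_mean_signal Minimum mean raw signal.
#' @param min_mean_corr Minimum mean inter-sample correlation.
#' @param detect_p Detection p-value cutoff defining "detected" (default
#'   0.05).
#' @return Logical keep-mask over samples.
#' @export
sample_qc <- function(em, min_detected, min_mean_signal, min_mean_corr,
                      detect_p = 0.05) {
  if (ncol(em$signals) < 2L) stop("sample QC needs at least 2 samples")
  n_det <- colSums(em$detection_p <= detect_p)
  mean_sig <- colMeans(em$signals)
  cc <- suppressWarnings(stats::cor(em$signals))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- NA
  mean_corr <- rowMeans(cc, na.rm = TRUE)
  n_det >= min_detected & mean_sig >= min_mean_signal & mean_corr >= min_mean_corr
}

#' Exact binomial test of probe detection
#'
#' One-sided exact binomial tail `P(X >= n_detected)` for `X ~ Binomial(n,
#' p0)`: is the probe detected (detection p <= 0.05) in more samples than the
#' null rate `p0` would produce?
#'
#' @param n_detected Number of samples in which the probe was detected.
#' @param n_samples Total number of samples.
#' @param p0 Null detection rate (default 0.05, the detection p-value cutoff
#'   itself).
#' @return The p-value.
#' @export
#' @examples
#' probe_detection_test(20, 20)   # 0.05^20
probe_detection_test <- function(n_detected, n_samples, p0 = 0.05) {
  stopifnot(n_detected >= 0, n_detected <= n_samples, n_samples >= 1)
  stats::pbinom(n_detected - 1, n_samples, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`p * m / rank`, with the running
#' minimum from the largest p downwards), delegated to
#' [stats::p.adjust()]`(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Shift, log2-transform and quantile-normalize expression signals
#'
#' All signals are shifted upward by a single global constant so the observed
#' minimum (over every probe and sample) becomes exactly 1.0, log2-transformed
#' (the minimum maps to 0), then quantile-normalized across samples: each
#' sample's order statistics are replaced by the across-sample means of order
#' statistics (ties receive the average of their tied quantile means). After
#' normalization every column shares an identical sorted vector.
#'
#' @param em An [expression_matrix()] (or a bare numeric matrix of signals).
#' @return The normalized probes x samples matrix.
#' @export
normalize_expression <- function(em) {
  x <- if (inherits(em, "expression_matrix")) em$signals else as.matrix(em)
  if (length(x) == 0L) return(x)
  if (!all(is.finite(x))) stop("signals must be finite")
  shifted <- x + (1 - min(x))
  lg <- log2(shifted)
  qn <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(qn) <- dimnames(x)
  qn
}

#' Screen genes for functional status
#'
#' A gene qualifies as "functional" for the simulation when its expression is
#' both phenotypically and genetically correlated with the blood-pressure
#' trait: `|phenotypic correlation| >= phen_corr_min` (computed here from the
#' expression matrix and trait) and `|genetic correlation| >= gen_corr_min`
#' (supplied externally, e.g. from a bivariate variance-components analysis).
#' Genes with zero-variance expression, or missing from the genetic
#' correlation table, are skipped with a warning.
#'
#' @param expr Normalized genes x samples matrix with gene rownames.
#' @param trait Numeric trait vector aligned with the columns of `expr`.
#' @param gen_corr Named numeric vector of per-gene genetic correlations.
#' @param phen_corr_min,gen_corr_min Absolute-correlation thresholds.
#' @return Data frame of passing genes with their two correlations.
#' @export
screen_functional_genes <- function(expr, trait, gen_corr,
                                    phen_corr_min = 0.1, gen_corr_min = 0.1) {
  stopifnot(ncol(expr) == length(trait))
  genes <- rownames(expr)
  if (is.null(genes)) stop("expr must have gene rownames")
  keep <- list()
  for (g in genes) {
    x <- expr[g, ]
    if (stats::sd(x) == 0) {
      warning("gene ", g, " has zero expression variance; skipped")
      next
    }
    if (!g %in% names(gen_corr) || is.na(gen_corr[[g]])) {
      warning("no genetic correlation for gene ", g, "; skipped")
      next
    }
    pc <- stats::cor(x, trait)
    if (abs(pc) >= phen_corr_min && abs(gen_corr[[g]]) >= gen_corr_min) {
      keep[[g]] <- data.frame(gene = g, phen_corr = pc,
                              gen_corr = gen_corr[[g]],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(keep)) {
    return(data.frame(gene = character(), phen_corr = numeric(),
                      gen_corr = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Read / write expression matrices as TSV
#'
#' `read_expression` expects two TSV files with probes in rows (first column
#' probe id, remaining columns samples): one of raw signals and one of
#' detection p-values.
#'
#' @param signal_path,detection_path TSV paths.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(signal_path, detection_path) {
  rd <- function(p) {
    d <- utils::read.table(p, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L)
    as.matrix(d)
  }
  expression_matrix(rd(signal_path), rd(detection_path))
}

#' @rdname read_expression
#' @param mat Numeric matrix (probes x samples) with probe rownames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  utils::write.table(data.frame(PROBE = rownames(mat), mat, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
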