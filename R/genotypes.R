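# Genotype containers, VCF I/O (GT / DOS / NALTT dialect), gene-dropping,
# allele frequencies, variant QC and MAF/annotation summaries.

VARIANT_ANNOTATIONS <- c("synonymous", "nonsynonymous", "highly_deleterious",
                         "utr5", "utr3", "other_noncoding")

#' Construct a genotype matrix
#'
#' Holds per-variant, per-individual alternate-allele counts in `{0, 1, 2, NA}`
#' (variants in rows, individuals in columns), optional real-valued dosages in
#' `[0, 2]`, and a variant table with at least `chrom`, `pos`, `ref`, `alt`;
#' optionally `gene`, `annotation` (one of `r paste(VARIANT_ANNOTATIONS,
#' collapse = ", ")`) and `pp2s` (PolyPhen-2 score in `[0, 1]`, coding variants
#' only).
#'
#' @param calls Integer matrix, variants x individuals, values 0/1/2/NA.
#' @param variants Data frame of variant records, one row per call row.
#' @param ids Character vector of individual ids (column order).
#' @param dosages Optional numeric matrix in `[0, 2]`, same shape as `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, ids, dosages = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ids <- as.character(ids)
  if (ncol(calls) != length(ids)) stop("ncol(calls) must equal length(ids)")
  if (nrow(calls) != nrow(variants)) stop("nrow(calls) must equal nrow(variants)")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(variants))) {
    stop("variants table needs columns chrom, pos, ref, alt")
  }
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (!is.null(dosages)) {
    dosages <- as.matrix(dosages)
    if (!all(dim(dosages) == dim(calls))) stop("dosages shape mismatch")
    if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
      stop("dosages must lie in [0, 2]")
    }
  }
  if ("annotation" %in% names(variants)) {
    ann <- variants$annotation
    if (!all(is.na(ann) | ann %in% VARIANT_ANNOTATIONS)) {
      stop("unknown annotation values; expected one of: ",
           paste(VARIANT_ANNOTATIONS, collapse = ", "))
    }
  }
  dimnames(calls) <- list(NULL, ids)
  structure(list(calls = calls, dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d variants x %d individuals (%s dosages)\n",
              nrow(x$calls), length(x$ids),
              if (is.null(x$dosages)) "no" else "with"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# ---------------------------------------------------------------------------
# VCF I/O

vcf_format_fields <- function(vcf) {
  unique(unlist(strsplit(unique(vcf@gt[, "FORMAT"]), ":", fixed = TRUE)))
}

#' Read genotypes from a VCF file
#'
#' Reads one FORMAT field from a VCF 4.x file (plain or bgzip-compressed):
#' `GT` hard calls, `DOS` likelihood-based allele dosages, or `NALTT`
#' high-quality 0/1/2 calls. `GT` separators `/` and `|` are both accepted and
#' `./.` becomes missing. Multi-allelic records are split into one row per
#' alternate allele for `GT` (the call counts copies of that allele, with a
#' warning); for the numeric fields `DOS` and `NALTT` a per-record scalar
#' cannot be attributed to a single allele, so multi-allelic records are
#' dropped with a warning.
#'
#' @param path VCF file path.
#' @param field One of `"GT"`, `"DOS"`, `"NALTT"`.
#' @return A [genotype_matrix()]; for `field = "DOS"` the rounded dosage is
#'   *not* substituted into `calls` — `calls` carries `NA` and the values are
#'   in `$dosages`.
#' @export
read_vcf <- function(path, field = c("GT", "DOS", "NALTT")) {
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  avail <- vcf_format_fields(vcf)
  if (!field %in% avail) {
    stop(sprintf("FORMAT field '%s' absent from %s; available: %s",
                 field, path, paste(avail, collapse = ", ")))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ids <- colnames(vcf@gt)[-1L]
  multi <- grepl(",", fix$ALT, fixed = TRUE)

  if (field == "GT") {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (any(multi)) {
      warning(sum(multi), " multi-allelic record(s) split into per-allele rows")
    }
    rows <- list(); vrows <- list(); k <- 0L
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
      toks <- strsplit(gt[i, ], "[/|]")
      for (a in seq_along(alts)) {
        k <- k + 1L
        rows[[k]] <- vapply(toks, function(tk) {
          if (length(tk) == 0L || anyNA(tk) || any(tk == ".")) return(NA_integer_)
          sum(tk == as.character(a))
        }, integer(1L))
        vrows[[k]] <- data.frame(chrom = fix$CHROM[i],
                                 pos = as.integer(fix$POS[i]),
                                 ref = fix$REF[i], alt = alts[a],
                                 stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, rows)
    return(genotype_matrix(calls, do.call(rbind, vrows), ids))
  }

  num <- suppressWarnings(vcfR::extract.gt(vcf, element = field,
                                           as.numeric = TRUE))
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped for numeric field ",
            field)
    num <- num[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  vars <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  if (field == "NALTT") {
    calls <- round(num)
    genotype_matrix(calls, vars, ids)
  } else {
    calls <- matrix(NA_integer_, nrow(num), ncol(num))
    genotype_matrix(calls, vars, ids, dosages = num)
  }
}

#' Write a genotype matrix to a plain-text VCF file
#'
#' Emits a minimal VCF 4.2 with FORMAT `GT:DOS:NALTT`: `GT` and `NALTT` from
#' the hard calls, `DOS` from `$dosages` when present (otherwise the call
#' value). `read_vcf(write_vcf(gm))` round-trips the non-missing fields.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DOS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    "##FORMAT=<ID=NALTT,Number=1,Type=Integer,Description=\"High-quality alternate allele count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$ids), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(gm$calls))) {
    g <- gm$calls[i, ]
    d <- if (is.null(gm$dosages)) as.numeric(g) else gm$dosages[i, ]
    cells <- ifelse(is.na(g) & is.na(d), "./.:.:.",
                    paste(ifelse(is.na(g), "./.", gt_str[g + 1L]),
                          ifelse(is.na(d), ".", formatC(d, format = "g", digits = 6)),
                          ifelse(is.na(g), ".", g), sep = ":"))
    v <- gm$variants[i, ]
    writeLines(paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                       "GT:DOS:NALTT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene dropping

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founders receive genotypes drawn in Hardy-Weinberg proportions at the given
#' allele frequencies; each non-founder inherits one allele from each parent,
#' chosen uniformly at random. Per-variant random streams are derived from the
#' seed by counter, so results do not depend on variant order or count.
#'
#' @param ped A [pedigree()].
#' @param founder_freqs Vector of alternate-allele frequencies in `[0, 1]`.
#' @param seed Integer seed.
#' @param variants Optional variant table (defaults to synthetic records on
#'   chromosome 1 at 1 kb spacing).
#' @return A [genotype_matrix()] with individuals in pedigree order.
#' @export
gene_drop <- function(ped, founder_freqs, seed, variants = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  p <- as.numeric(founder_freqs)
  if (any(is.na(p) | p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  n <- nrow(ped)
  m <- length(p)
  idx <- stats::setNames(seq_len(n), ped$id)
  ord <- attr(ped, "order")
  # generation depth, so transmission can be vectorized level by level
  depth <- integer(n)
  for (i in ord) {
    if (!is.na(ped$father[i])) {
      depth[i] <- max(depth[idx[[ped$father[i]]]], depth[idx[[ped$mother[i]]]]) + 1L
    }
  }
  levels <- split(seq_len(n), depth)
  fidx <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  midx <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])

  calls <- matrix(NA_integer_, m, n, dimnames = list(NULL, ped$id))
  for (v in seq_len(m)) {
    a1 <- integer(n); a2 <- integer(n)
    with_seed(derive_seed(seed, 101L, v), {
      for (lev in levels) {
        fo <- lev[is.na(fidx[lev])]
        if (length(fo)) {
          a1[fo] <- stats::rbinom(length(fo), 1L, p[v])
          a2[fo] <- stats::rbinom(length(fo), 1L, p[v])
        }
        nf <- lev[!is.na(fidx[lev])]
        if (length(nf)) {
          pick_f <- stats::rbinom(length(nf), 1L, 0.5)
          pick_m <- stats::rbinom(length(nf), 1L, 0.5)
          a1[nf] <- ifelse(pick_f == 0L, a1[fidx[nf]], a2[fidx[nf]])
          a2[nf] <- ifelse(pick_m == 0L, a1[midx[nf]], a2[midx[nf]])
        }
      }
    })
    calls[v, ] <- a1 + a2
  }
  if (is.null(variants)) {
    variants <- data.frame(chrom = "1", pos = 1000L * seq_len(m),
                           ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, variants, ped$id)
}

# ---------------------------------------------------------------------------
# Frequencies, HWE, QC, summaries

#' Non-reference allele frequencies
#'
#' `(sum of calls) / (2 x non-missing count)` per variant; missing calls are
#' excluded from the denominator. Variants with no non-missing call get `NA`
#' with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector, one frequency per variant.
#' @export
allele_frequency <- function(gm) {
  nn <- rowSums(!is.na(gm$calls))
  if (any(nn == 0L)) warning(sum(nn == 0L), " variant(s) with all calls missing")
  rowSums(gm$calls, na.rm = TRUE) / (2 * nn)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is the
#' sum of probabilities of all heterozygote counts (same parity, compatible
#' with the allele totals) that are no more probable than the observed count
#' under the HWE null. Monomorphic input returns 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote). Total must be >= 1.
#' @return The exact p-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # HWE-consistent
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("at least one genotype required")
  n_alt <- 2L * n_aa + n_Aa
  n_min <- min(n_alt, 2L * n - n_alt)
  if (n_min == 0L) return(1)
  hets <- seq.int(n_min %% 2L, n_min, by = 2L)
  # conditional log-probability of h heterozygotes given allele counts
  hom_min <- (n_min - hets) / 2
  hom_maj <- n - hets - hom_min
  logp <- hets * log(2) + lfactorial(n) -
    (lfactorial(hets) + lfactorial(hom_min) + lfactorial(hom_maj))
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

#' Variant quality-control filter
#'
#' A variant is retained iff, in *every* group, its call rate is at least
#' `call_rate_min` and its exact Hardy-Weinberg p-value ([hwe_exact_test()]) is
#' at least `hwe_p_min`, and (when case labels are supplied) a two-sided Fisher
#' exact test of called/missing counts between cases and controls, combined
#' over all individuals, has p at least `diff_call_p_min`.
#'
#' @param gm A [genotype_matrix()].
#' @param group_labels Group (study) membership for every individual.
#' @param case_labels Logical case indicator per individual, or `NULL` to skip
#'   the differential-call-rate test.
#' @param call_rate_min,hwe_p_min,diff_call_p_min Thresholds in `[0, 1]`.
#' @return Logical keep-mask, one entry per variant, with per-test details in
#'   attribute `"details"`.
#' @export
variant_qc <- function(gm, group_labels, case_labels = NULL,
                       call_rate_min = 0.90, hwe_p_min = 1e-6,
                       diff_call_p_min = 1e-4) {
  for (thr in c(call_rate_min, hwe_p_min, diff_call_p_min)) {
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  }
  group_labels <- as.character(group_labels)
  if (length(group_labels) != length(gm$ids)) {
    stop("group_labels must cover all individuals")
  }
  if (!is.null(case_labels) && length(case_labels) != length(gm$ids)) {
    stop("case_labels must cover all individuals")
  }
  m <- nrow(gm$calls)
  groups <- unique(group_labels)
  call_ok <- hwe_ok <- rep(TRUE, m)
  min_call_rate <- rep(1, m); min_hwe_p <- rep(1, m)
  for (g in groups) {
    sub <- gm$calls[, group_labels == g, drop = FALSE]
    cr <- rowMeans(!is.na(sub))
    hp <- vapply(seq_len(m), function(i) {
      x <- sub[i, ]
      hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                     sum(x == 2L, na.rm = TRUE))
    }, numeric(1L))
    call_ok <- call_ok & cr >= call_rate_min
    hwe_ok <- hwe_ok & hp >= hwe_p_min
    min_call_rate <- pmin(min_call_rate, cr)
    min_hwe_p <- pmin(min_hwe_p, hp)
  }
  diff_p <- rep(NA_real_, m)
  diff_ok <- rep(TRUE, m)
  if (!is.null(case_labels)) {
    case_labels <- as.logical(case_labels)
    diff_p <- vapply(seq_len(m), function(i) {
      called <- !is.na(gm$calls[i, ])
      tab <- table(factor(called, c(FALSE, TRUE)),
                   factor(case_labels, c(FALSE, TRUE)))
      stats::fisher.test(tab)$p.value
    }, numeric(1L))
    diff_ok <- diff_p >= diff_call_p_min
  }
  keep <- call_ok & hwe_ok & diff_ok
  attr(keep, "details") <- data.frame(min_call_rate = min_call_rate,
                                      min_hwe_p = min_hwe_p,
                                      diff_call_p = diff_p)
  keep
}

#' Tabulate variants by annotation and minor-allele-frequency bin
#'
#' Variants with fewer than `min_minor_copies` observed copies of the minor
#' allele are excluded; the rest are counted by annotation category and MAF bin
#' (`MAF <= 0.01`, `0.01 < MAF <= 0.1`, `0.1 < MAF <= 0.5`; upper bounds
#' closed).
#'
#' @param gm A [genotype_matrix()] whose variant table has an `annotation`
#'   column.
#' @param min_minor_copies Minimum observed minor-allele copies (default 5).
#' @return A contingency table, annotation x MAF bin.
#' @export
summarize_variants <- function(gm, min_minor_copies = 5) {
  if (!"annotation" %in% names(gm$variants)) {
    stop("variant table has no annotation column")
  }
  alt_copies <- rowSums(gm$calls, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(gm$calls))
  minor_copies <- pmin(alt_copies, tot - alt_copies)
  p <- alt_copies / tot
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & minor_copies >= min_minor_copies
  bins <- cut(maf[keep], breaks = c(0, 0.01, 0.1, 0.5),
              labels = c("MAF <= 0.01", "0.01 < MAF <= 0.1", "0.1 < MAF <= 0.5"),
              include.lowest = TRUE)
  table(annotation = factor(gm$variants$annotation[keep], VARIANT_ANNOTATIONS),
        maf_bin = bins)
}

# ---------------------------------------------------------------------------
# Annotation tables

#' Read / attach a variant annotation table
#'
#' The annotation table is a TSV with columns CHROM, POS, REF, ALT, GENE,
#' ANNOTATION, PP2S (PP2S empty or NA for non-coding variants).
#' `attach_annotations` joins it onto a genotype matrix by chrom/pos/ref/alt.
#'
#' @param path TSV path.
#' @return `read_annotations`: a data frame with lower-case column names.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(CHROM = "character"))
  names(ann) <- tolower(names(ann))
  need <- c("chrom", "pos", "ref", "alt", "gene", "annotation", "pp2s")
  if (!all(need %in% names(ann))) {
    stop("annotation table needs columns ", paste(toupper(need), collapse = ", "))
  }
  ann
}

#' @rdname read_annotations
#' @param gm A [genotype_matrix()].
#' @param ann Annotation data frame from `read_annotations`.
#' @return `attach_annotations`: the genotype matrix with `gene`, `annotation`
#'   and `pp2s` merged into its variant table.
#' @export
attach_annotations <- function(gm, ann) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  i <- match(key(gm$variants), key(ann))
  gm$variants$gene <- ann$gene[i]
  gm$variants$annotation <- ann$annotation[i]
  gm$variants$pp2s <- ann$pp2s[i]
  gm
}
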