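vcf_fixture <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  writeLines(lines, path)
  path
}

small_vcf <- function(env = parent.frame()) {
  vcf_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DOS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT:DOS",
            "0/1:1.37", "0|0:0.02", "./.:."), collapse = "\t"),
    paste(c("1", "200", ".", "C", "T", ".", "PASS", ".", "GT:DOS",
            "1/1:1.92", "0/1:0.88", "0/0:0.11"), collapse = "\t")), env = env)
}

test_that("read_vcf parses GT and DOS and flags absent fields", {
  path <- small_vcf()
  gm <- read_vcf(path, "GT")
  expect_equal(unname(gm$calls[1, ]), c(1L, 0L, NA))
  expect_equal(unname(gm$calls[2, ]), c(2L, 1L, 0L))
  expect_equal(gm$ids, c("S1", "S2", "S3"))
  expect_equal(gm$variants$pos, c(100L, 200L))
  dm <- read_vcf(path, "DOS")
  expect_equal(unname(dm$dosages[1, ]), c(1.37, 0.02, NA))
  expect_error(read_vcf(path, "NALTT"), "available: GT, DOS")
})

test_that("multi-allelic GT records are split per alternate allele", {
  path <- vcf_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G,T", ".", "PASS", ".", "GT",
            "1/2", "0/2"), collapse = "\t")))
  expect_warning(gm <- read_vcf(path, "GT"), "multi-allelic")
  expect_equal(nrow(gm$calls), 2L)
  expect_equal(gm$variants$alt, c("G", "T"))
  expect_equal(unname(gm$calls[1, ]), c(1L, 0L))   # copies of G
  expect_equal(unname(gm$calls[2, ]), c(1L, 1L))   # copies of T
})

test_that("VCF writing round-trips gene-dropped genotypes", {
  gm <- gene_drop(ped_sibs(3), c(0.2, 0.5, 0.8), seed = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  for (field in c("GT", "NALTT")) {
    back <- read_vcf(path, field)
    expect_equal(unname(back$calls), unname(gm$calls))
    expect_equal(back$ids, gm$ids)
  }
  expect_equal(unname(read_vcf(path, "DOS")$dosages),
               unname(gm$calls) + 0)
  empty <- genotype_matrix(matrix(integer(), 0, 2),
                           data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           ids = c("A", "B"))
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, p2)
  expect_equal(sum(!startsWith(readLines(p2), "#")), 0L)   # header only
})

test_that("gene dropping respects fixed and intermediate frequencies", {
  ped <- ped_trio()
  expect_true(all(gene_drop(ped, c(0, 0), seed = 1)$calls == 0L))
  expect_true(all(gene_drop(ped, c(1, 1), seed = 1)$calls == 2L))
  # 500 independent founders at p = 0.3: mean call within binomial band
  big <- pedigree(paste0("I", 1:500), rep(NA, 500), rep(NA, 500),
                  rep(c("M", "F"), 250))
  g <- gene_drop(big, 0.3, seed = 2)
  expect_lt(abs(mean(g$calls) - 0.6), 0.06)
})

test_that("gene dropping is seed-reproducible and variant-order invariant", {
  ped <- ped_sibs(4)
  a <- gene_drop(ped, c(0.2, 0.4), seed = 9)
  b <- gene_drop(ped, c(0.2, 0.4), seed = 9)
  expect_identical(a$calls, b$calls)
  expect_false(identical(a$calls, gene_drop(ped, c(0.2, 0.4), seed = 10)$calls))
  # offspring calls always consistent with Mendelian transmission
  k <- as.matrix(pedigree_kinship(ped))
  g <- gene_drop(ped, rep(0.5, 200), seed = 3)$calls
  het_parents <- g[, 1] == 2 & g[, 2] == 0
  expect_true(all(g[het_parents, 3:6] == 1L))      # AA x aa -> all Aa
})

test_that("allele frequencies exclude missing calls from the denominator", {
  gm <- make_gm(rbind(c(0, 0, 0), c(2, 2, NA), c(0, 1, 2)))
  gm$calls[2, 3] <- NA
  expect_equal(allele_frequency(gm)[1], 0)
  expect_equal(allele_frequency(gm)[2], 1)
  expect_equal(allele_frequency(gm)[3], 0.5)
  gm2 <- make_gm(matrix(NA_integer_, 1, 3))
  expect_warning(f <- allele_frequency(gm2), "all calls missing")
  expect_true(is.na(f))
})

test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  p_extreme <- hwe_exact_test(50, 0, 50)
  expect_equal(p_extreme, oracle_hwe(50, 0, 50))
  expect_lt(p_extreme, 1e-6)
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25))
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:200, 1)
    g <- as.vector(stats::rmultinom(1, n, c(0.4, 0.3, 0.3)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]), tolerance = 1e-12)
  }
})

test_that("variant QC applies the published exclusion rules per group", {
  # 100 individuals per group; variant 1 has call rate 0.89 in group B
  set.seed(5)
  calls <- matrix(rbinom(3 * 200, 2, 0.4), 3, 200)
  calls[1, 101:111] <- NA                      # 89/100 called in group B
  calls[2, 101:200] <- rep(c(0L, 2L), 50)      # het deficit: HWE p << 1e-6
  gm <- make_gm(calls)
  groups <- rep(c("A", "B"), each = 100)
  keep <- variant_qc(gm, groups, case_labels = NULL)
  expect_equal(as.logical(keep), c(FALSE, FALSE, TRUE))
  details <- attr(keep, "details")
  expect_lt(details$min_call_rate[1], 0.90)
  expect_lt(details$min_hwe_p[2], 1e-6)
  # differential call rate between cases and controls
  calls2 <- matrix(rbinom(2 * 200, 2, 0.4), 2, 200)
  calls2[1, 1:40] <- NA                        # missing only in cases
  gm2 <- make_gm(calls2)
  cases <- rep(c(TRUE, FALSE), each = 100)
  keep2 <- variant_qc(gm2, rep("A", 200), cases)
  expect_false(keep2[1])
  expect_true(keep2[2])
})

test_that("variant QC is monotone in its thresholds", {
  set.seed(8)
  calls <- matrix(rbinom(30 * 80, 2, runif(30, 0.05, 0.5)), 30, 80)
  calls[sample(length(calls), 150)] <- NA
  gm <- make_gm(calls)
  groups <- rep(c("A", "B"), each = 40)
  cases <- rep(c(TRUE, FALSE), 40)
  strict <- variant_qc(gm, groups, cases,
                       call_rate_min = 0.95, hwe_p_min = 1e-3,
                       diff_call_p_min = 0.05)
  relaxed <- variant_qc(gm, groups, cases,
                        call_rate_min = 0.80, hwe_p_min = 1e-8,
                        diff_call_p_min = 1e-6)
  expect_true(all(relaxed[strict]))             # relaxing never drops a keeper
  expect_error(variant_qc(gm, groups, cases, call_rate_min = 1.2), "\\[0, 1\\]")
})

test_that("variant summaries bin by MAF with closed upper bounds", {
  n <- 300
  freq_for_copies <- function(k) k / (2 * n)    # k minor copies among 2n alleles
  calls <- rbind(
    c(rep(1L, 4), rep(0L, n - 4)),              # 4 copies: excluded
    c(rep(1L, 5), rep(0L, n - 5)),              # 5 copies, MAF < 0.01
    c(rep(1L, 6), rep(0L, n - 6)),              # MAF exactly 0.01
    c(rep(1L, 7), rep(0L, n - 7)),              # MAF just over 0.01
    c(rep(1L, n), rep(0L, 0)),                  # MAF 0.5
    rep(1L, n))                                 # all het -> freq .5 -> top bin
  calls[5, ] <- rep(c(0L, 1L, 1L, 0L), length.out = n)  # MAF 0.25
  ann <- c("synonymous", "synonymous", "nonsynonymous", "nonsynonymous",
           "utr5", "highly_deleterious")
  gm <- make_gm(calls, annotation = ann)
  tab <- summarize_variants(gm, min_minor_copies = 5)
  expect_equal(sum(tab), 5)                      # first row excluded
  expect_equal(unname(tab["synonymous", "MAF <= 0.01"]), 1)
  expect_equal(unname(tab["nonsynonymous", "MAF <= 0.01"]), 1)   # exactly 0.01
  expect_equal(unname(tab["nonsynonymous", "0.01 < MAF <= 0.1"]), 1)
  expect_equal(unname(tab["utr5", "0.1 < MAF <= 0.5"]), 1)
  expect_equal(unname(tab["highly_deleterious", "0.1 < MAF <= 0.5"]), 1)
})

test_that("annotation tables attach onto genotype matrices by variant key", {
  fx <- make_fixture(n_families = 2, n_children = 2, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  ann <- fx$annotations
  names(ann) <- toupper(names(ann))
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- genotype_matrix(fx$genotypes$calls,
                        fx$genotypes$variants[, c("chrom", "pos", "ref", "alt")],
                        fx$genotypes$ids)
  gm <- attach_annotations(gm, read_annotations(path))
  expect_equal(gm$variants$gene, fx$genotypes$variants$gene)
  expect_equal(gm$variants$pp2s, fx$genotypes$variants$pp2s)
})
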