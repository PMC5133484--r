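# pair-family kinship: many independent 2-member blocks with a given phi
pair_kinship <- function(n_pairs, phi) {
  fam <- rep(sprintf("P%05d", seq_len(n_pairs)), each = 2)
  ids <- paste0(fam, "_", rep(1:2, n_pairs))
  blocks <- lapply(seq_len(n_pairs), function(i) {
    matrix(c(0.5, phi, phi, 0.5), 2, 2)
  })
  names(blocks) <- unique(fam)
  structure(list(ids = ids, family = fam, blocks = blocks),
            class = "kinship_matrix")
}

flat_covariates <- function(ids, age = 40, sex = "F") {
  data.frame(id = ids, age = age, sex = sex, stringsAsFactors = FALSE)
}

test_that("polygenic values follow the kinship covariance", {
  kin <- identity_kinship(paste0("I", 1:20000))
  a <- simulate_polygenic(kin, sigma2_a = 4, seed = 1)
  expect_equal(stats::var(a), 4, tolerance = 0.1)
  expect_equal(mean(a), 0, tolerance = 3 * sqrt(4 / 20000) * 1.5)
  # duplicated individual: phi = 0.5 off-diagonal, correlation 1
  dup <- pair_kinship(500, 0.5)
  ad <- simulate_polygenic(dup, 1, seed = 2)
  expect_equal(ad[seq(1, 999, 2)], ad[seq(2, 1000, 2)],
               tolerance = 1e-8, ignore_attr = TRUE)
  # parent-offspring phi = 0.25: correlation ~ 0.5 over 10,000 pairs
  po <- pair_kinship(10000, 0.25)
  ap <- simulate_polygenic(po, 1, seed = 3)
  r <- stats::cor(ap[seq(1, 19999, 2)], ap[seq(2, 20000, 2)])
  expect_equal(r, 0.5, tolerance = 0.03)
})

test_that("polygenic sampling rejects non-PSD kinship blocks", {
  bad <- structure(list(ids = c("a", "b"), family = c("X", "X"),
                        blocks = list(X = matrix(c(0.5, 0.9, 0.9, 0.5), 2, 2))),
                   class = "kinship_matrix")
  expect_error(simulate_polygenic(bad, 1, seed = 1), "positive semi-definite")
})

test_that("a bivariate exam reduces to the mean when variance vanishes", {
  m <- trait_model(sigma2_sbp = 1e-10, sigma2_dbp = 1e-10,
                   beta_age_sbp = 0, beta_age_dbp = 0,
                   beta_sex_sbp = 0, beta_sex_dbp = 0)
  cov <- flat_covariates(paste0("I", 1:50))
  out <- simulate_bivariate_exam(m, matrix(0, 50, 2), NULL, cov, seed = 5)
  expect_equal(out$sbp, rep(m$mu_sbp, 50), tolerance = 1e-3)
  expect_equal(out$dbp, rep(m$mu_dbp, 50), tolerance = 1e-3)
})

test_that("perfectly correlated components make SBP and DBP comonotone", {
  m <- trait_model(sigma2_sbp = 100, sigma2_dbp = 100,
                   rho_g_traits = 1, rho_e_traits = 1,
                   h2_sbp = 0.4, h2_dbp = 0.4,
                   beta_age_sbp = 0, beta_age_dbp = 0,
                   beta_sex_sbp = 0, beta_sex_dbp = 0)
  kin <- identity_kinship(paste0("I", 1:2000))
  vc <- residual_polygenic_cov(m)
  a <- with_seed(derive_seed(9, 1), bpsimr:::mvn_kinship(kin, vc$sigma_a))
  out <- simulate_bivariate_exam(m, a, NULL, flat_covariates(kin$ids), seed = 9)
  expect_gt(stats::cor(out$sbp - m$mu_sbp, out$dbp - m$mu_dbp), 0.999)
})

test_that("marginal variances and the SBP-DBP correlation match the model", {
  m <- trait_model(beta_age_sbp = 0, beta_age_dbp = 0,
                   beta_sex_sbp = 0, beta_sex_dbp = 0)
  n <- 40000
  kin <- identity_kinship(paste0("I", 1:n))
  vc <- residual_polygenic_cov(m)
  a <- with_seed(derive_seed(2, 1), bpsimr:::mvn_kinship(kin, vc$sigma_a))
  out <- simulate_bivariate_exam(m, a, NULL, flat_covariates(kin$ids), seed = 2)
  # 3-SE bands: SE(var) ~ sigma2 sqrt(2/n), SE(cor) ~ 1/sqrt(n)
  expect_lt(abs(stats::var(out$sbp) - m$sigma2_sbp),
            3 * m$sigma2_sbp * sqrt(2 / n))
  expect_lt(abs(stats::var(out$dbp) - m$sigma2_dbp),
            3 * m$sigma2_dbp * sqrt(2 / n))
  h <- sqrt(m$h2_sbp * m$h2_dbp)
  e <- sqrt((1 - m$h2_sbp) * (1 - m$h2_dbp))
  rho_expected <- m$rho_g_traits * h + m$rho_e_traits * e
  expect_lt(abs(stats::cor(out$sbp, out$dbp) - rho_expected), 3 / sqrt(n))
})

test_that("regression on a simulated variant recovers its effect size", {
  # single diallelic variant, beta on DBP, 50,000 unrelateds
  n <- 50000
  p <- 0.3; beta <- 2.5
  m <- trait_model(beta_age_sbp = 0, beta_age_dbp = 0,
                   beta_sex_sbp = 0, beta_sex_dbp = 0)
  kin <- identity_kinship(paste0("I", 1:n))
  g <- with_seed(1, stats::rbinom(n, 2, p))
  eff <- data.frame(freq = p, beta_sbp = 0, beta_dbp = beta)
  vc <- residual_polygenic_cov(m, eff)
  a <- with_seed(derive_seed(4, 1), bpsimr:::mvn_kinship(kin, vc$sigma_a))
  ve <- cbind(sbp = 0 * g, dbp = beta * g)
  out <- simulate_bivariate_exam(m, a, ve, flat_covariates(kin$ids), seed = 4)
  fit <- stats::lm(out$dbp ~ g)
  se <- sqrt(m$sigma2_dbp / (n * 2 * p * (1 - p)))
  expect_lt(abs(stats::coef(fit)[["g"]] - beta), 3 * se)
})

test_that("the medication interaction truth table is exact", {
  m <- trait_model()   # -10 SBP, -5 DBP
  sbp <- c(150, 150, 150, 150); dbp <- c(95, 95, 95, 95)
  med <- c(TRUE, TRUE, FALSE, FALSE)
  car <- c(TRUE, FALSE, TRUE, FALSE)
  out <- apply_medication(sbp, dbp, med, car, m)
  expect_equal(out$sbp, c(150, 140, 150, 150))   # only treated non-carrier
  expect_equal(out$dbp, c(95, 90, 95, 95))
  # idempotent only where no shift was applied
  again <- apply_medication(out$sbp, out$dbp, med, car, m)
  expect_equal(again$sbp[c(1, 3, 4)], out$sbp[c(1, 3, 4)])
  expect_equal(again$sbp[2], out$sbp[2] - m$med_effect_sbp)
})

test_that("medication assignment respects its proportion and varies by seed", {
  expect_false(any(assign_medication(100, 0, seed = 1)))
  expect_true(all(assign_medication(100, 1, seed = 1)))
  x <- assign_medication(10000, 0.2, seed = 2)
  expect_lt(abs(mean(x) - 0.2), 0.012)
  expect_false(identical(assign_medication(100, 0.5, seed = 3),
                         assign_medication(100, 0.5, seed = 4)))
})

test_that("longitudinal exams share genetics and correlate as h2 predicts", {
  m <- trait_model(rho_e_time = 0, beta_sex_sbp = 0, beta_sex_dbp = 0)
  n <- 20000
  kin <- identity_kinship(paste0("I", 1:n))
  vc <- residual_polygenic_cov(m)
  a <- with_seed(derive_seed(6, 1), bpsimr:::mvn_kinship(kin, vc$sigma_a))
  long <- simulate_longitudinal(m, a, NULL, flat_covariates(kin$ids), seed = 6)
  expect_equal(nrow(long), n * 3)
  s1 <- long$sbp[long$exam == 1]; s2 <- long$sbp[long$exam == 2]
  # independent environments: exam-to-exam correlation ~ h2
  expect_equal(stats::cor(s1, s2), m$h2_sbp, tolerance = 0.025)
  # ages advance by the exam interval
  expect_equal(long$age[long$exam == 3] - long$age[long$exam == 1],
               rep(2 * m$exam_interval_years, n))
})

test_that("perfect exam-to-exam correlation collapses to an age shift", {
  m <- trait_model(rho_e_time = 1)
  n <- 200
  kin <- identity_kinship(paste0("I", 1:n))
  a <- matrix(0, n, 2)
  long <- simulate_longitudinal(m, a, NULL, flat_covariates(kin$ids), seed = 7)
  s1 <- long$sbp[long$exam == 1]; s2 <- long$sbp[long$exam == 2]
  expect_equal(s2 - s1, rep(m$beta_age_sbp * m$exam_interval_years, n),
               tolerance = 1e-6)
})

test_that("a single exam reduces the longitudinal model to one draw", {
  m <- trait_model(n_exams = 1)
  n <- 100
  kin <- identity_kinship(paste0("I", 1:n))
  a <- with_seed(derive_seed(8, 1), bpsimr:::mvn_kinship(
    kin, residual_polygenic_cov(m)$sigma_a))
  cov <- flat_covariates(kin$ids)
  long <- simulate_longitudinal(m, a, NULL, cov, seed = 8)
  one <- simulate_bivariate_exam(m, a, NULL, cov, seed = 8)
  expect_equal(long$sbp, one$sbp)
  expect_equal(long$dbp, one$dbp)
})

test_that("Q1 is heritable through kinship and independent of genotypes", {
  # h2 = 0: i.i.d. with the requested variance
  kin0 <- pair_kinship(2500, 0.25)
  q0 <- simulate_q1(kin0, q1_h2 = 0, total_var = 2, seed = 1)
  expect_equal(stats::var(q0), 2, tolerance = 0.15)
  expect_lt(abs(stats::cor(q0[seq(1, 4999, 2)], q0[seq(2, 5000, 2)])), 0.05)
  # h2 = 0.68: parent-offspring correlation ~ 2 * phi * h2 = 0.34
  q1 <- simulate_q1(kin0, q1_h2 = 0.68, total_var = 1, seed = 2)
  expect_equal(stats::cor(q1[seq(1, 4999, 2)], q1[seq(2, 5000, 2)]),
               0.34, tolerance = 0.04)
})

test_that("Q1 association p-values against genotypes are uniform in unrelateds", {
  n <- 400
  kin <- identity_kinship(paste0("I", 1:n))
  set.seed(11)
  g <- matrix(stats::rbinom(50 * n, 2, 0.3), 50, n)
  pvals <- vapply(1:200, function(r) {
    q <- simulate_q1(kin, seed = derive_seed(99, r))
    i <- (r - 1) %% 50 + 1
    summary(stats::lm(q ~ g[i, ]))$coefficients[2, 4]
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("hypertension combines thresholds and medication use", {
  expect_true(hypertension_status(150, 80, FALSE))
  expect_true(hypertension_status(120, 95, FALSE))
  expect_true(hypertension_status(120, 70, TRUE))
  expect_false(hypertension_status(140, 90, FALSE))   # strict inequalities
  expect_false(hypertension_status(120, 70, FALSE))
})

test_that("carrier masks flag deleterious-variant carriers of one gene", {
  calls <- rbind(c(0L, 1L, 0L), c(0L, 0L, 2L), c(1L, 1L, 1L))
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                                   gene = c("CYP3A43", "CYP3A43", "OTHER"),
                                   annotation = c("highly_deleterious",
                                                  "nonsynonymous",
                                                  "highly_deleterious"),
                                   pp2s = c(0.99, 0.2, 0.95)),
                        ids = c("a", "b", "c"))
  expect_equal(unname(carrier_mask(gm, "CYP3A43")), c(FALSE, TRUE, FALSE))
  expect_false(any(carrier_mask(gm, "ABSENT")))
})

test_that("replicates are reproducible, with fixed demographics", {
  fx <- make_fixture(n_families = 4, n_children = 3, seed = 17)
  kin <- pedigree_kinship(fx$pedigree)
  m <- trait_model(n_replicates = 3)
  r1 <- run_replicates(m, kin, fx$covariates, fx$genotypes, seed = 5)
  r2 <- run_replicates(m, kin, fx$covariates, fx$genotypes, seed = 5)
  expect_identical(r1, r2)
  # age/sex fixed across replicates; draws differ
  expect_equal(r1[[1]]$age, r1[[3]]$age)
  expect_equal(r1[[1]]$sex, r1[[3]]$sex)
  expect_false(identical(r1[[1]]$sbp, r1[[2]]$sbp))
  expect_false(identical(r1[[1]]$q1, r1[[2]]$q1))
  # q1 constant within individual across exams; htn consistent
  d <- r1[[1]]
  expect_equal(unname(tapply(d$q1, d$id, function(v) length(unique(v)))),
               rep(1, length(unique(d$id))), ignore_attr = TRUE)
  expect_equal(d$htn, d$sbp > 140 | d$dbp > 90 | d$med)
})

test_that("replicate means converge to the modeled mean plus covariates", {
  n <- 30
  kin <- identity_kinship(paste0("I", 1:n))
  cov <- data.frame(id = kin$ids, age = 50, sex = "M")
  m <- trait_model(n_exams = 1)
  reps <- run_replicates(m, kin, cov, med = matrix(FALSE, n, 1),
                         n_replicates = 200, seed = 12, design = "unrelated")
  sbp_mean <- mean(vapply(reps, function(d) mean(d$sbp), numeric(1)))
  expected <- m$mu_sbp + m$beta_age_sbp * 10 + m$beta_sex_sbp
  expect_lt(abs(sbp_mean - expected),
            3 * sqrt(m$sigma2_sbp / (200 * n)) * 2)
})

test_that("Haseman-Elston regression recovers the configured heritability", {
  fams <- do.call(rbind, lapply(1:100, function(f) {
    data.frame(family = paste0("F", f),
               id = paste0("F", f, "_", 1:6),
               father = c(NA, NA, rep(paste0("F", f, "_1"), 4)),
               mother = c(NA, NA, rep(paste0("F", f, "_2"), 4)),
               sex = rep(c("M", "F"), 3))
  }))
  ped <- pedigree(fams$id, fams$father, fams$mother, fams$sex, fams$family)
  kin <- pedigree_kinship(ped)
  h2 <- vapply(1:60, function(r) {
    haseman_elston(simulate_q1(kin, q1_h2 = 0.68, seed = derive_seed(3, r)), kin)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.68), 0.05)
})
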