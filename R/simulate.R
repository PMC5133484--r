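# Phenotype simulation: kinship-structured polygenic values, bivariate exams,
# longitudinal structure, medication interaction, the null trait Q1, and the
# replicate driver.

# lower-triangular factor of the 2x2 cross-trait covariance (R with R %*% t(R))
cov2_factor <- function(v1, v2, rho) {
  s <- matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2L, 2L)
  t(chol(s + diag(1e-12, 2L)))
}

#' Residual polygenic covariance after variant effects
#'
#' The simulator keeps total heritability at the configured `h2` by assigning
#' the polygenic residual the variance `h2 * sigma2 - sum_j 2 p_j (1-p_j)
#' beta_j^2` per trait (floored at zero with a warning if the variants alone
#' exceed it), and the cross-trait genetic covariance
#' `rho_g_traits * sqrt(h2_s sigma2_s h2_d sigma2_d) - sum_j 2 p_j (1-p_j)
#' beta_sbp_j beta_dbp_j` (clamped so the residual matrix stays positive
#' semi-definite).
#'
#' @param model A [trait_model()].
#' @param effects Effect table from [build_effect_table()], or `NULL` for no
#'   variant effects.
#' @return List with `sigma_a` (2x2 residual polygenic covariance, sbp/dbp
#'   order) and `variant_var` (per-trait variance contributed by variants).
#' @export
residual_polygenic_cov <- function(model, effects = NULL) {
  v_s <- v_d <- v_sd <- 0
  if (!is.null(effects) && nrow(effects)) {
    w <- 2 * effects$freq * (1 - effects$freq)
    v_s <- sum(w * effects$beta_sbp^2)
    v_d <- sum(w * effects$beta_dbp^2)
    v_sd <- sum(w * effects$beta_sbp * effects$beta_dbp)
  }
  a_s <- model$h2_sbp * model$sigma2_sbp - v_s
  a_d <- model$h2_dbp * model$sigma2_dbp - v_d
  if (a_s < 0 || a_d < 0) {
    warning("variant effects exceed h2 * sigma2; residual polygenic variance floored at 0")
    a_s <- max(a_s, 0); a_d <- max(a_d, 0)
  }
  a_sd <- model$rho_g_traits *
    sqrt(model$h2_sbp * model$sigma2_sbp * model$h2_dbp * model$sigma2_dbp) - v_sd
  lim <- sqrt(a_s * a_d)
  a_sd <- min(max(a_sd, -lim), lim)
  sigma_a <- matrix(c(a_s, a_sd, a_sd, a_d), 2L, 2L,
                    dimnames = list(c("sbp", "dbp"), c("sbp", "dbp")))
  list(sigma_a = sigma_a, variant_var = list(sbp = v_s, dbp = v_d, sbp_dbp = v_sd))
}

# draw an n x k matrix with rows following the kinship structure and columns
# the k x k covariance sigma (matrix-normal: cov = sigma (x) 2*phi)
mvn_kinship <- function(kin, sigma, chols = NULL) {
  if (is.null(chols)) chols <- kinship_chol(kin)
  k <- nrow(sigma)
  rt <- t(chol(as.matrix(sigma) + diag(1e-12, k)))
  out <- matrix(0, length(kin$ids), k)
  # all identity (phi = I/2) families in one i.i.d. draw
  ident <- kin$family %in% names(kin$blocks)[vapply(kin$blocks, is.null,
                                                    logical(1L))]
  if (any(ident)) {
    out[ident, ] <- matrix(stats::rnorm(sum(ident) * k), sum(ident), k) %*% t(rt)
  }
  for (fam in unique(kin$family[!ident])) {
    sel <- which(kin$family == fam)
    z <- matrix(stats::rnorm(length(sel) * k), length(sel), k)
    out[sel, ] <- chols[[fam]] %*% z %*% t(rt)
  }
  rownames(out) <- kin$ids
  out
}

#' Simulate additive polygenic values over a kinship structure
#'
#' Draws a multivariate-normal vector with mean 0 and covariance
#' `2 * phi * sigma2_a`, sampled per family block through a Cholesky (or, for
#' semi-definite blocks, eigen) factorization. Identity kinship reduces to
#' i.i.d. `N(0, sigma2_a)`.
#'
#' @param kin A [kinship_matrix].
#' @param sigma2_a Additive genetic variance (>= 0).
#' @param seed Integer seed.
#' @param chols Optional precomputed factor list from the internal factorizer
#'   (reused across replicates by [run_replicates()]).
#' @return Named numeric vector of genetic values.
#' @export
simulate_polygenic <- function(kin, sigma2_a, seed, chols = NULL) {
  stopifnot(sigma2_a >= 0)
  a <- with_seed(derive_seed(seed, 1L),
                 mvn_kinship(kin, matrix(sigma2_a, 1L, 1L), chols))
  stats::setNames(a[, 1L], kin$ids)
}

#' Simulate one bivariate SBP/DBP exam
#'
#' Each trait is `mu + beta_age * (age - age_ref) + beta_sex * male +
#' variant_sum + a + e`, where the pair `(a_sbp, a_dbp)` is the supplied
#' polygenic value and `(e_sbp, e_dbp)` is drawn here with the model's
#' environmental variances `(1 - h2) * sigma2` and cross-trait correlation
#' `rho_e_traits`.
#'
#' @param model A [trait_model()].
#' @param genetic_values `n x 2` matrix (columns sbp, dbp) of polygenic values.
#' @param variant_effects `n x 2` matrix of per-individual summed variant
#'   effects (columns sbp, dbp); `NULL` for none.
#' @param covariates Data frame with `age` (years) and `sex` (`"M"`/`"F"`).
#' @param seed Integer seed.
#' @return Data frame with columns `sbp`, `dbp`.
#' @export
simulate_bivariate_exam <- function(model, genetic_values, variant_effects,
                                    covariates, seed) {
  n <- nrow(covariates)
  genetic_values <- as.matrix(genetic_values)
  if (nrow(genetic_values) != n) stop("genetic_values misaligned with covariates")
  if (is.null(variant_effects)) variant_effects <- matrix(0, n, 2L)
  if (nrow(variant_effects) != n) stop("variant_effects misaligned with covariates")
  e <- with_seed(derive_seed(seed, 2L), {
    z <- matrix(stats::rnorm(2L * n), n, 2L)
    re <- cov2_factor((1 - model$h2_sbp) * model$sigma2_sbp,
                      (1 - model$h2_dbp) * model$sigma2_dbp,
                      model$rho_e_traits)
    z %*% t(re)
  })
  male <- as.numeric(covariates$sex == "M")
  dage <- covariates$age - model$age_ref
  data.frame(
    sbp = model$mu_sbp + model$beta_age_sbp * dage + model$beta_sex_sbp * male +
      variant_effects[, 1L] + genetic_values[, 1L] + e[, 1L],
    dbp = model$mu_dbp + model$beta_age_dbp * dage + model$beta_sex_dbp * male +
      variant_effects[, 2L] + genetic_values[, 2L] + e[, 2L])
}

#' Apply the medication effect with its genotype interaction
#'
#' Treated individuals have SBP and DBP reduced by the configured treatment
#' effects — except carriers of deleterious variants in the interaction gene,
#' who do not respond. Untreated individuals are unchanged.
#'
#' @param sbp,dbp Numeric trait vectors.
#' @param med_status Logical treated indicator.
#' @param carrier_mask Logical non-responder (carrier) indicator.
#' @param model A [trait_model()].
#' @return List with adjusted `sbp` and `dbp`.
#' @export
apply_medication <- function(sbp, dbp, med_status, carrier_mask, model) {
  stopifnot(length(sbp) == length(dbp), length(sbp) == length(med_status),
            length(sbp) == length(carrier_mask))
  responds <- med_status & !carrier_mask
  list(sbp = sbp - model$med_effect_sbp * responds,
       dbp = dbp - model$med_effect_dbp * responds)
}

#' Randomly assign medication status
#'
#' Independent Bernoulli draws; intended to be called with a per-replicate
#' derived seed so assignments vary across replicates.
#'
#' @param n Number of individuals.
#' @param proportion Treatment probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Logical vector of length `n`.
#' @export
assign_medication <- function(n, proportion, seed) {
  if (proportion < 0 || proportion > 1) stop("proportion must lie in [0, 1]")
  with_seed(derive_seed(seed, 3L),
            stats::runif(n) < proportion)
}

# environmental correlation matrix across exams
exam_corr_matrix <- function(model) {
  t_ex <- model$n_exams
  r <- model$env_corr_exams
  if (is.null(r)) {
    r <- matrix(model$rho_e_time, t_ex, t_ex)
    diag(r) <- 1
  }
  r
}

#' Simulate longitudinal bivariate exams
#'
#' The genetic contribution (polygenic values plus variant effects) is
#' identical at every exam; environmental deviations are drawn with the
#' configured exam-to-exam correlation structure (exchangeable `rho_e_time` by
#' default, or a full matrix), and ages advance by `exam_interval_years` per
#' exam. With `n_exams = 1` this reduces to [simulate_bivariate_exam()].
#'
#' @inheritParams simulate_bivariate_exam
#' @return Data frame with columns `exam`, `id`, `age`, `sex`, `sbp`, `dbp`
#'   (exam-major, `n * n_exams` rows).
#' @export
simulate_longitudinal <- function(model, genetic_values, variant_effects,
                                  covariates, seed) {
  n <- nrow(covariates)
  t_ex <- model$n_exams
  genetic_values <- as.matrix(genetic_values)
  if (is.null(variant_effects)) variant_effects <- matrix(0, n, 2L)
  r_time <- exam_corr_matrix(model)
  lt <- tryCatch(t(chol(r_time)),
                 error = function(e) {
                   ev <- eigen(r_time, symmetric = TRUE)
                   if (any(ev$values < -1e-8)) stop("env_corr_exams is not positive semi-definite")
                   ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), t_ex)
                 })
  re <- cov2_factor((1 - model$h2_sbp) * model$sigma2_sbp,
                    (1 - model$h2_dbp) * model$sigma2_dbp,
                    model$rho_e_traits)
  env <- with_seed(derive_seed(seed, 2L), {
    f <- lapply(seq_len(t_ex), function(k) {
      matrix(stats::rnorm(2L * n), n, 2L) %*% t(re)
    })
    lapply(seq_len(t_ex), function(t) {
      e_t <- matrix(0, n, 2L)
      for (k in seq_len(t_ex)) e_t <- e_t + lt[t, k] * f[[k]]
      e_t
    })
  })
  male <- as.numeric(covariates$sex == "M")
  out <- vector("list", t_ex)
  for (t in seq_len(t_ex)) {
    age_t <- covariates$age + (t - 1L) * model$exam_interval_years
    dage <- age_t - model$age_ref
    out[[t]] <- data.frame(
      exam = t, id = covariates$id, age = age_t, sex = covariates$sex,
      sbp = model$mu_sbp + model$beta_age_sbp * dage +
        model$beta_sex_sbp * male + variant_effects[, 1L] +
        genetic_values[, 1L] + env[[t]][, 1L],
      dbp = model$mu_dbp + model$beta_age_dbp * dage +
        model$beta_sex_dbp * male + variant_effects[, 2L] +
        genetic_values[, 2L] + env[[t]][, 2L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate the heritable null trait Q1
#'
#' `q1 = a + e` with `a ~ MVN(0, 2 phi h2 sigma2)` and `e` i.i.d.
#' `N(0, (1 - h2) sigma2)`. No sequence variant ever contributes, so Q1 is a
#' pure type-I-error benchmark for association methods.
#'
#' @param kin A [kinship_matrix].
#' @param q1_h2 Heritability (default 0.68).
#' @param total_var Total variance (default 1).
#' @param seed Integer seed.
#' @param chols Optional precomputed kinship factors.
#' @return Named numeric vector.
#' @export
simulate_q1 <- function(kin, q1_h2 = 0.68, total_var = 1, seed, chols = NULL) {
  stopifnot(q1_h2 >= 0, q1_h2 <= 1, total_var > 0)
  n <- length(kin$ids)
  with_seed(derive_seed(seed, 4L), {
    a <- mvn_kinship(kin, matrix(q1_h2 * total_var, 1L, 1L), chols)[, 1L]
    e <- stats::rnorm(n, sd = sqrt((1 - q1_h2) * total_var))
    stats::setNames(a + e, kin$ids)
  })
}

#' Hypertension status
#'
#' `SBP > 140`, `DBP > 90`, and/or current use of antihypertensive medication
#' (strict inequalities).
#'
#' @param sbp,dbp Numeric pressures (mmHg).
#' @param med Logical medication-use indicator.
#' @return Logical vector.
#' @export
hypertension_status <- function(sbp, dbp, med) {
  sbp > 140 | dbp > 90 | as.logical(med)
}

#' Per-individual summed variant effects
#'
#' `n x 2` matrix of `sum_j beta_j g_ij` for SBP and DBP. Missing calls are
#' imputed to the variant mean `2 p`.
#'
#' @param gm A [genotype_matrix()].
#' @param effects Effect table from [build_effect_table()]; its `orig_index`
#'   column addresses rows of `gm`.
#' @return Matrix with columns `sbp`, `dbp` and one row per individual.
#' @export
variant_effect_sums <- function(gm, effects) {
  n <- length(gm$ids)
  if (is.null(effects) || nrow(effects) == 0L) {
    return(matrix(0, n, 2L, dimnames = list(gm$ids, c("sbp", "dbp"))))
  }
  g <- gm$calls[effects$orig_index, , drop = FALSE]
  if (anyNA(g)) {
    mu <- 2 * effects$freq
    for (i in seq_len(nrow(g))) g[i, is.na(g[i, ])] <- mu[i]
  }
  out <- cbind(sbp = as.numeric(crossprod(g, effects$beta_sbp)),
               dbp = as.numeric(crossprod(g, effects$beta_dbp)))
  rownames(out) <- gm$ids
  out
}

#' Carriers of deleterious variants in a gene
#'
#' Default carrier rule for the genotype-by-medication interaction: an
#' individual carries at least one alternate allele at any variant of the gene
#' annotated `highly_deleterious` or with PP2S at or above `pp2s_min`.
#'
#' @param gm A [genotype_matrix()] with annotated variants.
#' @param gene Gene symbol.
#' @param pp2s_min PP2S cutoff (default 0.85).
#' @return Logical vector, one per individual.
#' @export
carrier_mask <- function(gm, gene, pp2s_min = 0.85) {
  v <- gm$variants
  sel <- !is.na(v$gene) & v$gene == gene &
    ((!is.na(v$annotation) & v$annotation == "highly_deleterious") |
       (!is.na(v$pp2s) & v$pp2s >= pp2s_min))
  if (!any(sel)) return(stats::setNames(rep(FALSE, length(gm$ids)), gm$ids))
  colSums(gm$calls[sel, , drop = FALSE] >= 1L, na.rm = TRUE) > 0L
}

#' Generate replicated phenotype data
#'
#' The replicate driver: ages and sexes stay fixed across replicates while all
#' genetic and environmental draws, medication assignment (when random) and Q1
#' are refreshed per replicate from seeds derived as `(seed, replicate,
#' component)`, so replicate `r` is reproducible in isolation.
#'
#' @param model A [trait_model()].
#' @param kin A [kinship_matrix] over the simulated individuals.
#' @param covariates Data frame with `id`, `age`, `sex` aligned with `kin`.
#' @param genotypes Optional [genotype_matrix()] supplying variant genotypes.
#' @param effects Optional effect table ([build_effect_table()]).
#' @param carriers Optional logical non-responder mask; defaults to
#'   [carrier_mask()] on `model$interaction_gene` when genotypes are annotated,
#'   else no carriers.
#' @param med Optional observed medication status: a logical `n x n_exams`
#'   matrix (or length-`n` vector, recycled across exams) held fixed across
#'   replicates, as when usage is taken from real data. `NULL` assigns
#'   Bernoulli(`model$med_proportion`) status per replicate.
#' @param n_replicates Number of replicates (default `model$n_replicates`).
#' @param seed Integer seed.
#' @param design `"family"` (longitudinal, `model$n_exams` exams) or
#'   `"unrelated"` (single exam).
#' @return List of per-replicate data frames with columns `rep`, `id`, `exam`,
#'   `age`, `sex`, `sbp`, `dbp`, `med`, `htn`, `q1`.
#' @export
run_replicates <- function(model, kin, covariates, genotypes = NULL,
                           effects = NULL, carriers = NULL, med = NULL,
                           n_replicates = model$n_replicates, seed = 1L,
                           design = c("family", "unrelated")) {
  design <- match.arg(design)
  n <- length(kin$ids)
  stopifnot(nrow(covariates) == n)
  if (!all(covariates$id == kin$ids)) stop("covariates must align with kinship ids")
  t_ex <- if (design == "unrelated") 1L else model$n_exams
  model_run <- model
  model_run$n_exams <- t_ex

  vsum <- if (is.null(genotypes)) NULL else variant_effect_sums(genotypes, effects)
  if (is.null(carriers)) {
    carriers <- if (!is.null(genotypes) && "gene" %in% names(genotypes$variants)) {
      carrier_mask(genotypes, model$interaction_gene)
    } else rep(FALSE, n)
  }
  if (!is.null(med)) {
    med <- if (is.matrix(med)) med else matrix(med, n, t_ex)
    stopifnot(nrow(med) == n, ncol(med) == t_ex)
  }
  vc <- residual_polygenic_cov(model, effects)
  chols <- kinship_chol(kin)

  lapply(seq_len(n_replicates), function(r) {
    a <- with_seed(derive_seed(seed, r, 1L),
                   mvn_kinship(kin, vc$sigma_a, chols))
    long <- simulate_longitudinal(model_run, a, vsum, covariates,
                                  seed = derive_seed(seed, r, 2L))
    med_r <- if (is.null(med)) {
      matrix(assign_medication(n * t_ex, model$med_proportion,
                               derive_seed(seed, r, 3L)), n, t_ex)
    } else med
    q1 <- simulate_q1(kin, model$q1_h2, model$q1_var,
                      seed = derive_seed(seed, r, 4L), chols = chols)
    long$med <- as.logical(med_r[cbind(rep(seq_len(n), t_ex), long$exam)])
    adj <- apply_medication(long$sbp, long$dbp, long$med,
                            rep(carriers, t_ex), model)
    long$sbp <- adj$sbp
    long$dbp <- adj$dbp
    long$htn <- hypertension_status(long$sbp, long$dbp, long$med)
    long$q1 <- rep(unname(q1), t_ex)
    cbind(rep = r, long)
  })
}

#' Simulate method for trait models
#'
#' Convenience wrapper around [run_replicates()] following the base-R
#' [stats::simulate()] contract.
#'
#' @param object A [trait_model()].
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param kin,covariates,... Passed to [run_replicates()].
#' @return List of per-replicate data frames.
#' @export
simulate.trait_model <- function(object, nsim = 1, seed = 1L, kin, covariates,
                                 ...) {
  run_replicates(object, kin, covariates, n_replicates = nsim, seed = seed, ...)
}

#' Haseman-Elston estimate of narrow-sense heritability
#'
#' Regresses, over all related pairs (phi > 0) within family blocks, the
#' cross-products of the standardized trait on `2 * phi` without an intercept
#' (unrelated pairs have expected cross-product zero after standardization).
#' The slope estimates `h2` when the trait's total variance is its sample
#' variance.
#'
#' @param y Numeric trait vector aligned with `kin`.
#' @param kin A [kinship_matrix].
#' @return The heritability estimate (unbounded; may fall outside `[0, 1]` by
#'   sampling error).
#' @export
haseman_elston <- function(y, kin) {
  z <- as.numeric(scale(y))
  num <- 0; den <- 0
  for (fam in unique(kin$family)) {
    b <- kin$blocks[[fam]]
    if (is.null(b) || nrow(b) < 2L) next
    sel <- which(kin$family == fam)
    ut <- which(upper.tri(b), arr.ind = TRUE)
    phi2 <- 2 * b[ut]
    rel <- phi2 > 0
    if (!any(rel)) next
    cp <- z[sel[ut[, 1L]]] * z[sel[ut[, 2L]]]
    num <- num + sum(cp[rel] * phi2[rel])
    den <- den + sum(phi2[rel]^2)
  }
  if (den == 0) stop("no related pairs; heritability is not estimable")
  num / den
}
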