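# Full parameterization of the phenotype simulator.

#' Trait-model parameterization
#'
#' Collects every parameter of the bivariate blood-pressure simulation: trait
#' means and total variances, narrow-sense heritabilities, the genetic and
#' environmental correlations between SBP and DBP, covariate effects, the
#' antihypertensive-medication effect and the gene whose deleterious-variant
#' carriers do not respond to it, the longitudinal design (number of exams,
#' exam spacing, exam-to-exam environmental correlation), and the heritable
#' null trait Q1.
#'
#' Defaults describe a realistic adult cohort: means 125/74 mmHg, total
#' variances 238.6 (SBP) and 88.4 (DBP) mmHg^2, heritabilities 0.30, a
#' genetic correlation of 0.65 and an environmental correlation of 0.35
#' between the two pressures, age slopes of +0.5 / +0.2 mmHg per year
#' (centered at `age_ref` = 40), male-female differences of +4 / +3 mmHg, and
#' treatment reductions of 10 / 5 mmHg. Q1 has heritability 0.68 and unit
#' variance and never receives variant effects.
#'
#' @param mu_sbp,mu_dbp Trait means (mmHg).
#' @param sigma2_sbp,sigma2_dbp Total phenotypic variances (mmHg^2), > 0.
#' @param h2_sbp,h2_dbp Narrow-sense heritabilities in `[0, 1]`.
#' @param rho_g_traits,rho_e_traits Genetic / environmental SBP-DBP
#'   correlations in `[-1, 1]`.
#' @param beta_age_sbp,beta_age_dbp Age effects (mmHg per year), non-negative
#'   under the default configuration.
#' @param beta_sex_sbp,beta_sex_dbp Male minus female mean difference (mmHg),
#'   non-negative under the default configuration.
#' @param age_ref Centering age for the age effect (years).
#' @param med_effect_sbp,med_effect_dbp Treatment reductions (mmHg, >= 0).
#' @param med_proportion Proportion treated, used when medication status is
#'   assigned at random.
#' @param interaction_gene Gene whose deleterious-variant carriers are
#'   non-responders to treatment.
#' @param n_exams Number of exams (>= 1); default 3.
#' @param exam_interval_years Years between exams; default 5.
#' @param rho_e_time Exchangeable exam-to-exam environmental correlation, or a
#'   full `n_exams x n_exams` correlation matrix via `env_corr_exams`.
#' @param env_corr_exams Optional full environmental correlation matrix across
#'   exams (overrides `rho_e_time`).
#' @param q1_h2 Heritability of the null trait Q1; default 0.68.
#' @param q1_var Total variance of Q1; default 1.
#' @param n_replicates Default number of replicates; default 200.
#' @return An object of class `trait_model`.
#' @seealso [run_replicates()], [simulate.trait_model()]
#' @export
trait_model <- function(mu_sbp = 125, mu_dbp = 74,
                        sigma2_sbp = 238.6, sigma2_dbp = 88.4,
                        h2_sbp = 0.30, h2_dbp = 0.30,
                        rho_g_traits = 0.65, rho_e_traits = 0.35,
                        beta_age_sbp = 0.5, beta_age_dbp = 0.2,
                        beta_sex_sbp = 4, beta_sex_dbp = 3,
                        age_ref = 40,
                        med_effect_sbp = 10, med_effect_dbp = 5,
                        med_proportion = 0.18,
                        interaction_gene = "CYP3A43",
                        n_exams = 3, exam_interval_years = 5,
                        rho_e_time = 0.5, env_corr_exams = NULL,
                        q1_h2 = 0.68, q1_var = 1,
                        n_replicates = 200) {
  if (sigma2_sbp <= 0 || sigma2_dbp <= 0) stop("total variances must be positive")
  for (h in c(h2_sbp, h2_dbp, q1_h2)) {
    if (h < 0 || h > 1) stop("heritabilities must lie in [0, 1]")
  }
  for (r in c(rho_g_traits, rho_e_traits)) {
    if (abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  if (h2_sbp >= 1 || h2_dbp >= 1) {
    stop("implied environmental variance (1 - h2) * sigma2 must be positive")
  }
  if (med_effect_sbp < 0 || med_effect_dbp < 0) {
    stop("medication effects are reductions and must be >= 0")
  }
  if (med_proportion < 0 || med_proportion > 1) stop("med_proportion in [0, 1]")
  if (n_exams < 1) stop("n_exams must be >= 1")
  if (!is.null(env_corr_exams)) {
    env_corr_exams <- as.matrix(env_corr_exams)
    if (!all(dim(env_corr_exams) == n_exams)) {
      stop("env_corr_exams must be n_exams x n_exams")
    }
  }
  structure(list(mu_sbp = mu_sbp, mu_dbp = mu_dbp,
                 sigma2_sbp = sigma2_sbp, sigma2_dbp = sigma2_dbp,
                 h2_sbp = h2_sbp, h2_dbp = h2_dbp,
                 rho_g_traits = rho_g_traits, rho_e_traits = rho_e_traits,
                 beta_age_sbp = beta_age_sbp, beta_age_dbp = beta_age_dbp,
                 beta_sex_sbp = beta_sex_sbp, beta_sex_dbp = beta_sex_dbp,
                 age_ref = age_ref,
                 med_effect_sbp = med_effect_sbp,
                 med_effect_dbp = med_effect_dbp,
                 med_proportion = med_proportion,
                 interaction_gene = interaction_gene,
                 n_exams = as.integer(n_exams),
                 exam_interval_years = exam_interval_years,
                 rho_e_time = rho_e_time, env_corr_exams = env_corr_exams,
                 q1_h2 = q1_h2, q1_var = q1_var,
                 n_replicates = as.integer(n_replicates)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Bivariate blood-pressure trait model\n")
  cat(sprintf("  SBP: mean %.1f, variance %.1f, h2 %.2f\n",
              x$mu_sbp, x$sigma2_sbp, x$h2_sbp))
  cat(sprintf("  DBP: mean %.1f, variance %.1f, h2 %.2f\n",
              x$mu_dbp, x$sigma2_dbp, x$h2_dbp))
  cat(sprintf("  SBP-DBP correlations: genetic %.2f, environmental %.2f\n",
              x$rho_g_traits, x$rho_e_traits))
  cat(sprintf("  exams: %d at %.0f-year intervals (rho_e_time %.2f)\n",
              x$n_exams, x$exam_interval_years, x$rho_e_time))
  cat(sprintf("  medication: -%.0f/-%.0f mmHg, non-responder gene %s\n",
              x$med_effect_sbp, x$med_effect_dbp, x$interaction_gene))
  cat(sprintf("  Q1: h2 %.2f, variance %.2f; %d replicates\n",
              x$q1_h2, x$q1_var, x$n_replicates))
  invisible(x)
}

#' @export
summary.trait_model <- function(object, effects = NULL, ...) {
  vc <- residual_polygenic_cov(object, effects)
  cat("Variance decomposition (per trait: variant + residual polygenic + environmental)\n")
  for (t in c("sbp", "dbp")) {
    s2 <- object[[paste0("sigma2_", t)]]
    h2 <- object[[paste0("h2_", t)]]
    vvar <- vc$variant_var[[t]]
    cat(sprintf("  %s: %.2f = %.2f + %.2f + %.2f (h2 = %.2f)\n",
                toupper(t), s2, vvar, vc$sigma_a[t, t], (1 - h2) * s2, h2))
  }
  invisible(vc)
}
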