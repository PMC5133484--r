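# Shared fixtures and independent oracles, kept deliberately separate from the
# implementation paths they check.

ped_trio <- function() {
  pedigree(id = c("f", "m", "c"),
           father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
           sex = c("M", "F", "F"))
}

ped_sibs <- function(k = 2) {
  pedigree(id = c("f", "m", paste0("c", seq_len(k))),
           father = c(NA, NA, rep("f", k)),
           mother = c(NA, NA, rep("m", k)),
           sex = c("M", "F", rep(c("M", "F"), length.out = k)))
}

# first cousins: two sibs marry unrelated spouses, one child each (8 members)
ped_cousins <- function() {
  pedigree(
    id     = c("g1", "g2", "s1", "s2", "x1", "x2", "k1", "k2"),
    father = c(NA,   NA,   "g1", "g1", NA,   NA,   "s1", "s2"),
    mother = c(NA,   NA,   "g2", "g2", NA,   NA,   "x1", "x2"),
    sex    = c("M",  "F",  "M",  "M",  "F",  "F",  "M",  "F"))
}

# Exhaustive-inheritance-vector kinship oracle: enumerates every possible
# transmission pattern, labels founder alleles uniquely, and averages the
# probability that a random allele from i is identical by descent with a
# random allele from j. Only feasible for small pedigrees.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  ord <- attr(ped, "order")
  nonf <- ord[!is.na(ped$father[ord])]
  ncomb <- 4^length(nonf)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (r in seq_len(ncomb) - 1L) {
    al <- matrix(0L, n, 2L)
    cnt <- 0L
    code <- r
    choice <- integer(length(nonf))
    for (q in seq_along(nonf)) {
      choice[q] <- code %% 4L
      code <- code %/% 4L
    }
    for (i in ord) {
      if (is.na(ped$father[i])) {
        al[i, ] <- c(cnt + 1L, cnt + 2L)
        cnt <- cnt + 2L
      } else {
        ch <- choice[match(i, nonf)]
        fa <- idx[[ped$father[i]]]; mo <- idx[[ped$mother[i]]]
        al[i, 1L] <- al[fa, ch %% 2L + 1L]
        al[i, 2L] <- al[mo, ch %/% 2L + 1L]
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      phi[i, j] <- phi[i, j] +
        sum(outer(al[i, ], al[j, ], "==")) / 4
    }
  }
  phi / ncomb
}

# HWE exact-test oracle by direct enumeration of genotype configurations:
# P(het = h | n, nA) = [n! / (hom_a! h! hom_b!)] * 2^h / choose(2n, nA),
# computed termwise with choose()/factorial() rather than the normalized
# log-sum route used by the implementation.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa           # alternate allele count
  prob_h <- function(h) {
    hom_alt <- (na - h) / 2
    hom_ref <- n - h - hom_alt
    if (hom_alt < 0 || hom_ref < 0) return(0)
    exp(lfactorial(n) - lfactorial(hom_alt) - lfactorial(h) -
          lfactorial(hom_ref) + h * log(2) - lchoose(2 * n, na))
  }
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, prob_h, numeric(1))
  obs <- prob_h(n_Aa)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent binomial upper-tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# HWE genotype sampler for empirical-kinship checks
hwe_genotypes <- function(n_ind, freqs) {
  vapply(seq_len(n_ind), function(i) stats::rbinom(length(freqs), 2, freqs),
         numeric(length(freqs)))
}

make_gm <- function(calls, ...) {
  calls <- as.matrix(calls)
  genotype_matrix(calls,
                  data.frame(chrom = "1", pos = seq_len(nrow(calls)),
                             ref = "A", alt = "G", ...),
                  ids = paste0("I", seq_len(ncol(calls))))
}
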