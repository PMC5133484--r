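# Kinship matrices: pedigree-derived (recursive) and SNV-based empirical.
#
# Kinship is stored block-diagonally by family so that large collections of
# unrelated individuals (or many independent pedigrees) never materialize an
# n x n dense matrix. A block value of NULL marks an identity family
# (phi = 0.5 on the diagonal, 0 off it), which gives sampling code a fast
# i.i.d. path.

new_kinship_matrix <- function(ids, family, blocks) {
  structure(list(ids = ids, family = family, blocks = blocks),
            class = "kinship_matrix")
}

#' Kinship matrix objects
#'
#' A `kinship_matrix` stores per-pair kinship coefficients phi block-wise by
#' family (individuals in different families have phi = 0). `as.matrix`
#' assembles the dense symmetric matrix; `identity_kinship` builds the
#' unrelated-individuals case phi = I/2.
#'
#' @param x,object A `kinship_matrix`.
#' @param ids Individual ids.
#' @param ... Unused.
#' @name kinship_matrix
NULL

#' @rdname kinship_matrix
#' @export
identity_kinship <- function(ids) {
  ids <- as.character(ids)
  new_kinship_matrix(ids, family = ids,
                     blocks = stats::setNames(vector("list", length(ids)), ids))
}

#' @rdname kinship_matrix
#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  n <- length(x$ids)
  phi <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  for (fam in unique(x$family)) {
    sel <- which(x$family == fam)
    b <- x$blocks[[fam]]
    if (is.null(b)) {
      phi[cbind(sel, sel)] <- 0.5
    } else {
      phi[sel, sel] <- b
    }
  }
  phi
}

#' @rdname kinship_matrix
#' @export
print.kinship_matrix <- function(x, ...) {
  nfam <- length(unique(x$family))
  cat(sprintf("Kinship matrix: %d individuals, %d family block%s\n",
              length(x$ids), nfam, if (nfam == 1L) "" else "s"))
  invisible(x)
}

#' Pedigree-derived kinship coefficients
#'
#' Computes the kinship coefficient phi for every pair of individuals by the
#' standard recursion, processing parents before children: for a non-founder
#' `i` with parents `f` and `m`, `phi(i,i) = (1 + phi(f,m)) / 2` and
#' `phi(i,j) = (phi(f,j) + phi(m,j)) / 2` for any `j` that is not a descendant
#' of `i`. Founders are taken as non-inbred and mutually unrelated, so
#' `phi(i,i) = 0.5` for them. Individuals in different families have phi = 0.
#'
#' @param ped A [pedigree()].
#' @return A [kinship_matrix] over the pedigree's individuals, in input order.
#' @export
#' @examples
#' trio <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
#'                  c("M", "F", "F"))
#' as.matrix(pedigree_kinship(trio))   # parent-offspring phi = 0.25
pedigree_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  blocks <- list()
  for (fam in unique(ped$family)) {
    sub <- ped[ped$family == fam, , drop = FALSE]
    ord <- ped_topological_order(sub)
    n <- nrow(sub)
    phi <- matrix(0, n, n, dimnames = list(sub$id, sub$id))
    idx <- stats::setNames(seq_len(n), sub$id)
    done <- logical(n)
    for (i in ord) {
      fa <- sub$father[i]; mo <- sub$mother[i]
      if (is.na(fa)) {                       # founder
        phi[i, i] <- 0.5                     # phi with earlier ids stays 0
      } else {
        fi <- idx[[fa]]; mi <- idx[[mo]]
        phi[i, i] <- 0.5 * (1 + phi[fi, mi])
        prev <- which(done)
        prev <- prev[prev != i]
        if (length(prev)) {
          v <- 0.5 * (phi[fi, prev] + phi[mi, prev])
          phi[i, prev] <- v
          phi[prev, i] <- v
        }
      }
      done[i] <- TRUE
    }
    blocks[[fam]] <- phi
  }
  new_kinship_matrix(ped$id, ped$family, blocks)
}

#' SNV-based empirical kinship (GRM / 2)
#'
#' Estimates kinship between all pairs of individuals from genotype data with
#' the allele-frequency-standardized cross-product (genomic relationship
#' matrix) estimator,
#' `phi_ij = sum_m (g_im - 2 p_m)(g_jm - 2 p_m) / (2 p_m (1 - p_m)) / (2 M)`,
#' where `p_m` is the sample allele frequency of variant `m` and `M` the number
#' of variants retained. On the kinship scale a duplicated sample has expected
#' phi of 0.5. Missing genotypes are imputed to the variant mean `2 p_m` before
#' standardization; variants with minor allele frequency at or below `min_maf`
#' are excluded.
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf Minor-allele-frequency filter in `[0, 0.5)`; variants with
#'   `MAF <= min_maf` are dropped (so the default 0 drops monomorphic sites).
#' @return A [kinship_matrix] with a single all-individuals block.
#' @export
empirical_kinship <- function(gm, min_maf = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$ids) < 2L) stop("empirical kinship needs at least 2 individuals")
  g <- gm$calls                              # variants x individuals
  p <- allele_frequency(gm)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep)) stop("no polymorphic variants left after the MAF filter")
  g <- g[keep, , drop = FALSE]
  p <- p[keep]
  m <- nrow(g)
  centered <- sweep(g, 1L, 2 * p)
  centered[is.na(centered)] <- 0             # mean imputation of missing calls
  z <- centered / sqrt(2 * p * (1 - p))
  phi <- crossprod(z) / (2 * m)
  dimnames(phi) <- list(gm$ids, gm$ids)
  new_kinship_matrix(gm$ids, family = rep("ALL", length(gm$ids)),
                     blocks = list(ALL = phi))
}

is_identity_block <- function(kin) {
  vapply(kin$blocks, is.null, logical(1L))
}

# Cholesky-like factors of 2*phi per family block, lower-triangular, so that
# L %*% t(L) = 2*phi. Identity blocks yield NULL (fast i.i.d. path). Small
# negative eigenvalues within tol are clamped; larger ones are an error.
kinship_chol <- function(kin, tol = 1e-8) {
  lapply(kin$blocks, function(b) {
    if (is.null(b)) return(NULL)
    a <- 2 * b
    L <- tryCatch(t(chol(a)), error = function(e) NULL)
    if (is.null(L)) {
      e <- eigen(a, symmetric = TRUE)
      if (any(e$values < -tol * max(abs(e$values), 1))) {
        stop("kinship block is not positive semi-definite")
      }
      L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(a))
    }
    L
  })
}

#' Write a kinship matrix to a text file
#'
#' @param kin A [kinship_matrix].
#' @param path Output path.
#' @param format `"lower"` writes the non-zero lower triangle (including the
#'   diagonal) as `id1 id2 phi` triples; `"square"` writes the dense matrix
#'   with row/column ids.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path, format = c("lower", "square")) {
  format <- match.arg(format)
  if (format == "square") {
    m <- as.matrix(kin)
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       path, quote = FALSE, row.names = FALSE, sep = "\t")
  } else {
    rows <- list()
    for (fam in unique(kin$family)) {
      sel <- which(kin$family == fam)
      b <- kin$blocks[[fam]]
      if (is.null(b)) {
        rows[[fam]] <- data.frame(id1 = kin$ids[sel], id2 = kin$ids[sel],
                                  phi = 0.5)
      } else {
        lt <- which(lower.tri(b, diag = TRUE), arr.ind = TRUE)
        rows[[fam]] <- data.frame(id1 = kin$ids[sel][lt[, 1L]],
                                  id2 = kin$ids[sel][lt[, 2L]],
                                  phi = b[lt])
      }
    }
    utils::write.table(do.call(rbind, rows), path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  invisible(path)
}
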