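# Pedigree representation and validation.

#' Construct a pedigree
#'
#' A pedigree records, for each individual, its father, mother, sex and family.
#' Founders have both parents missing; non-founders must have both parents
#' present (single known parents are not representable). Validation rejects
#' cyclic structures (an individual that is its own ancestor) and references to
#' parents that are not themselves listed.
#'
#' @param id Character vector of unique individual identifiers.
#' @param father,mother Character vectors of parental ids; `NA`, `""` or `"0"`
#'   denote a missing parent.
#' @param sex Sex codes: `"M"`/`"F"`, or `1`/`2` (PLINK convention, 1 = male).
#' @param family Family identifiers; defaults to a single family `"F1"`.
#' @return An object of class `pedigree`: a data frame with columns `family`,
#'   `id`, `father`, `mother`, `sex`, plus an attribute `order` giving a
#'   parents-before-children (topological) permutation of the rows.
#' @seealso [read_pedigree()], [pedigree_kinship()], [gene_drop()]
#' @export
#' @examples
#' trio <- pedigree(id = c("f", "m", "c"),
#'                  father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"),
#'                  sex = c("M", "F", "F"))
#' founders(trio)
pedigree <- function(id, father, mother, sex, family = rep("F1", length(id))) {
  id     <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  family <- as.character(family)
  father[father %in% c("0", "", "NA")] <- NA_character_
  mother[mother %in% c("0", "", "NA")] <- NA_character_

  if (length(id) == 0L) stop("empty pedigree")
  if (anyDuplicated(id)) stop("duplicated individual ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  n <- length(id)
  stopifnot(length(father) == n, length(mother) == n,
            length(sex) == n, length(family) == n)

  sex <- toupper(as.character(sex))
  sex[sex == "1"] <- "M"
  sex[sex == "2"] <- "F"
  if (!all(sex %in% c("M", "F"))) {
    stop("sex must be coded M/F or 1/2")
  }

  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent)) {
    stop("individuals with exactly one known parent: ",
         paste(id[one_parent], collapse = ", "),
         " (founders must have both parents missing)")
  }
  for (p in c(stats::na.omit(father), stats::na.omit(mother))) {
    if (!p %in% id) stop("unknown parent id: ", p)
  }

  ped <- data.frame(family = family, id = id, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)
  attr(ped, "order") <- ped_topological_order(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors on cycles (individual its own ancestor).
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  indeg <- integer(n)
  children <- vector("list", n)   # children[[parent]] = child indices
  for (i in seq_len(n)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("cyclic pedigree: ",
         paste(ped$id[setdiff(seq_len(n), out)], collapse = ", "))
  }
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d famil%s (%d founders)\n",
              nrow(x), length(unique(x$family)),
              if (length(unique(x$family)) == 1L) "y" else "ies",
              sum(is_founder(x))))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Founder indicators and founder ids
#'
#' @param ped A [pedigree()].
#' @return `is_founder` returns a logical vector aligned with the pedigree
#'   rows; `founders` returns the founder ids.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' @rdname is_founder
#' @export
founders <- function(ped) ped$id[is_founder(ped)]

#' Read a pedigree from a PLINK .fam-style file
#'
#' Whitespace-delimited columns FID, IID, FATHER, MOTHER, SEX (additional
#' columns such as a phenotype are ignored). `0` or `NA` denotes a missing
#' parent; sex is 1 = male, 2 = female.
#'
#' @param path File path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 5L) stop("pedigree file needs >= 5 columns (FID IID FATHER MOTHER SEX)")
  pedigree(id = tab[[2L]], father = tab[[3L]], mother = tab[[4L]],
           sex = tab[[5L]], family = tab[[1L]])
}

#' Write a pedigree to a PLINK .fam-style file
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  out$sex <- ifelse(out$sex == "M", "1", "2")
  utils::write.table(out[, c("family", "id", "father", "mother", "sex")],
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
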