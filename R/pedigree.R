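#' Pedigree objects
#'
#' A pedigree is an ordered set of individuals, each with an optional sire
#' and dam. Founders (e.g. wild-caught spawning adults) have both parents
#' unknown. Input rows may be in any order; individuals are re-ordered
#' topologically (parents before offspring) on construction.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers; use `NA` or `""`
#'   for unknown parents. A parent must itself appear in `id`.
#' @return An object of class `"pedigree"`: a list with elements `id`
#'   (character), `sire` and `dam` (integer indices into `id`, `NA` for
#'   founders).
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' additive_relationship_matrix(ped)["s", "o"]  # parent-offspring: 0.5
#' @export
pedigree <- function(id, sire = NA, dam = NA) {
  id <- as.character(id)
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  sire[!is.na(sire) & sire == ""] <- NA
  dam[!is.na(dam) & dam == ""] <- NA
  if (anyDuplicated(id)) {
    stop("duplicated individual ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- setdiff(c(sire, dam), c(id, NA))
  if (length(bad)) {
    stop("parent ids not present in pedigree: ", paste(bad, collapse = ", "))
  }
  si <- match(sire, id)
  di <- match(dam, id)

  ## Kahn topological sort; failure to place everyone means a cycle
  ## (an individual that is its own ancestor).
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (length(order) < n) {
    stop("cyclic pedigree: ", paste(id[!placed], collapse = ", "))
  }
  id <- id[order]
  si <- match(sire[order], id)
  di <- match(dam[order], id)
  structure(list(id = id, sire = si, dam = di), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$id), "individuals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  invisible(x)
}

#' @export
length.pedigree <- function(x) length(x$id)

#' @rdname pedigree
#' @param df a data frame with columns `id`, `sire`, `dam`.
#' @export
as_pedigree <- function(df) {
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  pedigree(df$id, df$sire, df$dam)
}

#' @rdname pedigree
#' @param x a pedigree.
#' @param ... unused.
#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(id = x$id,
             sire = ifelse(is.na(x$sire), NA_character_, x$id[x$sire]),
             dam = ifelse(is.na(x$dam), NA_character_, x$id[x$dam]),
             stringsAsFactors = FALSE)
}

#' Read / write a pedigree as CSV
#'
#' Plain CSV with columns `id,sire,dam`; empty parent fields denote founders.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [pedigree]; `write_pedigree()` returns
#'   `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a pedigree.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Additive (numerator) relationship matrix
#'
#' Computes Wright's numerator relationship matrix A by the tabular method:
#' founders are taken as unrelated and non-inbred, and for individual j with
#' parents s and d, `A[i, j] = 0.5 * (A[i, s] + A[i, d])` for i preceding j,
#' with `A[j, j] = 1 + 0.5 * A[s, d]`. Entries are expected additive
#' relatedness: 0.5 between full sibs and between parent and offspring,
#' 0.25 between half sibs.
#'
#' @param ped a [pedigree].
#' @return a symmetric positive-semidefinite matrix with dimnames equal to
#'   the pedigree ids.
#' @export
additive_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- ped$sire[j]
    d <- ped$dam[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[i, s]
      if (!is.na(d)) row <- row + 0.5 * A[i, d]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inverse of the additive relationship matrix
#'
#' Uses Henderson's rules, which build the sparse inverse directly for
#' non-inbred pedigrees without forming A. If inbreeding is detected (some
#' individual's parents are related), the function falls back to dense
#' inversion of the tabular A with a warning.
#'
#' @param ped a [pedigree].
#' @return matrix inverse of [additive_relationship_matrix()] (dense).
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ## Inbreeding check: an individual is inbred iff its parents are related.
  A <- additive_relationship_matrix(ped)
  if (any(abs(diag(A) - 1) > 1e-12)) {
    warning("inbred pedigree detected; using dense inversion of A")
    Ai <- solve(A)
    dimnames(Ai) <- dimnames(A)
    return(Ai)
  }
  henderson_a_inverse(ped)
}

## Henderson's rules; assumes a non-inbred pedigree.
henderson_a_inverse <- function(ped) {
  n <- length(ped$id)
  Ai <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- ped$sire[j]
    d <- ped$dam[j]
    np <- sum(!is.na(s), !is.na(d))
    alpha <- c(1, 4 / 3, 2)[np + 1L]  # mendelian-sampling precision
    Ai[j, j] <- Ai[j, j] + alpha
    for (p in c(s, d)[!is.na(c(s, d))]) {
      Ai[j, p] <- Ai[j, p] - alpha / 2
      Ai[p, j] <- Ai[p, j] - alpha / 2
    }
    par <- c(s, d)[!is.na(c(s, d))]
    for (p1 in par) for (p2 in par) Ai[p1, p2] <- Ai[p1, p2] + alpha / 4
  }
  Ai
}

#' Monte-Carlo gene-drop estimate of the relationship matrix
#'
#' Assigns two unique alleles to every founder, transmits one allele per
#' parent at random down the pedigree, and estimates additive relatedness
#' as twice the coefficient of coancestry (the probability that alleles
#' drawn at random from two individuals are identical by descent). Serves
#' as an independent simulation oracle for
#' [additive_relationship_matrix()].
#'
#' @param ped a [pedigree].
#' @param n_reps number of independent gene drops (>= 1).
#' @param seed integer seed.
#' @return matrix estimate of A; standard error of each entry is
#'   O(1/sqrt(n_reps)).
#' @export
gene_drop_kinship <- function(ped, n_reps = 10000, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), n_reps >= 1)
  set.seed(seed)
  n <- length(ped$id)
  ## allele matrices: n x n_reps, integer allele labels
  pat <- matrix(0L, n, n_reps)
  mat <- matrix(0L, n, n_reps)
  next_allele <- 1L
  for (j in seq_len(n)) {
    s <- ped$sire[j]
    d <- ped$dam[j]
    if (is.na(s)) {
      pat[j, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- rbinom(n_reps, 1L, 0.5) == 1L
      pat[j, ] <- ifelse(pick, pat[s, ], mat[s, ])
    }
    if (is.na(d)) {
      mat[j, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- rbinom(n_reps, 1L, 0.5) == 1L
      mat[j, ] <- ifelse(pick, pat[d, ], mat[d, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ## 2 * kinship = mean over replicate drops of the IBD indicator sum / 2
      ibd <- (pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
        (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])
      A[i, j] <- A[j, i] <- mean(ibd) / 2
    }
  }
  A
}
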