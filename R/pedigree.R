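#' Construct a pedigree object
#'
#' A pedigree is a table of animals with sire and dam identifiers. Unknown
#' parents are encoded as `NA` (or `"0"` in files). Animals are reordered
#' so that every parent precedes its offspring; a cycle (an animal that is
#' its own ancestor) is an error.
#'
#' @param animal character or integer vector of animal identifiers (unique).
#' @param sire,dam parent identifiers, `NA` or `"0"` when unknown.
#' @param sex optional vector (`"M"`/`"F"`); when missing, sex is inferred
#'   where possible (sires male, dams female) and left `NA` otherwise.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `animal`, `sire`, `dam`, `sex`, ordered parents-first, plus integer
#'   index columns `sire_idx`/`dam_idx` (0 = unknown).
#' @examples
#' ped <- new_pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' @export
new_pedigree <- function(animal, sire, dam, sex = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[sire %in% c("0", "")] <- NA
  dam[dam %in% c("0", "")] <- NA
  if (anyDuplicated(animal)) {
    stop("duplicated animal identifiers: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  n <- length(animal)
  stopifnot(length(sire) == n, length(dam) == n)
  known <- function(p) !is.na(p) & !(p %in% animal)
  if (any(known(sire)) || any(known(dam))) {
    stop("parents not listed as animals: ",
         paste(unique(c(sire[known(sire)], dam[known(dam)])), collapse = ", "))
  }
  if (is.null(sex)) {
    sex <- rep(NA_character_, n)
  } else {
    sex <- as.character(sex)
  }
  sex[animal %in% sire] <- "M"
  sex[animal %in% dam] <- "F"
  both <- intersect(sire[!is.na(sire)], dam[!is.na(dam)])
  if (length(both)) {
    stop("animals appear as both sire and dam: ", paste(both, collapse = ", "))
  }

  ord <- pedigree_toposort(animal, sire, dam)
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]; sex <- sex[ord]
  idx <- function(p) {
    i <- match(p, animal)
    i[is.na(i)] <- 0L
    i
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam, sex = sex,
                    sire_idx = idx(sire), dam_idx = idx(dam),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort on the parent -> offspring graph.
pedigree_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal); di <- match(dam, animal)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

#' Read / write pedigree files
#'
#' Three-column CSV dialect `animal,sire,dam` with `0` for unknown parents.
#'
#' @param path file path.
#' @param ped a [new_pedigree()] object.
#' @return `read_pedigree` returns a `pedigree`; `write_pedigree` returns
#'   `path` invisibly.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  new_pedigree(d[[1L]], d[[2L]], d[[3L]],
               sex = if (ncol(d) >= 4L) d[[4L]] else NULL)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inbreeding coefficients
#'
#' Computes Wright's inbreeding coefficient F for every animal by the
#' Meuwissen--Luo algorithm (ancestor tracing on the Cholesky rows of the
#' numerator relationship matrix), without forming the full matrix.
#'
#' @param ped a [new_pedigree()] object.
#' @return named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  FF <- numeric(n)
  Dv <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) FF[s[i]] else -1
    fd <- if (d[i] > 0L) FF[d[i]] else -1
    # Mendelian sampling variance; unknown parent contributes F = -1 so that
    # founders get D = 1, single-known-parent animals D = 0.75 - F_known/4.
    Dv[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L && d[i] == 0L) {
      FF[i] <- 0
      next
    }
    # accumulate a_ii = sum_j L_ij^2 D_j by tracing ancestors of i
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * Dv[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    FF[i] <- aii - 1
  }
  names(FF) <- ped$animal
  FF
}

#' Numerator relationship matrix (A)
#'
#' Dense A by the tabular recursion
#' \eqn{a_{ij} = \tfrac12(a_{j,s(i)} + a_{j,d(i)})}, with diagonal
#' \eqn{1 + F_i}. Intended for pedigrees up to a few thousand animals; the
#' mixed-model machinery uses the sparse inverse from [ainverse()] instead.
#'
#' @param ped a [new_pedigree()] object.
#' @return dense symmetric matrix with animal dimnames.
#' @export
additive_relationship <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                    (if (d[i] > 0L) A[j, d[i]] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles \eqn{A^{-1}} directly by Henderson's rules accounting for
#' inbreeding: for each animal the inverse Mendelian-sampling variance
#' \eqn{\alpha_i = 1/d_i} is scattered over the animal/sire/dam equations.
#'
#' @param ped a [new_pedigree()] object.
#' @return sparse symmetric `Matrix::dsCMatrix` with animal dimnames.
#' @export
ainverse <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  FF <- inbreeding(ped)
  Fs <- ifelse(s > 0L, FF[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, FF[pmax(d, 1L)], -1)
  Dv <- 0.5 - 0.25 * (Fs + Fd)
  alpha <- 1 / Dv
  ti <- list(); tj <- list(); tx <- list(); k <- 1L
  add <- function(i, j, x) {
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x; k <<- k + 1L
  }
  add(seq_len(n), seq_len(n), alpha)
  bs <- which(s > 0L)
  bd <- which(d > 0L)
  add(bs, s[bs], -0.5 * alpha[bs])
  add(s[bs], bs, -0.5 * alpha[bs])
  add(bd, d[bd], -0.5 * alpha[bd])
  add(d[bd], bd, -0.5 * alpha[bd])
  add(s[bs], s[bs], 0.25 * alpha[bs])
  add(d[bd], d[bd], 0.25 * alpha[bd])
  both <- which(s > 0L & d > 0L)
  add(s[both], d[both], 0.25 * alpha[both])
  add(d[both], s[both], 0.25 * alpha[both])
  Ai <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(n, n),
    dimnames = list(ped$animal, ped$animal)
  )
  Ai <- Matrix::forceSymmetric(Ai, uplo = "U")
  attr(Ai, "logdetA") <- sum(log(Dv))
  Ai
}
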