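#' Build a pedigree table
#'
#' Assembles a validated three-column pedigree (animal, sire, dam). Unknown
#' parents may be coded \code{NA}, \code{"0"} or \code{""}. Parents that are
#' referenced but have no record of their own are appended as founders, so the
#' returned table is always closed under the parent relation.
#'
#' @param animal character vector of animal ids (unique).
#' @param sire,dam character vectors of parent ids, same length as
#'   \code{animal}; unknown coded \code{NA}, \code{"0"} or \code{""}.
#' @return A \code{data.frame} of class \code{ped_table} with character columns
#'   \code{animal}, \code{sire}, \code{dam} (\code{NA} = unknown parent).
#' @seealso [read_pedigree()], [compute_fped()]
#' @export
ped_table <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- .clean_parent(sire)
  dam <- .clean_parent(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("animal listed as its own parent")
  extra <- setdiff(c(sire, dam), c(animal, NA))
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  class(ped) <- c("ped_table", "data.frame")
  # validates acyclicity as a side effect
  topological_sort(ped)
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

#' Topologically sort a pedigree
#'
#' Reorders records so every parent precedes its offspring (Kahn's algorithm).
#' The order is stable: among animals whose parents are already placed, input
#' order is preserved, so an already-sorted pedigree is returned unchanged.
#'
#' @param ped a [ped_table()] (or plain data.frame with animal/sire/dam).
#' @return The pedigree reordered, same class.
#' @export
topological_sort <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  # stable Kahn: scan candidates in input order
  placed <- logical(n)
  order_out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    ready <- sort(ready)
    i <- ready[1L]
    ready <- ready[-1L]
    placed[i] <- TRUE
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "))
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds Henderson's additive (numerator) relationship matrix A recursively:
#' \code{a_ii = 1 + 0.5 * a[sire, dam]} (a missing parent contributes 0) and
#' \code{a_ij = 0.5 * (a[j, sire(i)] + a[j, dam(i)])} for j processed before i.
#'
#' @param ped a pedigree; sorted internally.
#' @return Symmetric matrix with dimnames = animal ids; \code{diag(A) - 1}
#'   are the inbreeding coefficients.
#' @export
nrm_tabular <- function(ped) {
  ped <- topological_sort(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (is.na(s)) 0 else A[s, j]
      rd <- if (is.na(d)) 0 else A[d, j]
      A[i, j] <- 0.5 * (rs + rd)
      A[j, i] <- A[i, j]
    }
  }
  A
}

#' Pedigree inbreeding coefficients (FPED)
#'
#' Computes F for every animal from the numerator relationship matrix
#' (tabular method), \code{F_i = a_ii - 1}. For pedigrees larger than
#' \code{max_tabular} animals the full A matrix is not materialized; the
#' diagonal is obtained with the Meuwissen--Luo recursion, which yields
#' identical values (to numerical precision) in O(n * ancestors) time and
#' O(n) memory.
#'
#' @param ped a pedigree table.
#' @param max_tabular largest pedigree for which the dense A matrix is built;
#'   default 2000.
#' @return \code{data.frame} with columns \code{animal}, \code{f_ped}, in the
#'   input row order of \code{ped}.
#' @export
compute_fped <- function(ped, max_tabular = 2000) {
  sorted <- topological_sort(ped)
  f <- if (nrow(sorted) <= max_tabular) {
    diag(nrm_tabular(sorted)) - 1
  } else {
    .fped_meuwissen_luo(sorted)
  }
  stopifnot(all(f >= 0), all(f < 1))
  out <- data.frame(animal = sorted$animal, f_ped = unname(f),
                    stringsAsFactors = FALSE)
  out <- out[match(ped$animal, out$animal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Meuwissen & Luo (1992): inbreeding without the dense A matrix.
# For animal i, a_ii = sum_j L_ij^2 * D_j over ancestors j, where
# L_ij = 0.5 (L_{sire(i),j} + L_{dam(i),j}), L_ii = 1 and D_j is the
# within-family (Mendelian sampling) variance given j's parents' F.
.fped_meuwissen_luo <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    D[i] <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (F[s] + F[d])
    else if (!is.na(s)) 0.75 - 0.25 * F[s]
    else if (!is.na(d)) 0.75 - 0.25 * F[d]
    else 1
    if (is.na(s) || is.na(d)) { F[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * L[j]
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  names(F) <- id
  F
}

#' Wright's path-counting inbreeding coefficient
#'
#' Independent reference computation of F for a single animal: the sum over
#' common ancestors Z of the sire and dam, and over pairs of ancestral paths
#' that share no animal other than Z, of \code{(1/2)^(n_s + n_d + 1) *
#' (1 + F_Z)}, with the common ancestor's own F obtained recursively by the
#' same rule. Exponential in pedigree depth; intended as a test oracle for
#' small pedigrees (tens of animals), not for production use.
#'
#' @param ped a pedigree table.
#' @param animal_id id of the animal whose F is wanted.
#' @return a single numeric value in [0, 1).
#' @export
wright_path_fped <- function(ped, animal_id) {
  id <- ped$animal
  i <- match(animal_id, id)
  if (is.na(i)) stop("unknown animal: ", animal_id)
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  memo <- new.env(parent = emptyenv())

  paths_up <- function(x) {
    # all ancestral paths starting at x (including the trivial path c(x))
    out <- list(x)
    for (p in c(si[x], di[x])) {
      if (!is.na(p)) {
        for (pp in paths_up(p)) out <- c(out, list(c(x, pp)))
      }
    }
    out
  }

  f_of <- function(x) {
    key <- as.character(x)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- si[x]; d <- di[x]
    if (is.na(s) || is.na(d)) { memo[[key]] <- 0; return(0) }
    ps <- paths_up(s)
    pd <- paths_up(d)
    total <- 0
    for (a in ps) {
      za <- a[length(a)]
      for (b in pd) {
        zb <- b[length(b)]
        if (za != zb) next
        shared <- intersect(a, b)
        if (length(shared) != 1L) next
        ns <- length(a) - 1L
        nd <- length(b) - 1L
        total <- total + 0.5^(ns + nd + 1) * (1 + f_of(za))
      }
    }
    memo[[key]] <- total
    total
  }
  f_of(i)
}

#' Write a pedigree-F table to CSV
#'
#' @param fped data.frame from [compute_fped()].
#' @param path output file.
#' @export
write_fped <- function(fped, path) {
  utils::write.csv(fped, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
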