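#' Construct a pedigree object
#'
#' A pedigree is a table of individuals with optional father/mother links.
#' Founders have both parents missing; every non-founder must have both
#' parents present in the pedigree (both-or-neither rule). The graph must be
#' acyclic so that a topological order (parents before offspring) exists.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother character vectors of parent identifiers; `NA` for
#'   missing (founder).
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#'   Sex is validated against parental roles but not used in relatedness
#'   computations.
#' @param auto_add_parents if `TRUE` (default), a parent referenced but not
#'   listed as a row is added as a founder with a warning.
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `father`, `mother`, `sex`, plus attributes `founders` (character
#'   vector) and `topo_order` (integer permutation, parents first).
#' @seealso [parse_pedigree()], [kinship_matrix()], [dominance_matrix()]
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", auto_add_parents = TRUE) {
  id <- as.character(id)
  n <- length(id)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  sex <- rep_len(as.character(sex), n)
  father[!is.na(father) & father %in% c("", "0")] <- NA_character_
  mother[!is.na(mother) & mother %in% c("", "0")] <- NA_character_
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent)) {
    stop("individual(s) with exactly one parent recorded (both-or-neither rule): ",
         paste(id[one_parent], collapse = ", "))
  }
  referenced <- setdiff(stats::na.omit(unique(c(father, mother))), id)
  if (length(referenced)) {
    if (!auto_add_parents) {
      stop("parent id(s) not present as rows: ",
           paste(referenced, collapse = ", "))
    }
    warning("parent(s) not listed as rows added as founders: ",
            paste(referenced, collapse = ", "))
    add_sex <- ifelse(referenced %in% father, "male",
                      ifelse(referenced %in% mother, "female", "unknown"))
    id <- c(id, referenced)
    father <- c(father, rep(NA_character_, length(referenced)))
    mother <- c(mother, rep(NA_character_, length(referenced)))
    sex <- c(sex, add_sex)
    n <- length(id)
  }
  sex <- match.arg(sex, c("male", "female", "unknown"), several.ok = TRUE)
  ## role/sex consistency
  bad_f <- !is.na(father) & sex[match(father, id)] == "female"
  bad_m <- !is.na(mother) & sex[match(mother, id)] == "male"
  if (any(bad_f) || any(bad_m)) {
    stop("sex inconsistent with parental role for: ",
         paste(unique(c(father[bad_f], mother[bad_m])), collapse = ", "))
  }
  ped <- data.frame(id = id, father = father, mother = mother, sex = sex,
                    stringsAsFactors = FALSE)
  ord <- ped_topological_order(ped)  # errors on cycles
  structure(ped,
            founders = id[is.na(father) & is.na(mother)],
            topo_order = ord,
            class = c("pedigree", "data.frame"))
}

## Kahn's algorithm; errors naming a cycle member if no topological order.
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) {
        if (p == i) stop("pedigree cycle: ", ped$id[i], " is its own parent")
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle detected involving: ",
         paste(ped$id[indeg > 0], collapse = ", "))
  }
  ord
}

#' Parse a PED-style pedigree file
#'
#' Reads a whitespace- or tab-separated file with columns
#' `id father mother sex` (an optional leading family column is tolerated and
#' ignored). Missing parents are encoded as `"0"` or the empty string; sex as
#' `1`/`M`/`male`, `2`/`F`/`female`, anything else unknown. Parents referenced
#' but absent as rows are auto-added as founders with a warning.
#'
#' @param path path to the pedigree file.
#' @param family_column `"auto"` (default: a 5-column file is assumed to carry
#'   a leading family column), `TRUE` or `FALSE`.
#' @param header whether the file has a header row (default `FALSE`; a header
#'   starting with a non-numeric sex column is auto-detected).
#' @return A [pedigree] object.
#' @export
parse_pedigree <- function(path, family_column = "auto", header = FALSE) {
  raw <- utils::read.table(path, header = header, colClasses = "character",
                           blank.lines.skip = TRUE, fill = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("pedigree file must have >= 4 columns")
  drop_fam <- isTRUE(family_column) ||
    (identical(family_column, "auto") && ncol(raw) >= 5)
  if (drop_fam) raw <- raw[, -1, drop = FALSE]
  sex_raw <- tolower(raw[[4]])
  sex <- ifelse(sex_raw %in% c("1", "m", "male"), "male",
                ifelse(sex_raw %in% c("2", "f", "female"), "female", "unknown"))
  pedigree(id = raw[[1]], father = raw[[2]], mother = raw[[3]], sex = sex)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders)\n",
              nrow(x), length(attr(x, "founders"))))
  invisible(x)
}

#' Founder identifiers of a pedigree
#' @param ped a [pedigree] object.
#' @return Character vector of founder ids.
#' @export
founders <- function(ped) attr(ped, "founders")

## Full kinship matrix over all pedigree members, tabular (Emik-Terrill)
## method in topological order. phi(i,i) = (1 + phi(f,m))/2, founders 1/2.
ped_full_kinship <- function(ped) {
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  done <- integer(0)
  for (i in ord) {
    f <- fi[i]; m <- mi[i]
    if (is.na(f)) {                     # founder
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      if (length(done)) {
        v <- 0.5 * (phi[f, done] + phi[m, done])
        phi[i, done] <- v
        phi[done, i] <- v
      }
    }
    done <- c(done, i)
  }
  phi
}

check_subjects <- function(ped, subjects) {
  if (is.null(subjects)) return(ped$id)
  subjects <- as.character(subjects)
  missing <- setdiff(subjects, ped$id)
  if (length(missing)) {
    stop("subject(s) not in pedigree: ", paste(missing, collapse = ", "))
  }
  subjects
}

#' Pedigree kinship matrix
#'
#' The kinship coefficient phi(i,j) is the probability that an allele drawn
#' at random from i and one from j are identical by descent given the
#' pedigree. Computed recursively in topological order:
#' phi(i,i) = (1 + phi(f_i, m_i))/2, phi(i,j) = (phi(f_i,j) + phi(m_i,j))/2,
#' with phi = 1/2 on the diagonal and 0 off-diagonal for founders.
#'
#' @param ped a [pedigree] object.
#' @param subjects ordered ids to restrict the matrix to (default: all).
#' @return A [relatedness_matrix] of kind `"kinship"`.
#' @export
kinship_matrix <- function(ped, subjects = NULL) {
  subjects <- check_subjects(ped, subjects)
  phi <- ped_full_kinship(ped)[subjects, subjects, drop = FALSE]
  relatedness_matrix(phi, kind = "kinship")
}

#' Additive (numerator) relationship matrix A = 2 * kinship
#'
#' Scaled so that the variance component attached to it is the additive
#' genetic variance and its share of phenotypic variance is the narrow-sense
#' heritability.
#'
#' @inheritParams kinship_matrix
#' @return A [relatedness_matrix] of kind `"additive"`.
#' @export
additive_matrix <- function(ped, subjects = NULL) {
  k <- kinship_matrix(ped, subjects)
  relatedness_matrix(2 * unclass_matrix(k), kind = "additive")
}

#' Pedigree dominance (fraternity) matrix
#'
#' d(i,j) is the probability that i and j share both alleles (the genotype)
#' identical by descent:
#' `d(i,j) = phi(f_i,f_j) phi(m_i,m_j) + phi(f_i,m_j) phi(m_i,f_j)` for
#' distinct individuals (zero whenever either is a founder with unknown
#' parents), and `d(i,i) = 1`. The pair formula is exact for non-inbred
#' pairs; it is applied to all pairs, and a warning lists inbred individuals
#' when the pedigree contains any (standard fraternity-coefficient practice;
#' condensed-identity corrections are out of scope).
#'
#' @inheritParams kinship_matrix
#' @return A [relatedness_matrix] of kind `"dominance"`.
#' @export
dominance_matrix <- function(ped, subjects = NULL) {
  subjects <- check_subjects(ped, subjects)
  phi <- ped_full_kinship(ped)
  n <- nrow(ped)
  ## extended index: n+1 is a virtual unknown parent, unrelated to everyone
  phie <- rbind(cbind(phi, 0), 0)
  fi <- match(ped$father, ped$id); fi[is.na(fi)] <- n + 1L
  mi <- match(ped$mother, ped$id); mi[is.na(mi)] <- n + 1L
  D <- phie[fi, fi, drop = FALSE] * phie[mi, mi, drop = FALSE] +
    phie[fi, mi, drop = FALSE] * phie[mi, fi, drop = FALSE]
  diag(D) <- 1
  dimnames(D) <- list(ped$id, ped$id)
  inbred <- ped$id[diag(phi) > 0.5 + 1e-12]
  if (length(inbred)) {
    warning("pair dominance formula is approximate for inbred individuals: ",
            paste(inbred, collapse = ", "))
  }
  relatedness_matrix(D[subjects, subjects, drop = FALSE], kind = "dominance")
}
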