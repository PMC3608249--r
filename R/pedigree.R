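#' Read a PED-like pedigree file
#'
#' Parses a whitespace- or comma-delimited pedigree file with columns
#' family id, individual id, father id, mother id, sex.  Missing parents are
#' coded \code{"0"} or left empty.  Sex may be coded \code{1}/\code{2},
#' \code{M}/\code{F} or \code{male}/\code{female}.  A header row is detected
#' and skipped when the fifth field of the first line is not a recognizable
#' sex code.
#'
#' @param path path to the pedigree file.
#' @param dialect input dialect; only \code{"ped_like"} is supported.
#' @return A \code{pedigree} object: a \code{data.frame} with character
#'   columns \code{fam}, \code{id}, \code{father}, \code{mother} (parent ids
#'   \code{NA} for founders) and \code{sex} (\code{"male"}/\code{"female"}),
#'   in file order.
#' @export
read_pedigree <- function(path, dialect = c("ped_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pedigree file is empty: ", path)
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  split1 <- function(x) {
    if (sep_comma) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    else strsplit(trimws(x), "[ \t]+")[[1]]
  }
  fields <- lapply(lines, split1)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 5L)) {
    stop("pedigree line(s) with fewer than 5 fields: line ",
         paste(which(nf < 5L)[1]))
  }
  # drop header if sex field is not interpretable
  if (is.na(.parse_sex(fields[[1]][5], quiet = TRUE))) fields <- fields[-1]
  if (length(fields) == 0L) stop("pedigree file has no data rows: ", path)
  m <- do.call(rbind, lapply(fields, function(f) f[1:5]))
  ped <- data.frame(fam = m[, 1], id = m[, 2], father = m[, 3],
                    mother = m[, 4], sex = NA_character_,
                    stringsAsFactors = FALSE)
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  ped$sex <- vapply(m[, 5], .parse_sex, character(1), quiet = FALSE,
                    USE.NAMES = FALSE)
  as_pedigree(ped)
}

.parse_sex <- function(x, quiet = FALSE) {
  s <- c("1" = "male", "2" = "female", "m" = "male", "f" = "female",
         "male" = "male", "female" = "female")
  out <- unname(s[tolower(x)])
  if (is.na(out) && !quiet) stop("unrecognized sex code: '", x, "'")
  out
}

#' Construct and validate a pedigree
#'
#' Validates parent references (both present or both absent, same family,
#' existing ids, no individual its own ancestor) and attaches the
#' \code{pedigree} class.
#'
#' @param df data.frame with columns \code{fam}, \code{id}, \code{father},
#'   \code{mother}, \code{sex}; parent ids \code{NA} when unknown.
#' @return the validated \code{pedigree} (row order preserved).
#' @export
as_pedigree <- function(df) {
  req <- c("fam", "id", "father", "mother", "sex")
  if (!all(req %in% names(df))) {
    stop("pedigree needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cl in req) df[[cl]] <- as.character(df[[cl]])
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate individual id(s): ",
                        paste(unique(dup), collapse = ", "))
  half <- xor(is.na(df$father), is.na(df$mother))
  if (any(half)) {
    stop("individual(s) with exactly one known parent: ",
         paste(df$id[half], collapse = ", "))
  }
  idx <- match(df$father, df$id)
  bad <- !is.na(df$father) & is.na(idx)
  if (any(bad)) stop("dangling father reference for: ",
                     paste(df$id[bad], collapse = ", "))
  jdx <- match(df$mother, df$id)
  bad <- !is.na(df$mother) & is.na(jdx)
  if (any(bad)) stop("dangling mother reference for: ",
                     paste(df$id[bad], collapse = ", "))
  for (p in c("father", "mother")) {
    k <- match(df[[p]], df$id)
    off <- !is.na(k) & df$fam[k] != df$fam
    if (any(off)) stop(p, " in a different family for: ",
                       paste(df$id[off], collapse = ", "))
  }
  .topo_order(df)  # errors on cycles / self-ancestry
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort over parent -> child edges; errors listing a cycle.
.topo_order <- function(df) {
  n <- nrow(df)
  fi <- match(df$father, df$id)
  mi <- match(df$mother, df$id)
  indeg <- ifelse(is.na(fi), 0L, 1L) + ifelse(is.na(mi), 0L, 1L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    stop("pedigree contains a parent cycle involving: ",
         paste(df$id[cyc], collapse = " -> "))
  }
  ord
}

#' Founders of a pedigree
#' @param ped a \code{pedigree}.
#' @return character vector of founder ids (both parents unknown).
#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Pairwise kinship matrix from a pedigree
#'
#' Computes the kinship coefficient phi for every pair by the standard
#' recursive (tabular) method in topological order:
#' phi(i,i) = 0.5 * (1 + phi(father_i, mother_i)),
#' phi(i,j) = 0.5 * (phi(father_i, j) + phi(mother_i, j)) for i a non-founder
#' processed after j, and phi = 0 between founders.  The additive genetic
#' covariance kernel used by the polygenic model is 2 * phi.
#'
#' @param ped a \code{pedigree}.
#' @return symmetric numeric matrix (dimnames = individual ids, in pedigree
#'   order) of kinship coefficients; diagonal 0.5 for non-inbred individuals.
#' @export
kinship_matrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  n <- nrow(ped)
  ord <- .topo_order(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  done <- logical(n)
  for (i in ord) {
    f <- fi[i]; m <- mi[i]
    if (is.na(f)) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      prev <- which(done)
      prev <- prev[prev != i]
      if (length(prev)) {
        v <- 0.5 * (phi[f, prev] + phi[m, prev])
        phi[i, prev] <- v
        phi[prev, i] <- v
      }
    }
    done[i] <- TRUE
  }
  phi
}

#' Eigen-decomposition of the additive relationship matrix
#'
#' Decomposes K = 2 * phi once so repeated polygenic fits on the same
#' pedigree can reuse the rotation.
#'
#' @param phi kinship matrix (as from [kinship_matrix()]).
#' @return list with \code{values}, \code{vectors}, \code{ids}; class
#'   \code{kinship_eigen}.
#' @export
kinship_eigen <- function(phi) {
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  e <- eigen(2 * phi, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stop("2*phi is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  }
  e$values <- pmax(e$values, 0)
  structure(list(values = e$values, vectors = e$vectors,
                 ids = rownames(phi)), class = "kinship_eigen")
}

#' Write a kinship matrix to CSV
#'
#' @param phi kinship matrix.
#' @param path output file.
#' @param format \code{"long"} for 3-column (id1,id2,phi) upper-triangle
#'   output including diagonal; \code{"dense"} for a square CSV with id
#'   header row and column.
#' @return invisibly, the path.
#' @export
write_kinship <- function(phi, path, format = c("long", "dense")) {
  format <- match.arg(format)
  ids <- rownames(phi)
  if (format == "long") {
    ut <- which(upper.tri(phi, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                     phi = phi[ut])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(id = ids, phi, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
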