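#' Construct and validate a pedigree
#'
#' Builds a validated, topologically ordered pedigree from a data frame of
#' animal records. Each animal appears once; parents must themselves appear
#' as animals (or be unknown, coded `"0"`, `""` or `NA`). The returned tibble
#' is ordered so every parent precedes its offspring; ties are broken by the
#' original row order so the ordering is reproducible.
#'
#' @param data A data frame with one row per animal.
#' @param animal,sire,dam Column names holding the animal and parent ids.
#' @param sex,generation,line Optional column names; missing columns are
#'   filled with `"unknown"`.
#' @param auto_add_founders If `TRUE`, parent ids that never appear as
#'   animals are added as founder records instead of raising an error.
#' @return A tibble of class `f2qg_ped` with columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent), `sex`, `generation`, `line` and `file_order`
#'   (the original row position), topologically ordered.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("kid", "pa", "ma"),
#'   sire = c("pa", "0", "0"),
#'   dam = c("ma", "0", "0")
#' ))
#' ped$animal # parents reordered before offspring
#' @export
as_pedigree <- function(data, animal = "animal", sire = "sire", dam = "dam",
                        sex = "sex", generation = "generation", line = "line",
                        auto_add_founders = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c(animal, sire, dam)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("pedigree columns not found: ", paste(miss, collapse = ", "))
  }
  norm_id <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  opt_col <- function(col, default) {
    if (!is.null(col) && col %in% names(data)) as.character(data[[col]]) else rep(default, nrow(data))
  }
  ped <- tibble::tibble(
    animal = trimws(as.character(data[[animal]])),
    sire = norm_id(data[[sire]]),
    dam = norm_id(data[[dam]]),
    sex = opt_col(sex, "unknown"),
    generation = opt_col(generation, "unknown"),
    line = opt_col(line, "unknown"),
    file_order = seq_len(nrow(data))
  )
  if (anyNA(ped$animal) || any(ped$animal == "")) {
    stop("missing animal id in pedigree")
  }
  dup <- ped$animal[duplicated(ped$animal)]
  if (length(dup) > 0) {
    stop("duplicate animal id(s): ", paste(unique(dup), collapse = ", "))
  }
  self <- ped$animal == ped$sire | ped$animal == ped$dam
  if (any(self, na.rm = TRUE)) {
    stop("pedigree cycle: animal ", ped$animal[which(self)[1]],
         " is its own parent")
  }
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  orphans <- setdiff(parents, ped$animal)
  if (length(orphans) > 0) {
    if (!auto_add_founders) {
      stop("parent id(s) never defined as animals: ",
           paste(orphans, collapse = ", "),
           " (set auto_add_founders = TRUE to add them)")
    }
    ped <- dplyr::bind_rows(
      tibble::tibble(animal = orphans, sire = NA_character_,
                     dam = NA_character_, sex = "unknown",
                     generation = "unknown", line = "unknown",
                     file_order = 0L),
      ped
    )
  }
  ped <- ped[topo_order(ped$animal, ped$sire, ped$dam), , drop = FALSE]
  class(ped) <- c("f2qg_ped", class(tibble::tibble()))
  ped
}

#' Read a pedigree file
#'
#' Reads a CSV or TSV pedigree (delimiter chosen from the file extension,
#' `.tsv`/`.txt` = tab, otherwise comma), maps columns through `dialect`, and
#' validates/orders it with [as_pedigree()]. Unknown parents may be coded
#' `0` or left empty.
#'
#' @param path Path to the file; a header row is required.
#' @param dialect Named character vector mapping the canonical fields
#'   (`animal`, `sire`, `dam`, optionally `sex`, `generation`, `line`) to the
#'   column names used in the file.
#' @param auto_add_founders Passed to [as_pedigree()].
#' @return A validated `f2qg_ped` tibble.
#' @export
read_pedigree <- function(path,
                          dialect = c(animal = "animal", sire = "sire", dam = "dam"),
                          auto_add_founders = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  get <- function(field, default) if (field %in% names(dialect)) unname(dialect[[field]]) else default
  as_pedigree(raw,
              animal = get("animal", "animal"),
              sire = get("sire", "sire"),
              dam = get("dam", "dam"),
              sex = get("sex", "sex"),
              generation = get("generation", "generation"),
              line = get("line", "line"),
              auto_add_founders = auto_add_founders)
}

#' Write a pedigree in canonical column order
#'
#' @param ped An `f2qg_ped` tibble.
#' @param path Output path; `.tsv` extension writes tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[, c("animal", "sire", "dam", "sex", "generation", "line")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

# Stable topological order (Kahn); ties resolved by input position.
# Errors with one member of a cycle if the pedigree is not acyclic.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- match(animal, animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L) # already in input order
  while (length(ready) > 0) {
    i <- ready[1]
    ready <- ready[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) {
        ready <- sort(c(ready, k))
      }
    }
  }
  if (length(out) < n) {
    stop("pedigree cycle involving animal ", animal[setdiff(seq_len(n), out)[1]])
  }
  out
}

ped_indices <- function(ped) {
  list(sire = match(ped$sire, ped$animal), dam = match(ped$dam, ped$animal))
}

#' Additive (numerator) relationship matrix
#'
#' Computes the dense additive relationship matrix A by the tabular
#' (recursive) method: for animal i with parents s and d,
#' `a_ij = 0.5 (a_js + a_jd)` for earlier j and `a_ii = 1 + 0.5 a_sd`,
#' an unknown parent contributing zero. Diagonal entries therefore equal
#' `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped An `f2qg_ped` pedigree (parents before offspring).
#' @param max_animals Guard against accidental huge dense matrices.
#' @return A symmetric dense matrix with `ped$animal` dimnames.
#' @export
additive_relationship <- function(ped, max_animals = 5000L) {
  n <- nrow(ped)
  if (n > max_animals) {
    stop("refusing dense A for ", n, " animals (> max_animals = ",
         max_animals, ")")
  }
  ix <- ped_indices(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ix$sire[i]
    d <- ix$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) + (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0)
  }
  A
}

#' Inbreeding coefficients
#'
#' `F_i = 0.5 a(sire_i, dam_i)`, the additive relationship between the
#' parents halved; founders and animals with an unknown parent get 0 (all
#' founders are assumed unrelated and non-inbred).
#'
#' @param ped An `f2qg_ped` pedigree.
#' @param method `"tabular"` takes F off the dense A diagonal (exact,
#'   default); `"meuwissen-luo"` uses an indirect recursive-kinship
#'   computation that never forms dense A, in the spirit of Meuwissen & Luo's
#'   memory-lean inbreeding algorithm.
#' @return A tibble with columns `animal` and `f`.
#' @export
inbreeding_coefficients <- function(ped, method = c("tabular", "meuwissen-luo")) {
  method <- match.arg(method)
  f <- if (method == "tabular") {
    diag(additive_relationship(ped)) - 1
  } else {
    recursive_inbreeding(ped)
  }
  tibble::tibble(animal = ped$animal, f = unname(f))
}

# Inbreeding without dense A: memoized recursive kinship phi(i,j);
# F_i = 2 phi(s_i, d_i); phi(i,i) = 0.5 (1 + F_i).
recursive_inbreeding <- function(ped) {
  ix <- ped_indices(ped)
  si <- ix$sire
  di <- ix$dam
  n <- nrow(ped)
  memo <- new.env(parent = emptyenv(), size = 4L * n)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) return(0.5 * (1 + Fv[i]))
    if (i < j) { tmp <- i; i <- j; j <- tmp } # i is the later animal
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- 0.5 * (phi(si[i], j) + phi(di[i], j))
    memo[[key]] <- val
    val
  }
  Fv <- numeric(n)
  for (i in seq_len(n)) {
    Fv[i] <- if (is.na(si[i]) || is.na(di[i])) 0 else phi(si[i], di[i])
  }
  Fv
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' accounting for inbreeding. Each animal contributes `1/d_i` times the
#' pattern `{1, -1/2, -1/2}` over itself and its known parents, where the
#' Mendelian-sampling variance is `d_i = 0.5 - 0.25 (F_s + F_d)` with both
#' parents known, `0.75 - 0.25 F_p` with one, and 1 with none.
#'
#' @param ped An `f2qg_ped` pedigree.
#' @param method How inbreeding coefficients are obtained; see
#'   [inbreeding_coefficients()]. Both give identical results; the
#'   `"meuwissen-luo"` route avoids the dense A.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with animal
#'   dimnames.
#' @export
a_inverse <- function(ped, method = c("henderson", "meuwissen-luo")) {
  method <- match.arg(method)
  f <- if (method == "henderson") {
    inbreeding_coefficients(ped, "tabular")$f
  } else {
    inbreeding_coefficients(ped, "meuwissen-luo")$f
  }
  ix <- ped_indices(ped)
  n <- nrow(ped)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- ix$sire[i]
    d <- ix$dam[i]
    npar <- sum(!is.na(c(s, d)))
    dd <- if (npar == 2L) {
      0.5 - 0.25 * (f[s] + f[d])
    } else if (npar == 1L) {
      0.75 - 0.25 * f[c(s, d)[!is.na(c(s, d))]]
    } else 1
    if (dd <= 0) stop("internal error: non-positive Mendelian-sampling variance")
    a <- 1 / dd
    add(i, i, a)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -0.5 * a)
        add(p, i, -0.5 * a)
      }
    }
    if (npar == 2L) {
      add(s, s, 0.25 * a)
      add(d, d, 0.25 * a)
      add(s, d, 0.25 * a)
      add(d, s, 0.25 * a)
    } else if (npar == 1L) {
      p <- c(s, d)[!is.na(c(s, d))]
      add(p, p, 0.25 * a)
    }
  }
  keep <- seq_len(k)
  Ainv <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                               dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Relationship matrix bundle
#'
#' Convenience wrapper computing the dense A and its sparse inverse once,
#' for reuse across model fits.
#'
#' @inheritParams additive_relationship
#' @return A list of class `relationship_matrix` with `ids`, `A`, `Ainv`
#'   and the inbreeding coefficients `f`.
#' @export
relationship_matrix <- function(ped, max_animals = 5000L) {
  A <- additive_relationship(ped, max_animals = max_animals)
  structure(
    list(ids = ped$animal, A = A, Ainv = a_inverse(ped), f = diag(A) - 1),
    class = "relationship_matrix"
  )
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> ", length(x$ids), " animals; mean F = ",
      signif(mean(x$f), 3), "\n", sep = "")
  invisible(x)
}

#' Prune a pedigree to a set of animals and their ancestors
#'
#' Returns the sub-pedigree containing `ids` plus every ancestor, reordered
#' topologically. Typical use: restrict the full breeding pedigree to the
#' phenotyped animals before building A (phenotyped F2 plus the F0/F1
#' parents).
#'
#' @param ped An `f2qg_ped` pedigree.
#' @param ids Character vector of animal ids to retain (with ancestors).
#' @return A pruned `f2qg_ped` tibble.
#' @export
prune_to_phenotyped <- function(ped, ids) {
  unknown <- setdiff(ids, ped$animal)
  if (length(unknown) > 0) {
    stop("id(s) not in pedigree: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  ix <- ped_indices(ped)
  keep <- ped$animal %in% ids
  # pedigree is parent-first, so one reverse sweep collects all ancestors
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      for (p in c(ix$sire[i], ix$dam[i])) {
        if (!is.na(p)) keep[p] <- TRUE
      }
    }
  }
  out <- ped[keep, , drop = FALSE]
  class(out) <- c("f2qg_ped", class(tibble::tibble()))
  out
}
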