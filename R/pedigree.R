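#' Read and validate a pedigree file
#'
#' Reads a delimited pedigree file (comma or tab, autodetected), maps unknown
#' parents to the missing sentinel, adds parents that are referenced but never
#' defined as founders (with a warning), and returns the animals in
#' topological order (parents always precede offspring). The input row order
#' is never trusted; ties in the sort are broken by input order so the result
#' is reproducible.
#'
#' @param path Path to a delimited text file with a header and columns
#'   `animal`, `sire`, `dam` and optionally `sex` and `birth_year`. Column
#'   matching is by name prefix (e.g. `animal_id` works). Unknown parents are
#'   coded `"0"`, `""` or `NA`.
#' @param missing_codes Character vector of tokens that denote an unknown
#'   parent.
#' @return An object of class `litter_pedigree`: a list with `ped` (a
#'   `data.frame` with columns `id`, `sire`, `dam`, `sex`, `birth_year`,
#'   and integer parent indices `sire_idx`, `dam_idx`, 0 = unknown) and `n`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("animal,sire,dam", "ram1,0,0", "ewe1,0,0", "lamb1,ram1,ewe1"), f)
#' ped <- read_pedigree(f)
#' ped$ped$id
#' @export
read_pedigree <- function(path, missing_codes = c("0", "", "NA")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "", quote = "\"")
  names(raw) <- tolower(names(raw))
  pick <- function(prefixes) {
    hit <- which(Reduce(`|`, lapply(prefixes, function(p) startsWith(names(raw), p))))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  ia <- pick(c("animal", "id"))
  is <- pick("sire")
  id <- pick("dam")
  if (anyNA(c(ia, is, id)))
    stop("pedigree file must have animal, sire and dam columns (header required)")
  animal <- raw[[ia]]
  sire <- raw[[is]]
  dam <- raw[[id]]
  ix <- pick("sex")
  iy <- pick(c("birth_year", "year", "birth"))
  sex <- if (!is.na(ix)) raw[[ix]] else rep(NA_character_, length(animal))
  byear <- if (!is.na(iy)) suppressWarnings(as.integer(raw[[iy]])) else
    rep(NA_integer_, length(animal))

  if (anyDuplicated(animal))
    stop("duplicated animal rows in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  sire[sire %in% missing_codes | is.na(sire)] <- NA_character_
  dam[dam %in% missing_codes | is.na(dam)] <- NA_character_

  # parents referenced but never defined become founders
  ghosts <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(ghosts) > 0L) {
    warning("parent(s) referenced but never defined, added as founders: ",
            paste(ghosts, collapse = ", "))
    animal <- c(animal, ghosts)
    sire <- c(sire, rep(NA_character_, length(ghosts)))
    dam <- c(dam, rep(NA_character_, length(ghosts)))
    sex <- c(sex, rep(NA_character_, length(ghosts)))
    byear <- c(byear, rep(NA_integer_, length(ghosts)))
  }
  ped <- data.frame(id = animal, sire = sire, dam = dam, sex = sex,
                    birth_year = byear, stringsAsFactors = FALSE)
  new_litter_pedigree(ped)
}

#' Construct a pedigree object from a data frame
#'
#' Topologically sorts the rows (parents before offspring; ties broken by
#' input order) and errors on cycles. Used by [read_pedigree()] and the
#' simulator.
#'
#' @param ped data.frame with character columns `id`, `sire`, `dam` (NA =
#'   unknown) and optionally `sex`, `birth_year`.
#' @return A `litter_pedigree` object.
#' @export
new_litter_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  if (is.null(ped$sex)) ped$sex <- NA_character_
  if (is.null(ped$birth_year)) ped$birth_year <- NA_integer_
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (anyNA(si) || anyNA(di)) stop("parent id not present in pedigree")

  ord <- topo_sort_pedigree(si, di, ped$id)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  idx <- seq_len(n)
  names(idx) <- ped$id
  ped$sire_idx <- ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire]))
  ped$dam_idx <- ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  structure(list(ped = ped, n = n), class = "litter_pedigree")
}

# Kahn's algorithm; ties (several animals ready at once) resolved by input
# order. On a cycle, reports one offending chain.
topo_sort_pedigree <- function(sire_idx, dam_idx, ids) {
  n <- length(sire_idx)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (p > 0L) {
        if (p == i) stop("pedigree cycle detected: ", ids[i], " -> ", ids[i])
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ready <- which(indeg == 0L)      # ascending = input order
  ord <- integer(0)
  while (length(ready) > 0L) {
    v <- ready[1L]
    ready <- ready[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- sort(c(ready, k))
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links among the leftover vertices to exhibit a cycle
    chain <- left[1L]
    repeat {
      cur <- chain[length(chain)]
      p <- c(sire_idx[cur], dam_idx[cur])
      p <- p[p %in% left][1L]
      if (p %in% chain) {
        chain <- c(chain, p)
        break
      }
      chain <- c(chain, p)
    }
    stop("pedigree cycle detected: ", paste(ids[chain], collapse = " -> "))
  }
  ord
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding F from a sorted pedigree. Unknown parents
#' are treated as unrelated non-inbred founders, so any animal with at least
#' one unknown parent has F = 0.
#'
#' @param pedigree A `litter_pedigree`.
#' @return Numeric vector of F, named by animal id, in pedigree order.
#' @export
compute_inbreeding <- function(pedigree) {
  stopifnot(inherits(pedigree, "litter_pedigree"))
  s <- pedigree$ped$sire_idx
  d <- pedigree$ped$dam_idx
  n <- pedigree$n
  F <- numeric(n)
  # Mendelian-sampling variance of animal j given its parents' F
  mendel_d <- function(j) {
    if (s[j] > 0L && d[j] > 0L) 0.5 - 0.25 * (F[s[j]] + F[d[j]])
    else if (s[j] > 0L) 0.75 - 0.25 * F[s[j]]
    else if (d[j] > 0L) 0.75 - 0.25 * F[d[j]]
    else 1
  }
  L <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0L || d[i] == 0L) next      # F stays 0
    L[seq_len(i)] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * mendel_d(j)
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  names(F) <- pedigree$ped$id
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' inbreeding in the Mendelian-sampling variances: for animal i with parents
#' s and d, d_i = 0.5 - 0.25 (F_s + F_d), with the corresponding term dropped
#' for each unknown parent (0.75 - 0.25 F for one known parent, 1 for none).
#'
#' @param pedigree A `litter_pedigree`.
#' @param use_inbreeding If `FALSE`, F is taken as 0 for everyone (classical
#'   rules without inbreeding).
#' @return A sparse symmetric `Matrix::dgCMatrix`, dimnames = animal ids.
#' @export
build_a_inverse <- function(pedigree, use_inbreeding = TRUE) {
  stopifnot(inherits(pedigree, "litter_pedigree"))
  n <- pedigree$n
  s <- pedigree$ped$sire_idx
  d <- pedigree$ped$dam_idx
  F <- if (use_inbreeding) compute_inbreeding(pedigree) else numeric(n)
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA_real_)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA_real_)
  mend <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(s > 0L, 0.75 - 0.25 * Fs,
          ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  if (any(mend <= 0))
    stop("non-positive Mendelian-sampling variance; corrupt inbreeding values")
  al <- 1 / mend
  i <- seq_len(n)
  ii <- c(i); jj <- c(i); xx <- c(al)
  hs <- s > 0L
  hd <- d > 0L
  ii <- c(ii, i[hs], s[hs], s[hs])
  jj <- c(jj, s[hs], i[hs], s[hs])
  xx <- c(xx, -0.5 * al[hs], -0.5 * al[hs], 0.25 * al[hs])
  ii <- c(ii, i[hd], d[hd], d[hd])
  jj <- c(jj, d[hd], i[hd], d[hd])
  xx <- c(xx, -0.5 * al[hd], -0.5 * al[hd], 0.25 * al[hd])
  hb <- hs & hd
  ii <- c(ii, s[hb], d[hb])
  jj <- c(jj, d[hb], s[hb])
  xx <- c(xx, 0.25 * al[hb], 0.25 * al[hb])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$ped$id, pedigree$ped$id))
  methods::as(Ainv, "CsparseMatrix")
}

#' Pedigree depth statistics
#'
#' Complete generations: the largest g such that all 2^g ancestors at depth g
#' are known. Equivalent generations: the sum over all known ancestors of
#' (1/2)^depth, a standard measure of pedigree completeness.
#'
#' @param pedigree A `litter_pedigree`.
#' @return data.frame with columns `id`, `complete_generations`,
#'   `equivalent_generations`, one row per animal in pedigree order.
#' @export
pedigree_depth <- function(pedigree) {
  stopifnot(inherits(pedigree, "litter_pedigree"))
  s <- pedigree$ped$sire_idx
  d <- pedigree$ped$dam_idx
  n <- pedigree$n
  comp <- integer(n)
  eq <- numeric(n)
  for (i in seq_len(n)) {   # parents precede offspring, so recursion unrolls
    if (s[i] > 0L && d[i] > 0L) comp[i] <- 1L + min(comp[s[i]], comp[d[i]])
    contrib <- 0
    if (s[i] > 0L) contrib <- contrib + 0.5 * (1 + eq[s[i]])
    if (d[i] > 0L) contrib <- contrib + 0.5 * (1 + eq[d[i]])
    eq[i] <- contrib
  }
  data.frame(id = pedigree$ped$id, complete_generations = comp,
             equivalent_generations = eq, stringsAsFactors = FALSE)
}

#' @export
print.litter_pedigree <- function(x, ...) {
  nf <- sum(x$ped$sire_idx == 0L & x$ped$dam_idx == 0L)
  cat("<litter_pedigree> ", x$n, " animals (", nf, " founders)\n", sep = "")
  invisible(x)
}
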