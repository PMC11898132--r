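#' Standardize a parity to the Legendre interval
#'
#' Maps parity t in `[t_min, t_max]` linearly onto `[-1, 1]`.
#'
#' @param t Parity (vectorized).
#' @param t_min,t_max Parity bounds (defaults 1 and 6).
#' @return Standardized time x in `[-1, 1]`.
#' @export
standardize_parity <- function(t, t_min = 1, t_max = 6) {
  stopifnot(t_min < t_max)
  if (any(t < t_min | t > t_max))
    stop("parity outside [", t_min, ", ", t_max, "]; collapse records first")
  -1 + 2 * (t - t_min) / (t_max - t_min)
}

#' Normalized Legendre polynomial value
#'
#' phi_k(x) = sqrt((2k+1)/2) * P_k(x), with P_k by the Bonnet recurrence.
#' The sqrt((2k+1)/2) scaling makes the basis orthonormal on `[-1, 1]`, the
#' usual parameterization for random-regression covariance functions.
#'
#' @param k Polynomial order (scalar, >= 0).
#' @param x Standardized time(s) in `[-1, 1]`.
#' @export
legendre_value <- function(k, x) {
  stopifnot(k >= 0, all(abs(x) <= 1 + 1e-12))
  pkm1 <- rep(1, length(x))            # P_0
  if (k == 0) return(sqrt(1 / 2) * pkm1)
  pk <- x                              # P_1
  if (k >= 2) {
    for (m in 2:k) {                   # Bonnet: m P_m = (2m-1) x P_{m-1} - (m-1) P_{m-2}
      pkp1 <- ((2 * m - 1) * x * pk - (m - 1) * pkm1) / m
      pkm1 <- pk
      pk <- pkp1
    }
  }
  sqrt((2 * k + 1) / 2) * pk
}

#' Build a parity trajectory basis
#'
#' Evaluates the normalized Legendre polynomials of order 0..`order` at the
#' standardized parities `t_min..t_max`. Row t of `phi` is the covariate
#' vector shared by the fixed regression and both random regressions.
#'
#' @param order Highest polynomial order (default 2).
#' @param t_min,t_max Parity bounds.
#' @return A `trajectory_basis`: list with `order`, `t_min`, `t_max` and the
#'   `(t_max - t_min + 1) x (order + 1)` matrix `phi`.
#' @export
build_basis <- function(order = 2, t_min = 1, t_max = 6) {
  stopifnot(order >= 0)
  ts <- t_min:t_max
  x <- standardize_parity(ts, t_min, t_max)
  phi <- sapply(0:order, function(k) legendre_value(k, x))
  phi <- matrix(phi, nrow = length(ts), ncol = order + 1,
                dimnames = list(ts, paste0("phi", 0:order)))
  structure(list(order = order, t_min = t_min, t_max = t_max, phi = phi,
                 raw_intercept = FALSE),
            class = "trajectory_basis")
}

#' Intercept-only basis for the repeatability model
#'
#' The repeatability model is the degenerate trajectory with a single raw
#' constant covariate 1 (not phi_0 = sqrt(1/2)) per random effect, so the
#' coefficient variances are the usual animal and permanent-environment
#' variances directly.
#'
#' @param t_min,t_max Parity bounds.
#' @return A `trajectory_basis` of order 0 whose `phi` column is all ones.
#' @export
repeatability_basis <- function(t_min = 1, t_max = 6) {
  ts <- t_min:t_max
  phi <- matrix(1, nrow = length(ts), ncol = 1,
                dimnames = list(ts, "intercept"))
  structure(list(order = 0, t_min = t_min, t_max = t_max, phi = phi,
                 raw_intercept = TRUE),
            class = "trajectory_basis")
}

#' @export
print.trajectory_basis <- function(x, ...) {
  cat("<trajectory_basis> order", x$order, "on parities",
      x$t_min, "..", x$t_max,
      if (x$raw_intercept) "(raw intercept)" else "(normalized Legendre)", "\n")
  print(round(x$phi, 5))
  invisible(x)
}

#' Encode litter size as an ordered category
#'
#' The prolific line uses three categories (one, two, more than two lambs);
#' the conventional line two (one, more than one).
#'
#' @param litter_size Integer count(s) of lambs born, >= 1.
#' @param line `"prolific"` or `"conventional"`.
#' @return Integer category in 1..3 (prolific) or 1..2 (conventional).
#' @export
encode_category <- function(litter_size, line = c("prolific", "conventional")) {
  line <- match.arg(line)
  ls <- litter_size
  if (any(is.na(ls)) || any(ls < 1) || any(ls != round(ls)))
    stop("litter sizes must be integers >= 1")
  if (line == "prolific") pmin(as.integer(ls), 3L) else
    ifelse(ls >= 2, 2L, 1L)
}

#' Map parity to a residual-variance class
#'
#' Residual variances are heterogeneous by parity in three classes:
#' prolific line \{1\}, \{2-4\}, \{5,6\}; conventional line \{1\}, \{2,6\},
#' \{3-5\}.
#'
#' @param parity Integer parity 1..6 (vectorized).
#' @param line `"prolific"` or `"conventional"`.
#' @return Integer class 1..3.
#' @export
assign_residual_class <- function(parity, line = c("prolific", "conventional")) {
  line <- match.arg(line)
  stopifnot(all(parity %in% 1:6))
  if (line == "prolific") {
    c(1L, 2L, 2L, 2L, 3L, 3L)[parity]
  } else {
    c(1L, 2L, 3L, 3L, 3L, 2L)[parity]
  }
}

#' Read a litter-size records file
#'
#' Reads delimited text with columns `ewe`, `year`, `month`, `parity`,
#' `litter_size` (header required; comma or tab autodetected). Months may be
#' calendar numbers 9/10/11 or names Sep/Oct/Nov. Parities above `t_max` are
#' collapsed to `t_max`; litter sizes must be integers >= 1 (zeros are
#' rejected). Categories and residual classes are attached according to
#' `line`.
#'
#' @param path Records file path.
#' @param line `"prolific"` (3 categories) or `"conventional"` (2).
#' @param pedigree Optional `litter_pedigree`; if given, every ewe must be in
#'   it (fatal otherwise, listing the missing ids).
#' @param t_max Last parity class (default 6).
#' @return data.frame of class `parity_records` with columns `ewe`,
#'   `year_level`, `month_level`, `parity`, `litter_size`, `category`,
#'   `residual_class`, and attributes `line`, `year_levels`, `month_levels`.
#' @export
read_records <- function(path, line = c("prolific", "conventional"),
                         pedigree = NULL, t_max = 6) {
  line <- match.arg(line)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  need <- c("ewe", "year", "month", "parity", "litter")
  col <- lapply(need, function(p) {
    hit <- which(startsWith(names(raw), p))
    if (length(hit) == 0L) stop("records file missing column: ", p)
    raw[[hit[1L]]]
  })
  names(col) <- need
  month_map <- c(sep = 1L, oct = 2L, nov = 3L, "9" = 1L, "10" = 2L, "11" = 3L,
                 "1" = 1L, "2" = 2L, "3" = 3L)
  mk <- tolower(substr(col$month, 1, 3))
  month <- unname(month_map[mk])
  if (anyNA(month)) stop("unrecognized month values: ",
                         paste(unique(col$month[is.na(month)]), collapse = ", "))
  parity <- as.integer(col$parity)
  if (anyNA(parity) || any(parity < 1)) stop("parities must be integers >= 1")
  parity <- pmin(parity, t_max)
  ls <- suppressWarnings(as.numeric(col$litter))
  rec <- data.frame(ewe = col$ewe,
                    year_level = as.integer(factor(col$year)),
                    month_level = month,
                    parity = parity,
                    litter_size = as.integer(ls),
                    stringsAsFactors = FALSE)
  rec$category <- encode_category(ls, line)
  rec$residual_class <- assign_residual_class(parity, line)
  if (!is.null(pedigree)) {
    miss <- setdiff(unique(rec$ewe), pedigree$ped$id)
    if (length(miss) > 0L)
      stop("ewes with records but absent from pedigree: ",
           paste(miss, collapse = ", "))
  }
  attr(rec, "line") <- line
  attr(rec, "year_levels") <- levels(factor(col$year))
  attr(rec, "month_levels") <- sort(unique(month))
  class(rec) <- c("parity_records", "data.frame")
  rec
}

#' Assemble records into a parity-records object
#'
#' In-memory counterpart of [read_records()], used by the simulator.
#'
#' @param ewe,year_level,month_level,parity,litter_size Vectors of equal
#'   length; `year_level` and `month_level` already integer factor levels.
#' @param line Line name driving category coding and residual classes.
#' @return `parity_records` data.frame.
#' @export
make_records <- function(ewe, year_level, month_level, parity, litter_size,
                         line = c("prolific", "conventional")) {
  line <- match.arg(line)
  rec <- data.frame(ewe = as.character(ewe),
                    year_level = as.integer(year_level),
                    month_level = as.integer(month_level),
                    parity = as.integer(pmin(parity, 6L)),
                    litter_size = as.integer(litter_size),
                    stringsAsFactors = FALSE)
  rec$category <- encode_category(rec$litter_size, line)
  rec$residual_class <- assign_residual_class(rec$parity, line)
  attr(rec, "line") <- line
  attr(rec, "year_levels") <- as.character(sort(unique(rec$year_level)))
  attr(rec, "month_levels") <- sort(unique(rec$month_level))
  class(rec) <- c("parity_records", "data.frame")
  rec
}

#' Build the model design matrices
#'
#' X holds all year-of-lambing dummies, month dummies with the first level
#' dropped as reference, and the fixed-regression covariates (the basis row
#' of each record's parity). Z places the same basis row in each record's
#' animal block and spans every animal in the pedigree (animals without
#' records contribute through A only); W does the same per recorded ewe.
#'
#' @param records A `parity_records` data.frame.
#' @param pedigree A `litter_pedigree` containing every recorded ewe.
#' @param basis A `trajectory_basis`.
#' @return List of class `design_matrices` with sparse `X`, `Z`, `W`,
#'   `residual_class_of`, `ewe_ids` (column-block order of W), and the
#'   column layout in `x_cols`.
#' @export
build_design <- function(records, pedigree, basis) {
  stopifnot(inherits(pedigree, "litter_pedigree"),
            inherits(basis, "trajectory_basis"))
  miss <- setdiff(unique(records$ewe), pedigree$ped$id)
  if (length(miss) > 0L)
    stop("ewes with records but absent from pedigree: ",
         paste(miss, collapse = ", "))
  nrec <- nrow(records)
  q <- basis$order + 1L
  ny <- max(records$year_level)
  months <- sort(unique(records$month_level))
  nm <- length(months)
  phi_r <- basis$phi[records$parity - basis$t_min + 1L, , drop = FALSE]

  # X: [year dummies | month dummies minus reference | fixed regression]
  xi <- seq_len(nrec); xj <- records$year_level; xx <- rep(1, nrec)
  if (nm > 1L) {
    for (m in months[-1L]) {
      r <- which(records$month_level == m)
      xi <- c(xi, r)
      xj <- c(xj, rep(ny + match(m, months) - 1L, length(r)))
      xx <- c(xx, rep(1, length(r)))
    }
  }
  off <- ny + nm - 1L
  for (k in seq_len(q)) {
    xi <- c(xi, seq_len(nrec))
    xj <- c(xj, rep(off + k, nrec))
    xx <- c(xx, phi_r[, k])
  }
  X <- Matrix::sparseMatrix(i = xi, j = xj, x = xx, dims = c(nrec, off + q))
  colnames(X) <- c(paste0("year", seq_len(ny)),
                   if (nm > 1L) paste0("month", months[-1L]),
                   paste0("beta", seq_len(q) - 1L))

  anim_idx <- match(records$ewe, pedigree$ped$id)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(nrec), each = q),
    j = as.vector(t((anim_idx - 1L) * q + matrix(seq_len(q), nrec, q, byrow = TRUE))),
    x = as.vector(t(phi_r)),
    dims = c(nrec, q * pedigree$n))
  ewe_ids <- unique(records$ewe)
  ewe_idx <- match(records$ewe, ewe_ids)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(nrec), each = q),
    j = as.vector(t((ewe_idx - 1L) * q + matrix(seq_len(q), nrec, q, byrow = TRUE))),
    x = as.vector(t(phi_r)),
    dims = c(nrec, q * length(ewe_ids)))
  structure(list(X = X, Z = Z, W = W,
                 residual_class_of = records$residual_class,
                 ewe_ids = ewe_ids,
                 x_cols = list(n_year = ny, months = months, q = q)),
            class = "design_matrices")
}
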