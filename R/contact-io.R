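## Contact-map and structure input/output plus matrix balancing.
## On-disk formats use 0-based bin indices; the R API is 1-based.

#' Read a contact map
#'
#' Two plain-text formats are supported. `triplet`: whitespace-delimited
#' `i j f` lines with 0-based bin indices and non-negative frequencies;
#' lines starting with `#` are comments (a `# n_loci=N` header, as written by
#' [writeContacts()], fixes the locus count for maps whose last bins are
#' empty). If only one triangle is present it is mirrored; if both are
#' present, mirror values must agree to relative 1e-6. `dense`: an `n x n`
#' whitespace-delimited matrix, which must be square and symmetric to
#' relative 1e-6.
#'
#' @param path file to read.
#' @param format `"triplet"` or `"dense"`.
#' @param nLoci optional locus count override (triplet format only).
#' @return a [ContactMap-class].
#' @seealso [writeContacts()]
#' @export
readContacts <- function(path, format = c("triplet", "dense"), nLoci = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) {
      stop("dense contact matrix must be square, got ",
           nrow(m), " x ", ncol(m))
    }
    if (any(m < 0)) stop("negative contact frequency")
    rel <- abs(m - t(m)) / pmax(abs(m), abs(t(m)), 1e-300)
    bad <- which(m != t(m) & rel > 1e-6, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("asymmetric dense matrix at (%d, %d) [0-based]",
                   bad[1, 1] - 1L, bad[1, 2] - 1L))
    }
    ut <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
    return(.newContactMap(ut[, 1L], ut[, 2L], m[ut], nrow(m)))
  }
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  nHeader <- NA_integer_
  hm <- regmatches(header, regexec("n_loci\\s*[=:]\\s*([0-9]+)", header))
  for (h in hm) if (length(h) == 2L) nHeader <- as.integer(h[2L])
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body)) {
    con <- textConnection(body)
    on.exit(close(con))
    d <- utils::read.table(con, header = FALSE, col.names = c("i", "j", "f"))
  } else {
    d <- data.frame(i = integer(), j = integer(), f = numeric())
  }
  if (any(d$f < 0)) stop("negative contact frequency")
  if (any(d$i < 0 | d$j < 0)) stop("negative bin index")
  i0 <- pmin(d$i, d$j)
  j0 <- pmax(d$i, d$j)
  key <- paste(i0, j0)
  if (anyDuplicated(key)) {
    split_f <- split(d$f, key)
    dup <- split_f[lengths(split_f) > 1L]
    for (k in names(dup)) {
      v <- dup[[k]]
      if (max(abs(v - v[1L])) > 1e-6 * max(abs(v))) {
        stop("asymmetric triplet input at bins (", k, ") [0-based]: ",
             paste(v, collapse = " vs "))
      }
    }
    first <- !duplicated(key)
    i0 <- i0[first]; j0 <- j0[first]
    d <- d[first, , drop = FALSE]
  }
  n <- max(nHeader, if (length(j0)) max(j0) + 1L else 0L, nLoci, 1L,
           na.rm = TRUE)
  .newContactMap(i0 + 1L, j0 + 1L, d$f, as.integer(n))
}

#' Write a contact map
#'
#' Triplet output stores the upper triangle (`i <= j`, 0-based) with a
#' `# n_loci=N` header so the shape round-trips even for empty maps; dense
#' output writes the full symmetric matrix. `readContacts(writeContacts(m))`
#' reproduces every stored entry.
#'
#' @param map a [ContactMap-class].
#' @param path output file.
#' @param format `"triplet"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
writeContacts <- function(map, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  stopifnot(is(map, "ContactMap"))
  n <- nLoci(map)
  if (format == "dense") {
    m <- as.matrix(map@contacts)
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  tr <- .mapTriplets(map)
  lines <- c(
    sprintf("# n_loci=%d", n),
    sprintf("%d %d %.15g", tr$i - 1L, tr$j - 1L, tr$f)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Balance a contact map by symmetric iterative proportional scaling
#'
#' Removes coverage biases by alternately rescaling the symmetric matrix by
#' the square roots of its row sums (Sinkhorn-style iterative proportional
#' scaling) until the coefficient of variation of the row sums drops below
#' `tol`. Loci with no contacts are dropped first and reported. This is a
#' deliberately simple stand-in for Knight-Ruiz-type balancing with the same
#' intent: near-equal coverage per locus.
#'
#' @param map a [ContactMap-class].
#' @param tol target coefficient of variation of row sums (default 1e-5).
#' @param maxIter iteration cap (default 1000); if reached without
#'   convergence the last iterate is returned with a warning and
#'   `attr(, "converged") = FALSE`.
#' @return a balanced [ContactMap-class] over the retained loci, with
#'   attributes `keptLoci` (1-based original indices), `dropped` (original
#'   indices removed), `factors` (strictly positive per-locus scaling
#'   factors) and `converged`.
#' @export
balanceContacts <- function(map, tol = 1e-5, maxIter = 1000L) {
  stopifnot(is(map, "ContactMap"))
  n <- nLoci(map)
  m <- map@contacts
  rs <- Matrix::rowSums(m)
  keep <- which(rs > 0)
  dropped <- setdiff(seq_len(n), keep)
  if (length(dropped)) {
    m <- as(Matrix::forceSymmetric(m[keep, keep, drop = FALSE], uplo = "U"),
            "CsparseMatrix")
  }
  nk <- length(keep)
  if (nk == 0L) stop("contact map has no non-empty locus")
  p <- m@p
  ii <- m@i + 1L
  jj <- rep.int(seq_len(nk), diff(p))
  factors <- rep(1, nk)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    rs <- Matrix::rowSums(m)
    cv <- if (nk > 1L) stats::sd(rs) / mean(rs) else 0
    if (is.na(cv) || cv < tol) {
      converged <- TRUE
      break
    }
    s <- sqrt(rs / mean(rs))
    m@x <- m@x / (s[ii] * s[jj])
    factors <- factors / s
    iter <- iter + 1L
  }
  if (!converged && iter >= maxIter) {
    # check once more in case the last rescale finished the job
    rs <- Matrix::rowSums(m)
    cv <- if (nk > 1L) stats::sd(rs) / mean(rs) else 0
    converged <- is.na(cv) || cv < tol
    if (!converged) {
      warning("balancing did not converge after ", maxIter,
              " iterations (row-sum CV = ", signif(cv, 3), ")")
    }
  }
  out <- new("ContactMap", contacts = m, resolution = map@resolution,
             chains = if (length(map@chains)) map@chains[keep] else character())
  attr(out, "keptLoci") <- keep
  attr(out, "dropped") <- dropped
  attr(out, "factors") <- factors
  attr(out, "converged") <- converged
  out
}

#' Read a 3D structure from TSV
#'
#' Columns are `index, x, y, z` or `index, chain, x, y, z` (tab- or
#' whitespace-delimited, `#` comments allowed, optional header line starting
#' with `index`). File indices are 0-based.
#'
#' @param path file to read.
#' @return a [Structure3D-class].
#' @export
readStructure <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) && grepl("^index", body[1L])) body <- body[-1L]
  if (!length(body)) stop("empty structure file: ", path)
  con <- textConnection(body)
  on.exit(close(con))
  d <- utils::read.table(con, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) == 4L) {
    names(d) <- c("index", "x", "y", "z")
    ch <- character()
  } else if (ncol(d) == 5L) {
    names(d) <- c("index", "chain", "x", "y", "z")
    ch <- as.character(d$chain)
  } else {
    stop("structure TSV must have 4 or 5 columns, got ", ncol(d))
  }
  xyz <- as.matrix(d[, c("x", "y", "z")])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    stop("non-numeric or non-finite coordinates in ", path)
  }
  if (anyDuplicated(d$index)) {
    stop("duplicate locus index in ", path, ": ",
         d$index[anyDuplicated(d$index)])
  }
  Structure3D(xyz, loci = as.integer(d$index) + 1L, chains = ch)
}

#' Write a 3D structure to TSV
#'
#' @param structure a [Structure3D-class].
#' @param path output file.
#' @return `path`, invisibly. Coordinates are written with enough digits to
#'   round-trip below 1e-9 absolute error.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "Structure3D"))
  X <- structure@coords
  idx <- structure@loci - 1L
  if (length(structure@chains)) {
    lines <- sprintf("%d\t%s\t%.17g\t%.17g\t%.17g", idx, structure@chains,
                     X[, 1L], X[, 2L], X[, 3L])
    header <- "index\tchain\tx\ty\tz"
  } else {
    lines <- sprintf("%d\t%.17g\t%.17g\t%.17g", idx, X[, 1L], X[, 2L], X[, 3L])
    header <- "index\tx\ty\tz"
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
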