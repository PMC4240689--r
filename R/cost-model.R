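#' Cost model for alignment columns
#'
#' A cost model assigns a nonnegative cost `C(a, b)` to every alignment
#' column pairing symbols `a` and `b` (either may be the gap `'-'`). The
#' model is constrained the way metric edit distances require it:
#' `C(a, a) = 0` and `C('-','-') = 0`; `C(a, b) = C(b, a) > 0` for distinct
#' symbols; `C(a, '-') = C('-', a) = indel > 0`. All recombination-aware
#' distances in the package take a cost model; the default is the unit-cost
#' (Levenshtein) model.
#'
#' @param mismatch Substitution cost used for any pair of distinct symbols
#'   not covered by `matrix`. Must be positive.
#' @param indel Cost of aligning a symbol against a gap. Must be positive.
#' @param matrix Optional symmetric numeric matrix of substitution costs
#'   with identical row and column names (the symbols it covers); its
#'   diagonal must be zero and off-diagonal entries positive. Symbols not
#'   named here fall back to `mismatch`.
#' @param penalty Nonnegative cost charged per recombination switch (an
#'   orientation change between consecutive diploid alignment columns) by
#'   [sync_distance()] and [sync_distance_banded()]. Default 0, i.e. free
#'   recombination.
#'
#' @return An object of class `cost_model`.
#' @examples
#' cost_model()                      # unit costs
#' cost_model(mismatch = 10, indel = 1)  # substitutions 10x an indel
#' @seealso [read_cost_model()] to load a model from a TSV file.
#' @export
cost_model <- function(mismatch = 1, indel = 1, matrix = NULL, penalty = 0) {
  stopifnot(is.numeric(mismatch), length(mismatch) == 1L,
            is.numeric(indel), length(indel) == 1L,
            is.numeric(penalty), length(penalty) == 1L)
  if (mismatch <= 0) stop("substitution cost must satisfy C(a, b) > 0 for a != b")
  if (indel <= 0) stop("indel cost must be positive")
  if (penalty < 0) stop("recombination penalty must be nonnegative")
  if (!is.null(matrix)) {
    m <- as.matrix(matrix)
    syms <- rownames(m)
    if (is.null(syms) || is.null(colnames(m)) || !identical(syms, colnames(m)))
      stop("cost matrix must have identical row and column names")
    if (any(nchar(syms) != 1L) || GAP %in% syms)
      stop("cost matrix symbols must be single characters other than '-'")
    if (!isTRUE(all.equal(m, t(m))))
      stop("cost matrix violates symmetry: C(a, b) must equal C(b, a)")
    if (any(diag(m) != 0))
      stop("cost matrix violates C(a, a) = 0 on the diagonal")
    off <- m[row(m) != col(m)]
    if (length(off) && any(off <= 0))
      stop("cost matrix violates C(a, b) > 0 for a != b")
    matrix <- m
  }
  structure(list(mismatch = as.numeric(mismatch), indel = as.numeric(indel),
                 matrix = matrix, penalty = as.numeric(penalty)),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model>\n")
  cat("  indel:", x$indel, " mismatch (default):", x$mismatch,
      " recombination penalty:", x$penalty, "\n")
  if (!is.null(x$matrix)) {
    cat("  substitution matrix over {", paste(rownames(x$matrix), collapse = ","),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Column cost under a cost model
#'
#' Vectorized lookup of `C(a, b)` for single-character symbols `a`, `b`
#' (gap `'-'` allowed).
#'
#' @param costs A [cost_model()].
#' @param a,b Character vectors of single symbols, recycled to a common
#'   length.
#' @return Numeric vector of column costs.
#' @examples
#' column_cost(cost_model(), c("a", "a", "a"), c("a", "c", "-"))
#' @export
column_cost <- function(costs, a, b) {
  stopifnot(inherits(costs, "cost_model"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  mapply(function(ai, bi) {
    if (ai == bi) return(0)
    if (ai == GAP || bi == GAP) return(costs$indel)
    m <- costs$matrix
    if (!is.null(m) && ai %in% rownames(m) && bi %in% rownames(m))
      return(m[ai, bi])
    costs$mismatch
  }, a, b, USE.NAMES = FALSE)
}

# Dense (K+1)x(K+1) cost matrix for the C++ kernels over the given symbol
# set; index 1 (code 0) is the gap.
cost_matrix_for <- function(costs, symbols) {
  k <- length(symbols)
  cm <- matrix(0, k + 1L, k + 1L)
  if (k > 0) {
    sub <- matrix(costs$mismatch, k, k)
    diag(sub) <- 0
    if (!is.null(costs$matrix)) {
      hit <- intersect(symbols, rownames(costs$matrix))
      if (length(hit))
        sub[match(hit, symbols), match(hit, symbols)] <-
          costs$matrix[hit, hit, drop = FALSE]
    }
    cm[-1L, -1L] <- sub
    cm[1L, -1L] <- costs$indel
    cm[-1L, 1L] <- costs$indel
  }
  cm
}

# Smallest strictly positive single-column cost; scales the band radius in
# the threshold-doubling variants.
min_positive_cost <- function(cm) {
  pos <- cm[cm > 0]
  if (length(pos) == 0L) return(1)
  min(pos)
}

#' Read a cost model from a TSV file
#'
#' The file holds a tab-separated substitution matrix with a symbol header
#' row and a symbol first column, followed by a row labeled `indel` whose
#' first value is the indel cost (an optional row labeled `penalty` sets
#' the recombination penalty). All cost-model invariants are enforced:
#' symmetry, zero diagonal, positive off-diagonal entries and positive
#' indel cost; violations are reported naming the invariant.
#'
#' @param path Path to the TSV file.
#' @return A [cost_model()].
#' @seealso [write_cost_model()]
#' @export
read_cost_model <- function(path) {
  if (!file.exists(path)) stop("cost model file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("cost model file is empty or truncated")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(fields, `[`, "", 1L)
  special <- labels %in% c("indel", "penalty")
  header <- fields[[1L]]
  syms <- header[nzchar(header)]  # header may carry a leading empty cell
  body <- fields[-1L][!special[-1L]]
  if (length(body) != length(syms))
    stop("cost model matrix must have one row per header symbol")
  m <- matrix(NA_real_, length(syms), length(syms),
              dimnames = list(syms, syms))
  for (f in body) {
    if (length(f) != length(syms) + 1L)
      stop("cost model row for '", f[1L], "' has the wrong number of fields")
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(vals)) stop("non-numeric cost in row '", f[1L], "'")
    m[f[1L], ] <- vals
  }
  get_special <- function(name) {
    row <- fields[-1L][special[-1L]]
    row <- row[vapply(row, `[`, "", 1L) == name]
    if (length(row) == 0L) return(NULL)
    v <- suppressWarnings(as.numeric(row[[1L]][2L]))
    if (is.na(v)) stop("non-numeric ", name, " value")
    v
  }
  indel <- get_special("indel")
  if (is.null(indel)) stop("cost model file is missing the required 'indel' row")
  penalty <- get_special("penalty")
  cost_model(mismatch = max(m[row(m) != col(m)], 1), indel = indel,
             matrix = m, penalty = if (is.null(penalty)) 0 else penalty)
}

#' Write a cost model to a TSV file
#'
#' Inverse of [read_cost_model()]. Models without an explicit substitution
#' matrix are materialized over the given alphabet.
#'
#' @param costs A [cost_model()].
#' @param path Output path.
#' @param symbols Alphabet to materialize when `costs$matrix` is `NULL`.
#' @return `path`, invisibly.
#' @export
write_cost_model <- function(costs, path, symbols = c("a", "c", "g", "t")) {
  stopifnot(inherits(costs, "cost_model"))
  m <- costs$matrix
  if (is.null(m)) {
    m <- matrix(costs$mismatch, length(symbols), length(symbols),
                dimnames = list(symbols, symbols))
    diag(m) <- 0
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", rownames(m)), collapse = "\t"), con)
  for (s in rownames(m))
    writeLines(paste(c(s, format(m[s, ], trim = TRUE)), collapse = "\t"), con)
  writeLines(paste("indel", format(costs$indel), sep = "\t"), con)
  if (costs$penalty != 0)
    writeLines(paste("penalty", format(costs$penalty), sep = "\t"), con)
  invisible(path)
}
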