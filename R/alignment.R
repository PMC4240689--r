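#' Pair-wise alignment of two haplotypes
#'
#' A diploid genome is represented as a pair-wise alignment: two gapped
#' rows of identical length `L` over the alphabet plus the gap symbol
#' `'-'`. Removing the gaps from either row recovers the two haplotype
#' sequences. No column may carry a gap in both rows; this invariant is
#' what makes every step of the synchronized dynamic program strictly
#' positive off the diagonal, and inputs violating it are rejected rather
#' than silently repaired.
#'
#' @param top,bottom The two rows, as strings (gaps as `'-'`).
#' @param case_fold Fold input to lower case (default `TRUE`).
#' @return An object of class `pairwise_alignment` with elements `top`,
#'   `bottom` and `length`.
#' @examples
#' pairwise_alignment("actg---g", "a-tgagag")
#' @export
pairwise_alignment <- function(top, bottom, case_fold = TRUE) {
  top <- norm_seq(top, case_fold); bottom <- norm_seq(bottom, case_fold)
  aln <- structure(list(top = top, bottom = bottom, length = nchar(top)),
                   class = "pairwise_alignment")
  ok <- validate_alignment(aln)
  if (!ok) stop("invalid pair-wise alignment: ", attr(ok, "diagnostics"))
  aln
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> length", x$length, "\n")
  cat(" ", x$top, "\n ", x$bottom, "\n", sep = "")
  invisible(x)
}

#' Validate a pair-wise alignment
#'
#' Checks the alignment invariants: both rows are strings of equal length,
#' only alphabet symbols and `'-'` occur, and no column has a gap in both
#' rows. Returns `TRUE`/`FALSE` with a `diagnostics` attribute naming the
#' first violation (1-based column index where applicable).
#'
#' @param aln A `pairwise_alignment`, or a character vector of two rows.
#' @return Logical scalar with attribute `diagnostics`.
#' @examples
#' validate_alignment(c("a-c", "a--"))   # FALSE: double gap in column 2
#' @export
validate_alignment <- function(aln) {
  if (inherits(aln, "pairwise_alignment")) {
    rows <- c(aln$top, aln$bottom)
  } else {
    rows <- as.character(aln)
    if (length(rows) != 2L)
      return(structure(FALSE, diagnostics = "an alignment needs exactly 2 rows"))
  }
  if (anyNA(rows))
    return(structure(FALSE, diagnostics = "rows must not be NA"))
  if (nchar(rows[1L]) != nchar(rows[2L]))
    return(structure(FALSE, diagnostics = sprintf(
      "rows differ in length (%d vs %d)", nchar(rows[1L]), nchar(rows[2L]))))
  if (grepl(".", rows[1L], fixed = TRUE) || grepl(".", rows[2L], fixed = TRUE))
    return(structure(FALSE,
      diagnostics = "'.' is not accepted as a gap; use '-'"))
  t <- chars(rows[1L]); b <- chars(rows[2L])
  both <- which(t == GAP & b == GAP)
  if (length(both))
    return(structure(FALSE, diagnostics = sprintf(
      "column %d has a gap in both rows", both[1L])))
  structure(TRUE, diagnostics = "ok")
}

#' Remove gaps from an alignment row
#'
#' Returns the underlying sequence of an alignment row: its non-gap symbols
#' in order. Vectorized over rows.
#'
#' @param row Character vector of gapped rows.
#' @return Character vector of gap-free sequences.
#' @examples
#' strip_gaps("actg---g")  # "actgg"
#' @export
strip_gaps <- function(row) {
  gsub(GAP, "", as.character(row), fixed = TRUE)
}

#' Haplotype sequences of an alignment
#'
#' @param aln A [pairwise_alignment()].
#' @return Named character vector `c(top = , bottom = )` of the two gap-free
#'   haplotypes.
#' @export
haplotypes <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  c(top = strip_gaps(aln$top), bottom = strip_gaps(aln$bottom))
}

#' Apply a recombination mask to an alignment
#'
#' A recombination of a pair-wise alignment exchanges its two rows
#' column-wise: column `i` keeps its orientation where `mask[i] = 1` and is
#' swapped where `mask[i] = 0`. Swapping preserves the no-double-gap
#' invariant, so the result is again a valid alignment of the recombined
#' haplotypes.
#'
#' @param aln A [pairwise_alignment()].
#' @param mask Integer or logical vector of length `aln$length`; 1/`TRUE`
#'   keeps the column, 0/`FALSE` swaps it.
#' @return A `pairwise_alignment` with the masked columns exchanged.
#' @examples
#' aln <- pairwise_alignment("ngc", "atv")
#' apply_recombination(aln, c(1, 0, 1))  # rows "ntc" / "agv"
#' @export
apply_recombination <- function(aln, mask) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  mask <- as.integer(mask)
  if (length(mask) != aln$length)
    stop("mask length (", length(mask), ") must equal alignment length (",
         aln$length, ")")
  if (any(is.na(mask)) || any(!mask %in% c(0L, 1L)))
    stop("mask must contain only 0 and 1")
  t <- chars(aln$top); b <- chars(aln$bottom)
  swap <- mask == 0L
  tmp <- t[swap]; t[swap] <- b[swap]; b[swap] <- tmp
  pairwise_alignment(paste(t, collapse = ""), paste(b, collapse = ""),
                     case_fold = FALSE)
}

#' Switch positions of a recombination mask
#'
#' The phasing-relevant summary of a mask: the 1-based column indices `i`
#' (with `i >= 2`) where the orientation changes, i.e. `mask[i] !=
#' mask[i-1]`. Unlike the raw bits, switch positions are invariant under
#' complementing the mask (which only exchanges the roles of the two output
#' haplotypes).
#'
#' @param mask Integer/logical vector of mask bits.
#' @return Integer vector of switch columns (possibly empty).
#' @examples
#' switch_positions(c(1, 1, 0, 0, 1))  # 3 and 5
#' @export
switch_positions <- function(mask) {
  mask <- as.integer(mask)
  if (length(mask) < 2L) return(integer(0))
  which(diff(mask) != 0L) + 1L
}

# internal: alignment rows as a character vector
aln_rows <- function(aln) c(aln$top, aln$bottom)
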