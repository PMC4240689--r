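#' Read sequences from a FASTA file
#'
#' Parses FASTA via Biostrings. In plain-sequence mode gaps are rejected;
#' with `aligned = TRUE` the gap symbol `'-'` is permitted (the `'.'` gap
#' dialect is rejected with a clear message). Input is case-folded to
#' lower case unless disabled.
#'
#' @param path Path to the FASTA file.
#' @param aligned Permit gap characters (for aligned rows)?
#' @param case_fold Fold to lower case (default `TRUE`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE, case_fold = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonempty <- which(nzchar(trimws(first)))
  if (!length(nonempty)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(first[nonempty[1L]]), ">"))
    stop("malformed FASTA at line ", nonempty[1L],
         ": expected a '>' header line")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- norm_seq(as.character(set), case_fold)
  names(seqs) <- names(set)
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("'.' is not accepted as a gap character; use '-'")
  if (!aligned && any(grepl(GAP, seqs, fixed = TRUE)))
    stop("gap characters found in plain-sequence input; ",
         "use read_alignment() for aligned rows")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (gapped rows allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a diploid alignment from a 2-record aligned FASTA file
#'
#' @param path Path to an aligned FASTA with exactly two records of equal
#'   length (gaps as `'-'`).
#' @param case_fold Fold to lower case.
#' @return A [pairwise_alignment()].
#' @export
read_alignment <- function(path, case_fold = TRUE) {
  seqs <- read_fasta(path, aligned = TRUE, case_fold = case_fold)
  if (length(seqs) != 2L)
    stop("aligned input must have exactly 2 records, found ", length(seqs))
  if (nchar(seqs[1L]) != nchar(seqs[2L]))
    stop("aligned rows differ in length (", nchar(seqs[1L]), " vs ",
         nchar(seqs[2L]), ")")
  pairwise_alignment(seqs[[1L]], seqs[[2L]], case_fold = FALSE)
}

#' Write a diploid alignment as aligned FASTA
#'
#' @param aln A [pairwise_alignment()].
#' @param path Output path.
#' @param names Record names (default `hapA`/`hapB`).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, names = c("hapA", "hapB")) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  write_fasta(stats::setNames(c(aln$top, aln$bottom), names), path)
}

# Machine-readable report of a distance result; positions are 1-based.
report_record <- function(result, inputs = NULL, runtime = NA_real_,
                          seed = NULL) {
  stopifnot(inherits(result, "dip_distance"))
  rep <- list(algorithm = result$algorithm,
              distance = result$distance,
              runtime_s = runtime)
  if (!is.null(result$mask)) {
    rep$mask <- paste(result$mask, collapse = "")
    rep$switch_positions <- as.integer(result$switch_positions)
  }
  for (nm in c("mask1", "mask2")) {
    if (!is.null(result[[nm]])) rep[[nm]] <- paste(result[[nm]], collapse = "")
  }
  if (!is.null(result$alignment_ax)) {
    rep$per_haplotype <- list(
      ax = alignment_cost(result$alignment_ax,
                          if (is.null(inputs$costs)) cost_model() else inputs$costs),
      by = alignment_cost(result$alignment_by,
                          if (is.null(inputs$costs)) cost_model() else inputs$costs))
  }
  if (!is.null(inputs$files)) rep$inputs <- inputs$files
  if (!is.null(seed)) rep$seed <- seed
  rep
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
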