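#' @title Distance results
#' @description Every distance in the package returns a `dip_distance`
#' object: the distance value plus, when traceback was requested, the
#' optimal recombination mask (bit 1 = column kept in its original
#' orientation), its switch positions (1-based columns where the
#' orientation changes), the recombined alignment and the optimal output
#' alignment(s) realizing the distance.
#' @name dip_distance
NULL

new_dip_distance <- function(distance, algorithm, ...) {
  extra <- list(...)
  res <- c(list(distance = distance, algorithm = algorithm), extra)
  if (!is.null(res$mask)) res$switch_positions <- switch_positions(res$mask)
  structure(res, class = "dip_distance")
}

#' @export
print.dip_distance <- function(x, ...) {
  cat("<dip_distance> ", x$algorithm, ": distance = ",
      format(x$distance), "\n", sep = "")
  if (!is.null(x$mask)) {
    cat("  mask: ", paste(x$mask, collapse = ""), "\n", sep = "")
    sw <- x$switch_positions
    cat("  switches: ", if (length(sw)) paste(sw, collapse = ", ") else "none",
        "\n", sep = "")
  }
  for (nm in c("alignment", "alignment_ax", "alignment_by")) {
    if (!is.null(x[[nm]])) {
      cat("  ", nm, ":\n    ", x[[nm]]$top, "\n    ", x[[nm]]$bottom, "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' @export
as.double.dip_distance <- function(x, ...) x$distance
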