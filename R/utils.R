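`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Plain base implementation (chartr + reverse); kept free of XString
#' construction overhead because the simulator calls it per fragment.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

## split a DNA string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}
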