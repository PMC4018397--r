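# Shared helpers: alphabet handling, rounding, seeded RNG scope.

# Internal alphabet is DNA (T); U is accepted on input and converted.
# Reports that face the RNA world (nucleotide-bias tables) spell U.

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Characters outside `{A,C,G,T,U,N}`
#' raise an error.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector over `{A,C,G,T,N}`.
#' @keywords internal
normalize_seq <- function(seq) {
  out <- chartr("u", "T", toupper(seq))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    abort(sprintf("sequence contains non-nucleotide characters: %s",
                  paste(head(which(bad), 3), collapse = ", ")),
          class = "caprimir_alphabet_error")
  }
  out
}

#' Reverse complement (DNA alphabet)
#'
#' @param seq character vector over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", normalize_seq(seq))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Round half away from zero
#'
#' Printed report tables round 2.375 to 2.38 (half-up), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards; all generators funnel through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer", class = "caprimir_domain_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# stopifnot-style domain check with classed condition
check_that <- function(ok, msg, class = "caprimir_domain_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
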