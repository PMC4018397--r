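# Energy parameter set for the folding and duplex modules.
#
# Approximate nearest-neighbour stacking free energies at 37 C in
# kcal/mol, rounded to 0.1; magnitudes follow the standard
# Watson-Crick and G.U wobble tables. Loop penalties are tabulated to
# a cutoff and extrapolated logarithmically (Jacobson-Stockmayer,
# 1.75 RT ln(L/L0) with RT = 0.616 kcal/mol at 37 C). The model has
# no dangling ends and no multibranch loops; it is deliberately small
# enough to verify against exhaustive enumeration.

PAIR_LEVELS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Folding energy parameters
#'
#' The parameter set shared by [fold_mfe()] and [duplex_energy()]:
#' a 6x6 stacking matrix over the pair types `AU, UA, CG, GC, GU, UG`
#' (row = outer pair 5'-3', column = inner pair) and hairpin / bulge /
#' internal loop penalties by unpaired length.
#'
#' @param min_hairpin minimum unpaired bases in a hairpin loop
#'   (default 3).
#' @param max_loop maximum unpaired bases in a bulge or internal loop
#'   (default 30).
#' @return a list with elements `stack` (matrix, kcal/mol), `hairpin`,
#'   `bulge`, `internal` (penalty lookup functions of loop length),
#'   `min_hairpin`, `max_loop`.
#' @export
energy_params <- function(min_hairpin = 3L, max_loop = 30L) {
  stack <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # outer GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.4,  # outer GU
    -1.0, -0.6, -2.1, -1.4, -0.3, -0.5), # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))

  rt175 <- 1.75 * 0.616
  hairpin_tab <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)      # L = 3..9
  bulge_tab <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)             # L = 1..6
  internal_tab <- c(1.5, 1.6, 1.7, 2.0, 2.1, 2.3, 2.5)     # L = 2..8

  list(
    stack = stack,
    hairpin = function(L) {
      ifelse(L < min_hairpin, Inf,
             ifelse(L <= 9, hairpin_tab[pmax(L, min_hairpin) - 2],
                    6.4 + rt175 * log(L / 9)))
    },
    bulge = function(L) {
      ifelse(L < 1 | L > max_loop, Inf,
             ifelse(L <= 6, bulge_tab[pmin(L, 6)],
                    4.4 + rt175 * log(L / 6)))
    },
    internal = function(L) {
      ifelse(L < 2 | L > max_loop, Inf,
             ifelse(L <= 8, internal_tab[pmin(pmax(L, 2), 8) - 1],
                    2.5 + rt175 * log(L / 8)))
    },
    min_hairpin = as.integer(min_hairpin),
    max_loop = as.integer(max_loop)
  )
}

# pair type of two bases in internal DNA spelling; NA if unpairable
pair_type <- function(a, b) {
  key <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  out <- rep(NA_character_, length(key))
  out[key %in% PAIR_LEVELS] <- key[key %in% PAIR_LEVELS]
  out
}

# encode internal-alphabet sequence as integer codes A=0 C=1 G=2 T=3
encode_seq <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) {
    abort("sequence must be over {A,C,G,U/T} for folding",
          class = "caprimir_alphabet_error")
  }
  codes
}

# penalty vectors of length n for the C++ engine (1-based by loop length)
loop_tables <- function(n, params) {
  L <- seq_len(max(n, 1L))
  list(hairpin = params$hairpin(L), bulge = params$bulge(L),
       internal = params$internal(L))
}
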