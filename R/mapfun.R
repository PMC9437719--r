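#' Map functions
#'
#' Convert between recombination fractions and genetic distances.
#' The Kosambi function, `d = 25 * log((1 + 2r) / (1 - 2r))` centimorgans,
#' allows for partial crossover interference and is the convention used
#' throughout this package; the Haldane function (no interference) is
#' provided for the simulator.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d genetic distance(s) in centimorgans, `>= 0`.
#' @return `kosambi()`/`haldane()` return distances in cM;
#'   `kosambi_inverse()`/`haldane_inverse()` return recombination fractions.
#' @examples
#' kosambi(0.25)                 # 25 * log(3) = 27.465
#' kosambi_inverse(kosambi(0.1)) # 0.1
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop_input("recombination fraction must lie in [0, 0.5); r = 0.5 maps to infinite distance")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_input("map distance must be non-negative")
  0.5 * tanh(d / 50)
}

#' @rdname kosambi
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop_input("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_input("map distance must be non-negative")
  0.5 * (1 - exp(-d / 50))
}

map_fun <- function(name) {
  switch(name, kosambi = kosambi, haldane = haldane,
         stop_input("unknown map function: ", name))
}

map_fun_inverse <- function(name) {
  switch(name, kosambi = kosambi_inverse, haldane = haldane_inverse,
         stop_input("unknown map function: ", name))
}
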