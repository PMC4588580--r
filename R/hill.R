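#' Hill activation function
#'
#' Fraction of maximal activity contributed by an activator at concentration
#' `x`, with half-maximal coefficient `a` and Hill exponent `n`:
#' `x^n / (a^n + x^n)`. All regulatory nonlinearities in the cell cycle model
#' use this form (or its repressive mirror [hillRepression()]); `n = 6` is
#' the model-wide default, reflecting the steep, switch-like response of
#' two-state (fully phosphorylated/dephosphorylated) proteins.
#'
#' @param x Concentration of the modifier (non-negative; values below zero
#'   are treated as zero).
#' @param a Half-maximal activation coefficient (> 0). The function equals
#'   0.5 exactly at `x = a`.
#' @param n Hill exponent (>= 1).
#' @return A value (or vector) in `[0, 1)`, strictly increasing in `x`.
#' @seealso [hillRepression()]
#' @examples
#' hillActivation(0.3, 0.3)        # 0.5 at the half-max point
#' hillActivation(0.6, 0.3, 6)     # 64/65: steeply on
#' @export
hillActivation <- function(x, a, n = 6) {
  if (any(!is.finite(a)) || any(a <= 0))
    stop("half-maximal coefficient 'a' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill exponent 'n' must be >= 1", call. = FALSE)
  x <- pmax(x, 0)
  xn <- x^n
  xn / (a^n + xn)
}

#' Hill repression function
#'
#' Fraction of maximal activity remaining under a repressor at concentration
#' `x`: `r^n / (r^n + x^n)`. Equals 1 with no repressor and 0.5 at `x = r`.
#'
#' @param x Concentration of the repressor (non-negative).
#' @param r Half-maximal repression coefficient (> 0).
#' @param n Hill exponent (>= 1).
#' @return A value (or vector) in `(0, 1]`, strictly decreasing in `x`.
#' @seealso [hillActivation()]
#' @examples
#' hillRepression(0, 0.2)      # 1: no repressor present
#' hillRepression(0.4, 0.2, 6) # 1/65: strongly repressed
#' @export
hillRepression <- function(x, r, n = 6) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("half-maximal coefficient 'r' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill exponent 'n' must be >= 1", call. = FALSE)
  x <- pmax(x, 0)
  rn <- r^n
  rn / (rn + x^n)
}
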