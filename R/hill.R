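#' Hill activation / repression term
#'
#' Saturating regulatory input used throughout the arch gene-regulatory network:
#' activation \eqn{s^n/(p^n + s^n)}, repression \eqn{p^n/(p^n + s^n)}.
#' The two modes are exact complements, so `hill(s, p, n, "activating") +
#' hill(s, p, n, "repressing") == 1` for any input.
#'
#' @param signal non-negative signal concentration(s); vectorised.
#' @param p microscopic dissociation constant (> 0), in the units of `signal`.
#' @param n Hill coefficient (integer >= 1, default 2).
#' @param mode `"activating"` or `"repressing"`.
#' @return fraction(s) in \[0, 1\], same length as `signal`.
#' @examples
#' hill(0, 1)            # 0
#' hill(1, 1)            # half-saturation: 0.5
#' hill(0, 1, mode = "repressing")  # 1
#' @export
hill <- function(signal, p, n = 2L, mode = c("activating", "repressing")) {
  mode <- match.arg(mode)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("hill(): 'signal' must be finite and non-negative")
  if (!is.finite(p) || p <= 0)
    stop("hill(): dissociation constant 'p' must be positive")
  if (n < 1) stop("hill(): Hill coefficient 'n' must be >= 1")
  sn <- signal^n
  pn <- p^n
  if (mode == "activating") sn / (pn + sn) else pn / (pn + sn)
}
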