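# Drug-combination synergy on fractional responses. The default criterion is
# the literal rule Fc > Fa * (1 - Fb). Note this differs from classic Bliss
# independence (Fa + Fb - Fa*Fb); both are exposed and neither is silently
# "corrected". Whether "fractional response" means fraction inhibited or
# fraction surviving changes which combinations qualify under the literal
# rule; callers must fix that interpretation for their data.

.check_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    .stopf("%s must be within [0, 1]", what)
}

#' Expected combination response under a null model
#'
#' `mode = "literal"` returns the threshold `fa * (1 - fb)`;
#' `mode = "bliss"` returns classic Bliss independence
#' `fa + fb - fa * fb`. Vectorized.
#'
#' @param fa,fb fractional responses to each single agent, in [0, 1].
#' @param mode `"literal"` (default) or `"bliss"`.
#' @return Numeric threshold(s).
#' @export
expected_combination <- function(fa, fb, mode = c("literal", "bliss")) {
  mode <- match.arg(mode)
  .check_fraction(fa, "fa"); .check_fraction(fb, "fb")
  if (mode == "literal") fa * (1 - fb) else fa + fb - fa * fb
}

#' Classify a combination as synergistic
#'
#' Synergy is declared when the combination's fractional response strictly
#' exceeds the null-model threshold; the margin `fc - threshold` is returned
#' for ranking.
#'
#' @param fa,fb,fc single-agent and combination fractional responses.
#' @param mode `"literal"` or `"bliss"` (see [expected_combination()]).
#' @return data.frame with `fa`, `fb`, `fc`, `threshold`, `margin`,
#'   `synergistic`. Vectorized over rows.
#' @export
is_synergistic <- function(fa, fb, fc, mode = c("literal", "bliss")) {
  mode <- match.arg(mode)
  .check_fraction(fc, "fc")
  thr <- expected_combination(fa, fb, mode)
  data.frame(fa = fa, fb = fb, fc = fc, threshold = thr,
             margin = fc - thr, synergistic = fc > thr)
}
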