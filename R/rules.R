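# Exact-mass constants (Da).  Singly charged ions are assumed throughout:
# observed m/z = neutral monoisotopic mass + delta_mz of the ionization rule.
PROTON_MASS   <- 1.007276
SODIUM_MASS   <- 22.989218
WATER_MASS    <- 18.010565
C13_SPACING   <- 1.003355  # 13C - 12C mass difference

#' Default adduct and neutral-loss rule table
#'
#' Returns the table of mass-shift rules used both by the structural search
#' and by the synthetic data generator, so that planted ion series and the
#' rules used to recover them share a single source of truth.  Each rule maps
#' a neutral monoisotopic mass M to an observed m/z as `mz = M + delta_mz`
#' (singly charged ions; no multi-charge deconvolution is attempted).
#'
#' @return A data.frame with columns `name`, `delta_mz` (Da), `polarity`
#'   (`"positive"` or `"negative"`) and `kind` (`"adduct"` or
#'   `"neutral_loss"`).  The identity adducts `[M+H]+` and `[M-H]-` are
#'   always present.
#' @examples
#' default_adduct_rules()
#' @export
default_adduct_rules <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+2Na-H]+", "[M+H-H2O]+",
             "[M-H]-", "[M-H-H2O]-"),
    delta_mz = c(PROTON_MASS,
                 SODIUM_MASS,
                 2 * SODIUM_MASS - PROTON_MASS,
                 PROTON_MASS - WATER_MASS,
                 -PROTON_MASS,
                 -PROTON_MASS - WATER_MASS),
    polarity = c("positive", "positive", "positive", "positive",
                 "negative", "negative"),
    kind = c("adduct", "adduct", "adduct", "neutral_loss",
             "adduct", "neutral_loss"),
    stringsAsFactors = FALSE
  )
}

validate_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("name", "delta_mz", "polarity", "kind") %in% names(rules)))
  if (!all(rules$polarity %in% c("positive", "negative")))
    stop("rule polarity must be 'positive' or 'negative'")
  for (pol in unique(rules$polarity)) {
    id <- if (pol == "positive") "[M+H]+" else "[M-H]-"
    if (!id %in% rules$name[rules$polarity == pol])
      stop("rule table must contain the identity adduct ", id,
           " for polarity ", pol)
  }
  invisible(rules)
}
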