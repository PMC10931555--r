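#' Drug/surfactant sample composition
#'
#' Composition record for a drug-loaded surfactant sample: drug content in
#' weight percent of the surfactant mass, the molar masses used for the
#' weight-to-mole conversion, and the optional calcium concentration of the
#' hydration medium (metadata).
#'
#' @param bud_wt_pct Drug (budesonide) content, mass percent of the
#'   surfactant mass (>= 0).
#' @param M_bud Drug molar mass, g/mol (default 430.53, budesonide).
#' @param M_lipid Effective surfactant molar mass, g/mol (default 762, the
#'   relative molar mass conventionally used for the porcine surfactant
#'   extract).
#' @param ca_mmol Ca2+ concentration of the hydration medium, mmol/L
#'   (metadata only).
#' @return An object of class `sample_composition`.
#' @export
sample_composition <- function(bud_wt_pct, M_bud = 430.53, M_lipid = 762,
                               ca_mmol = 0) {
  if (bud_wt_pct < 0) stop("`bud_wt_pct` must be >= 0", call. = FALSE)
  if (M_bud <= 0 || M_lipid <= 0) {
    stop("molar masses must be positive", call. = FALSE)
  }
  structure(list(bud_wt_pct = bud_wt_pct, M_bud = M_bud, M_lipid = M_lipid,
                 ca_mmol = ca_mmol),
            class = "sample_composition")
}

#' Moles of surfactant lipid per mole of drug
#'
#' Converts a weight-percent drug loading to the lipid-per-drug mole ratio:
#' r = (100 / M_lipid) / (wt% / M_drug), i.e. 100 g of surfactant against
#' wt% grams of drug. A loading of 4 wt% gives r = 14.1 ("1:14" drug:lipid);
#' 8 wt% gives r = 7.1 ("1:7").
#'
#' @param comp A [sample_composition()], or a bare wt% value (the default
#'   molar masses are then used).
#' @return The mole ratio r (> 0), a plain number. The rounded "1:N" label
#'   is available via [format_molar_ratio()].
#' @export
#' @examples
#' molar_ratio(4)  # ~14.1
#' format_molar_ratio(molar_ratio(8))  # "1:7"
molar_ratio <- function(comp) {
  if (!inherits(comp, "sample_composition")) {
    comp <- sample_composition(comp)
  }
  if (comp$bud_wt_pct == 0) {
    stop("drug content is 0 wt%: the lipid-per-drug ratio is not finite",
         call. = FALSE)
  }
  (100 / comp$M_lipid) / (comp$bud_wt_pct / comp$M_bud)
}

#' @rdname molar_ratio
#' @param r A mole ratio as returned by [molar_ratio()].
#' @export
format_molar_ratio <- function(r) sprintf("1:%d", round(r))
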