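#' Drug specification
#'
#' Describes one commercial parenteral-nutrition suspension: its nutrient
#' composition and the refractive indices that govern how strongly its
#' lipid micelles scatter coherent light. The micelle index `n_lipid`
#' (olive/soy/fish oil, ~1.450-1.485 RIU) always exceeds the aqueous
#' matrix index `n_matrix` (~1.349-1.361 RIU, driven mainly by water and
#' glucose content); the contrast `delta_n = n_lipid - n_matrix` together
#' with the lipid concentration sets the scattered intensity.
#'
#' @param name Commercial name.
#' @param lipids_g_per_L,amino_acids_g_per_L,glucose_g_per_L Nutrient
#'   concentrations in g/L.
#' @param calories_kcal_per_L Caloric density, kcal/L.
#' @param n_lipid,n_matrix Refractive indices in RIU.
#' @return A `drug_spec` object.
#' @export
drug_spec <- function(name, lipids_g_per_L, amino_acids_g_per_L,
                      glucose_g_per_L, calories_kcal_per_L,
                      n_lipid = 1.4675, n_matrix = 1.355) {
  stopifnot(is.character(name), length(name) == 1L)
  conc <- c(lipids_g_per_L, amino_acids_g_per_L, glucose_g_per_L,
            calories_kcal_per_L)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  if (n_lipid < 1.450 || n_lipid > 1.485)
    stop("n_lipid outside the plausible micelle range [1.450, 1.485]")
  if (n_matrix < 1.349 || n_matrix > 1.361)
    stop("n_matrix outside the plausible matrix range [1.349, 1.361]")
  if (n_lipid <= n_matrix) stop("n_lipid must exceed n_matrix")
  structure(
    list(name = name,
         lipids_g_per_L = lipids_g_per_L,
         amino_acids_g_per_L = amino_acids_g_per_L,
         glucose_g_per_L = glucose_g_per_L,
         calories_kcal_per_L = calories_kcal_per_L,
         n_lipid = n_lipid, n_matrix = n_matrix),
    class = "drug_spec")
}

#' Built-in catalog of the six commercial suspensions
#'
#' Returns the six-drug catalog with published compositions. The matrix
#' refractive index is not published per product; it is assigned by
#' rank-scaling the combined glucose + amino acid content onto the stated
#' matrix range \[1.349, 1.361\] (the matrix index is driven mainly by the
#' dissolved solutes), and the micelle index is fixed at the midpoint
#' 1.4675 of the oil range.
#'
#' @return A list of [drug_spec()] objects, length 6.
#' @examples
#' cat6 <- pan_drug_catalog()
#' sapply(cat6, function(d) brightness_factor(d, cat6))
#' @export
pan_drug_catalog <- function() {
  tab <- data.frame(
    name = c("OLIMEL N5E", "OLIMEL N7E", "OLIMEL N12E", "OLIMEL N4E",
             "FINOMEL", "NUMETA G13E"),
    lipids = c(40.00, 40.00, 35.07, 30.00, 28.20, 25.00),
    amino = c(32.93, 44.27, 76.00, 25.30, 31.51, 29.47),
    glucose = c(115.00, 140.00, 73.38, 75.00, 70.69, 133.33),
    kcal = c(990, 1140, 954, 700, 1091, 910),
    stringsAsFactors = FALSE)
  solutes <- tab$glucose + tab$amino
  r <- rank(solutes, ties.method = "first")
  n_m <- 1.349 + (1.361 - 1.349) * (r - 1) / (length(r) - 1)
  lapply(seq_len(nrow(tab)), function(i)
    drug_spec(tab$name[i], tab$lipids[i], tab$amino[i], tab$glucose[i],
              tab$kcal[i], n_lipid = 1.4675, n_matrix = n_m[i]))
}

#' Relative scattering brightness of a drug
#'
#' Single-scatterer (Rayleigh-Gans) scattered power scales with the
#' scatterer concentration and with the square of the refractive-index
#' contrast, so the expected speckle image brightness is modeled as
#' B = lipids * delta_n^2, normalized by the catalog maximum to \[0, 1\].
#'
#' @param drug A [drug_spec()].
#' @param catalog Non-empty list of [drug_spec()] used for normalization.
#' @return Scalar brightness factor in \[0, 1\].
#' @export
brightness_factor <- function(drug, catalog) {
  if (!inherits(drug, "drug_spec")) stop("drug must be a drug_spec")
  if (length(catalog) == 0L) stop("catalog must be non-empty")
  prod1 <- function(d) d$lipids_g_per_L * (d$n_lipid - d$n_matrix)^2
  mx <- max(vapply(catalog, prod1, numeric(1)))
  if (mx <= 0) stop("catalog has all-zero scattering products")
  prod1(drug) / mx
}
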