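# Avogadro-derived unit constants used throughout:
#   1 g/cm^3 = 0.6022141 amu/A^3;  molecules per A^3 at 1 mol/L = 6.022141e-4
.AMU_PER_A3_PER_GCC <- 0.6022141
.MOLEC_PER_A3_PER_M <- 6.022141e-4
.WATER_VOLUME_A3 <- 30 # reference volume of one water molecule, A^3

.COMPONENT_CLASSES <- c("fatty_acid", "protein", "lps", "saccharide",
                        "water", "ion")

#' Built-in component registry
#'
#' Returns the table of chemical components used by the composition builder
#' and particle generator: the four saturated fatty acids (lauric, myristic,
#' palmitic, stearic), Burkholderia cepacia lipase (BCL), a rough
#' lipopolysaccharide construct, glucose, a 15-mer branched laminarin,
#' water, and the seawater ions. Molar masses are standard chemistry values;
#' the LPS and laminarin masses are configurable because no single exact
#' construct mass is canonical.
#'
#' Coarse-graining: 1 bead for water/ions/glucose, 2-bead head-tail rods for
#' fatty acids, rods of beads for LPS and laminarin, a bead blob for BCL.
#'
#' @param lps_molar_mass molar mass (amu) used for the LPS construct.
#' @param laminarin_molar_mass molar mass (amu) for the laminarin 15-mer.
#' @return data.frame with columns `name`, `component_class`, `molar_mass`
#'   (amu), `beads_per_molecule`, `head_tail_defined`, `charge`, `geometry`.
#' @export
#' @examples
#' component_registry()[, c("name", "component_class", "molar_mass")]
component_registry <- function(lps_molar_mass = 14000,
                               laminarin_molar_mass = 2450) {
  stopifnot(lps_molar_mass > 0, laminarin_molar_mass > 0)
  reg <- data.frame(
    name = c("LA", "MA", "PA", "SA", "BCL", "LPS", "GLC", "LAM",
             "SOL", "NA", "CL", "MG", "CA", "K"),
    component_class = c(rep("fatty_acid", 4), "protein", "lps",
                        "saccharide", "saccharide", "water",
                        rep("ion", 5)),
    molar_mass = c(200.32, 228.37, 256.42, 284.48, 33000,
                   lps_molar_mass, 180.16, laminarin_molar_mass,
                   18.015, 22.990, 35.453, 24.305, 40.078, 39.098),
    beads_per_molecule = c(2L, 2L, 2L, 2L, 12L, 10L, 1L, 5L,
                           1L, 1L, 1L, 1L, 1L, 1L),
    head_tail_defined = c(rep(TRUE, 4), rep(FALSE, 10)),
    charge = c(rep(0, 8), 0, +1, -1, +2, +2, +1),
    geometry = c(rep("rod", 4), "blob", "rod", "point", "rod",
                 "point", rep("point", 5)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(reg$molar_mass > 0),
            all(reg$beads_per_molecule >= 1L),
            all(!reg$head_tail_defined | reg$beads_per_molecule >= 2L))
  reg
}

# Mass split of the fatty-acid block given the 1:2:4:3 LA:MA:PA:SA molar ratio
.fa_mass_shares <- function(registry) {
  fa <- registry[registry$component_class == "fatty_acid", ]
  fa <- fa[match(c("LA", "MA", "PA", "SA"), fa$name), ]
  molar <- c(1, 2, 4, 3)
  m <- molar * fa$molar_mass
  stats::setNames(m / sum(m), fa$name)
}

#' Composition design for the three aerosol systems
#'
#' Builds the design targets for one of the three 40-nm sea-spray systems:
#' A (fatty acids + lipase), B (adds LPS and the divalent/minor cations),
#' C (adds glucose and laminarin). Targets are a total
#' inorganic:organic:water mass ratio of 0.09:0.40:0.51, a fatty-acid share
#' of organic mass of 93/80/63 % for A/B/C, a constant lipase load of 7 % of
#' organic mass (about 3 % of total mass), 0.4 M NaCl, and for B/C
#' 110 mM Mg2+, 25 mM Ca2+ and 20 mM K+.
#'
#' @param system_id "A", "B" or "C".
#' @param diameter particle diameter in Angstrom (default 400, i.e. 40 nm).
#' @param density overall particle mass density in g/cm^3 used to convert the
#'   particle volume into a mass budget (default 1.2, typical of an aqueous
#'   organic-salt particle near 70 % relative humidity).
#' @param registry component registry, see [component_registry()].
#' @return object of class `composition_spec`: list with `system_id`,
#'   `diameter`, `density`, `target_mass_ratio` (inorganic, organic, water),
#'   `organic_breakdown` (component -> fraction of organic mass, sums to 1),
#'   `salinity` (mol/L per cation species), `registry`.
#' @export
composition_spec <- function(system_id, diameter = 400, density = 1.2,
                             registry = component_registry()) {
  system_id <- as.character(system_id)
  if (!system_id %in% c("A", "B", "C")) {
    stop("unknown system_id '", system_id, "': must be one of A, B, C")
  }
  stopifnot(diameter > 0, density > 0)

  fa_share <- c(A = 0.93, B = 0.80, C = 0.63)[[system_id]]
  bcl_share <- 0.07   # constant lipase load, ~3 % of total particle mass
  fa <- .fa_mass_shares(registry) * fa_share
  breakdown <- switch(system_id,
    A = c(fa, BCL = bcl_share),
    B = c(fa, BCL = bcl_share, LPS = 0.13),
    C = c(fa, BCL = bcl_share, LPS = 0.13, GLC = 0.085, LAM = 0.085)
  )
  stopifnot(abs(sum(breakdown) - 1) < 1e-9)

  salinity <- if (system_id == "A") {
    c("NA" = 0.4)
  } else {
    c("NA" = 0.4, MG = 0.110, CA = 0.025, K = 0.020)
  }

  structure(list(
    system_id = system_id,
    diameter = diameter,
    density = density,
    target_mass_ratio = c(inorganic = 0.09, organic = 0.40, water = 0.51),
    organic_breakdown = breakdown,
    salinity = salinity,
    registry = registry
  ), class = "composition_spec")
}

# Largest-remainder rounding of nonnegative real counts to integers whose sum
# equals round(sum(x)). Deterministic: ties broken by index.
largest_remainder_round <- function(x) {
  stopifnot(all(x >= 0))
  total <- round(sum(x))
  fl <- floor(x)
  k <- total - sum(fl)
  if (k > 0) {
    rem <- x - fl
    ord <- order(rem, seq_along(x), decreasing = c(TRUE, FALSE),
                 method = "radix")
    fl[ord[seq_len(k)]] <- fl[ord[seq_len(k)]] + 1
  }
  as.integer(fl)
}

#' Discretize a composition design into integer molecule counts
#'
#' Converts the design targets of a [composition_spec()] into integer
#' molecule counts for a particle of the requested diameter. The water mass
#' is fixed at its target fraction (0.51) of the realized particle mass; ion
#' counts are set so the stated molarities hold in the aqueous volume (30 A^3
#' per water molecule) with chloride adjusted last for electroneutrality;
#' the organic phase takes the remaining mass budget, split according to the
#' design's organic breakdown and discretized by largest-remainder rounding.
#' Every component with a nonzero target receives at least one molecule.
#'
#' Note the published design quantities cannot all hold at once: 0.4 M NaCl
#' contributes far less mass than the nominal 9 % inorganic fraction, so the
#' realized inorganic fraction is ~1-2 % and the organic fraction absorbs the
#' difference. Molarities and the water fraction are honored exactly.
#'
#' @param system_id "A", "B" or "C", or a ready-made `composition_spec`.
#' @param diameter particle diameter, Angstrom.
#' @param ... passed to [composition_spec()].
#' @return object of class `composition`: list with `spec`, `counts` (named
#'   integer vector), and `achieved` (realized mass fractions, organic
#'   breakdown, fatty-acid share of organic mass, molarities).
#' @export
#' @examples
#' comp <- build_composition("A", diameter = 400)
#' comp$achieved$mass_fractions
#' comp$achieved$fa_share_of_organic_pct
build_composition <- function(system_id, diameter = 400, ...) {
  spec <- if (inherits(system_id, "composition_spec")) system_id
          else composition_spec(system_id, diameter = diameter, ...)
  reg <- spec$registry
  mm <- stats::setNames(reg$molar_mass, reg$name)

  volume <- (4 / 3) * pi * (spec$diameter / 2)^3
  total_mass <- spec$density * .AMU_PER_A3_PER_GCC * volume

  # ion mass per unit water mass implied by the molarities (+ neutral Cl)
  cation_per_water <- spec$salinity * .MOLEC_PER_A3_PER_M * .WATER_VOLUME_A3
  charges <- stats::setNames(reg$charge, reg$name)[names(cation_per_water)]
  cl_per_water <- sum(cation_per_water * charges)
  ion_mass_per_water <- sum(cation_per_water * mm[names(cation_per_water)]) +
    cl_per_water * mm[["CL"]]
  c_ion <- ion_mass_per_water / mm[["SOL"]]

  f_w <- spec$target_mass_ratio[["water"]]
  water_mass <- f_w * total_mass
  organic_mass <- total_mass - water_mass * (1 + c_ion)
  if (organic_mass <= 0) {
    stop("diameter ", spec$diameter,
         " A leaves no organic mass budget at the requested water fraction")
  }

  # one-of-each feasibility check for the organic phase
  org_names <- names(spec$organic_breakdown)
  need <- mm[org_names]
  if (organic_mass < sum(need)) {
    worst <- org_names[which.max(need)]
    stop("diameter ", spec$diameter, " A too small to hold >= 1 molecule of ",
         "every component (offending component: ", worst, ")")
  }

  n_water <- max(1L, as.integer(round(water_mass / mm[["SOL"]])))
  cation_counts <- largest_remainder_round(cation_per_water * n_water)
  names(cation_counts) <- names(cation_per_water)
  n_cl <- as.integer(sum(cation_counts * charges)) # electroneutrality

  org_real <- organic_mass * spec$organic_breakdown / mm[org_names]
  org_counts <- largest_remainder_round(org_real)
  org_counts[spec$organic_breakdown > 0 & org_counts < 1L] <- 1L
  names(org_counts) <- org_names

  counts <- c(org_counts, SOL = n_water, cation_counts, CL = n_cl)
  counts <- counts[counts > 0]

  masses <- counts * mm[names(counts)]
  cls <- stats::setNames(reg$component_class, reg$name)[names(counts)]
  organic_classes <- c("fatty_acid", "protein", "lps", "saccharide")
  m_org <- sum(masses[cls %in% organic_classes])
  m_wat <- sum(masses[cls == "water"])
  m_ion <- sum(masses[cls == "ion"])
  m_tot <- sum(masses)
  m_fa <- sum(masses[cls == "fatty_acid"])

  aq_volume_L <- counts[["SOL"]] * .WATER_VOLUME_A3 * 1e-27
  molarity <- counts[names(spec$salinity)] /
    (6.022141e23 * aq_volume_L)
  names(molarity) <- names(spec$salinity)

  achieved <- list(
    mass_fractions = c(inorganic = m_ion / m_tot, organic = m_org / m_tot,
                       water = m_wat / m_tot),
    organic_breakdown = masses[cls %in% organic_classes] / m_org,
    fa_share_of_organic_pct = 100 * m_fa / m_org,
    bcl_share_of_organic_pct = 100 * masses[["BCL"]] / m_org,
    molarity = molarity,
    total_mass_amu = m_tot
  )

  structure(list(spec = spec, counts = counts, achieved = achieved),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Sea-spray aerosol composition, system", x$spec$system_id,
      sprintf("(%.0f A diameter)\n", x$spec$diameter))
  cat("  molecules:", sum(x$counts), "\n")
  cat("  mass fractions (inorganic/organic/water):",
      sprintf("%.3f", x$achieved$mass_fractions), "\n")
  cat(sprintf("  fatty-acid share of organic mass: %.1f %%\n",
              x$achieved$fa_share_of_organic_pct))
  invisible(x)
}
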