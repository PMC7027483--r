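# Tier-2 livestock GHG kernels and an annualised energy/protein-balance
# milk model (a lifetime-averaged surrogate for a daily herd simulator).
# All per-head results are kg head^-1 yr^-1; CO2-equivalents use GWP100
# factors from the emission-factor configuration.

#' Annual concentrate intake from a daily lactation ration
#'
#' Concentrate is fed only during early lactation, so the annual amount is
#' the daily ration times the feeding days (e.g. 3 kg/day over 150 days =
#' 450 kg).
#'
#' @param kg_per_day daily ration, kg DM day⁻¹ (>= 0).
#' @param lactation_days feeding days per year (<= 365).
#' @return kg head⁻¹ yr⁻¹.
#' @export
annual_concentrate <- function(kg_per_day, lactation_days = 150) {
  if (any(kg_per_day < 0)) stop("ration must be non-negative")
  if (any(lactation_days > 365)) stop("feeding days cannot exceed 365")
  kg_per_day * lactation_days
}

#' Gross energy intake of a diet
#'
#' @param diet a `diet` (named annual intakes, kg DM head⁻¹ yr⁻¹).
#' @param feeds feed table from [load_feed_table()].
#' @return MJ head⁻¹ yr⁻¹.
#' @export
gross_energy_intake <- function(diet, feeds) {
  intake <- diet$intake[diet$intake > 0]
  if (!length(intake)) return(0)
  idx <- match(names(intake), feeds$name)
  if (anyNA(idx))
    stop("no feed record for: ",
         paste(names(intake)[is.na(idx)], collapse = ", "))
  sum(intake * feeds$gross_energy_density[idx])
}

#' Intake-weighted dry-matter digestibility of a diet
#' @inheritParams gross_energy_intake
#' @return unitless fraction in \[0, 1\]; `NA` for an empty diet.
#' @export
diet_digestibility <- function(diet, feeds) {
  intake <- diet$intake[diet$intake > 0]
  if (!length(intake)) return(NA_real_)
  idx <- match(names(intake), feeds$name)
  if (anyNA(idx))
    stop("no feed record for: ",
         paste(names(intake)[is.na(idx)], collapse = ", "))
  sum(intake * feeds$dm_digestibility[idx]) / sum(intake)
}

#' Enteric fermentation methane
#'
#' Tier-2 form: a fixed fraction `ym` of gross energy is lost as CH4;
#' 55.65 MJ per kg CH4 converts energy to mass.
#'
#' @param ge gross energy intake, MJ yr⁻¹ (>= 0).
#' @param ym methane conversion factor, in (0, 0.12\].
#' @return kg CH4 yr⁻¹.
#' @export
enteric_ch4 <- function(ge, ym) {
  if (any(ge < 0)) stop("gross energy must be non-negative")
  if (any(ym <= 0 | ym > 0.12)) stop("ym must lie in (0, 0.12]")
  ge * ym / 55.65
}

#' Volatile solids excretion
#'
#' Undigested plus urinary energy, net of ash, converted back to dry
#' matter at the feed gross-energy density of 18.45 MJ/kg.
#'
#' @param ge gross energy intake, MJ yr⁻¹.
#' @param digestibility diet dry-matter digestibility fraction.
#' @param ash ash fraction of manure dry matter.
#' @param urinary urinary energy fraction of GE.
#' @return kg VS yr⁻¹.
#' @export
vs_excretion <- function(ge, digestibility, ash = 0.08, urinary = 0.04) {
  (ge * (1 - digestibility) + urinary * ge) * (1 - ash) / 18.45
}

#' Manure management methane
#'
#' `VS x B0 x 0.67 x sum_s split_s x MCF_s` — 0.67 kg/m³ is the density
#' of methane.
#'
#' @param vs_excreted kg VS yr⁻¹.
#' @param b0 maximum CH4 producing capacity, m³ CH4 (kg VS)⁻¹.
#' @param mcf_by_system named vector of methane conversion factors per
#'   manure system (fractions).
#' @param system_split named vector of manure fractions per system,
#'   summing to 1; names must match `mcf_by_system`.
#' @return kg CH4 yr⁻¹.
#' @export
manure_ch4 <- function(vs_excreted, b0, mcf_by_system, system_split) {
  if (abs(sum(system_split) - 1) > 1e-8)
    stop("manure system split must sum to 1")
  mcf <- mcf_by_system[names(system_split)]
  if (anyNA(mcf)) stop("missing MCF for a manure system in the split")
  vs_excreted * b0 * 0.67 * sum(system_split * mcf)
}

#' Nitrogen flows of a lactating cow
#'
#' Intake N from crude protein (CP/6.25), milk N from the milk protein
#' content (protein mass / 6.38), a small body-retention term, and
#' excreted N as the balance.
#'
#' @param diet a `diet`.
#' @param feeds feed table.
#' @param milk_yield kg FPCM head⁻¹ yr⁻¹.
#' @param milk_protein_pct milk protein content, %.
#' @param retention_frac fraction of N intake retained in body tissue.
#' @return list `n_intake`, `n_milk`, `n_retained`, `n_excreted`
#'   (kg N yr⁻¹).
#' @export
n_flows <- function(diet, feeds, milk_yield, milk_protein_pct = 3.3,
                    retention_frac = 0.02) {
  intake <- diet$intake[diet$intake > 0]
  n_intake <- if (!length(intake)) 0 else {
    idx <- match(names(intake), feeds$name)
    if (anyNA(idx))
      stop("no feed record for: ",
           paste(names(intake)[is.na(idx)], collapse = ", "))
    sum(intake * feeds$crude_protein[idx]) / 6.25
  }
  n_milk <- milk_yield * (milk_protein_pct / 100) / 6.38
  n_retained <- retention_frac * n_intake
  n_excreted <- n_intake - n_milk - n_retained
  if (n_excreted < -1e-9)
    stop("negative N excretion: diet protein and milk output are ",
         "inconsistent")
  list(n_intake = n_intake, n_milk = n_milk, n_retained = n_retained,
       n_excreted = max(n_excreted, 0))
}

#' Direct and indirect N2O emissions from manure and soils
#'
#' Excreted N is routed by the manure-system split: pasture-deposited N
#' is a managed-soil source (pasture emission factor), heap-stored N a
#' manure-management source. Indirect pathways are volatilisation
#' (`frac_gas x EF4`) and leaching (`frac_leach x EF5`, soils only).
#' 44/28 converts N2O-N to N2O; the GWP converts to CO2eq.
#'
#' @param n_excreted excreted N, kg N yr⁻¹.
#' @param n_fertilizer synthetic fertilizer N applied to feed crops,
#'   kg N yr⁻¹ (enters the separate fertilizer category).
#' @param factors emission-factor list from [load_emission_factors()]
#'   (mean values are used; pass overridden copies for sampling).
#' @param system_split named manure split (pasture/heap), summing to 1.
#' @return list of kg CO2eq yr⁻¹: `manure_direct`, `manure_indirect`,
#'   `soil_direct`, `soil_indirect`, `fertilizer` (direct + indirect of
#'   fertilizer N).
#' @export
n2o_emissions <- function(n_excreted, n_fertilizer, factors,
                          system_split = c(pasture = 0.7, heap = 0.3)) {
  if (abs(sum(system_split) - 1) > 1e-8)
    stop("manure system split must sum to 1")
  g <- function(nm) ef_mean(factors[[nm]])
  gwp <- g("gwp_n2o"); conv <- 44 / 28
  n_past <- n_excreted * system_split[["pasture"]]
  n_heap <- n_excreted * system_split[["heap"]]
  direct <- function(n, ef) n * ef * conv * gwp
  indirect_vol <- function(n) direct(n * g("frac_gas"), g("ef4"))
  indirect_leach <- function(n) direct(n * g("frac_leach"), g("ef5"))
  list(
    manure_direct = direct(n_heap, g("ef3_heap")),
    manure_indirect = indirect_vol(n_heap),
    soil_direct = direct(n_past, g("ef3_pasture")),
    soil_indirect = indirect_vol(n_past) + indirect_leach(n_past),
    fertilizer = direct(n_fertilizer, g("ef1")) +
      indirect_vol(n_fertilizer) + indirect_leach(n_fertilizer))
}

#' Fat-and-protein-corrected milk
#'
#' `FPCM = raw x (0.337 + 0.116 fat% + 0.06 protein%)`.
#'
#' @param raw_milk kg raw milk.
#' @param fat_pct,protein_pct milk composition, %.
#' @return kg FPCM.
#' @export
fpcm <- function(raw_milk, fat_pct = 4.0, protein_pct = 3.3) {
  raw_milk * (0.337 + 0.116 * fat_pct + 0.06 * protein_pct)
}

#' Cow life-history parameters
#'
#' @param lifetime total lifetime, years.
#' @param rearing_years years before first calving (non-productive).
#' @param lactation_length days in milk per year.
#' @param mature_weight kg live weight.
#' @param milk_fat_pct,milk_protein_pct milk composition, %.
#' @return a `cow_params` list.
#' @export
cow_params <- function(lifetime = 13, rearing_years = 3,
                       lactation_length = 305, mature_weight = 350,
                       milk_fat_pct = 4.0, milk_protein_pct = 3.3) {
  if (lifetime <= 0) stop("lifetime must be positive")
  if (lactation_length > 365) stop("lactation cannot exceed 365 days")
  structure(as.list(environment()), class = "cow_params")
}

#' Lifetime-averaged potential milk yield
#'
#' Annualised energy/protein balance: metabolisable energy is gross energy
#' times digestibility times 0.81; net energy availability uses the
#' digestible-energy-dependent conversion efficiency
#' `REM = 1.123 - 4.092e-3 DE% + 1.126e-5 DE%^2 - 25.4/DE%`; maintenance
#' is `0.322 W^0.75` MJ NE/day (a lifetime-average coefficient spanning
#' lactating and dry periods) with a 5% pregnancy overhead; the residual
#' divided by the energy content of milk (`1.47 + 0.40 fat%` MJ/kg) gives
#' energy-limited milk. Protein-limited milk converts digestible crude
#' protein (at 64% marginal efficiency, net of a maintenance allowance of
#' 1 g per kg metabolic weight per day) into milk protein. The minimum of the two, scaled by the productive fraction
#' of the lifetime, is the lifetime-averaged annual yield. When a
#' calibration table derived from a reference run is supplied, the matching
#' fixture yield overrides the surrogate, so downstream accounting is exact
#' even where the surrogate differs.
#'
#' @param diet a `diet`.
#' @param feeds feed table.
#' @param cow a [cow_params()].
#' @param calibration optional data.frame with columns `lps`, `scenario`,
#'   `milk_fpcm` (e.g. the packaged diet table): matching rows override
#'   the surrogate.
#' @return kg FPCM head⁻¹ yr⁻¹ (0 with a warning for sub-maintenance
#'   diets).
#' @export
lifetime_milk <- function(diet, feeds, cow = cow_params(),
                          calibration = NULL) {
  if (!is.null(calibration)) {
    hit <- calibration[calibration$lps == diet$lps &
                         calibration$scenario == diet$scenario, ,
                       drop = FALSE]
    if (nrow(hit)) return(hit$milk_fpcm[1])
  }
  ge <- gross_energy_intake(diet, feeds)
  if (ge <= 0) return(0)
  dig <- diet_digestibility(diet, feeds)
  de_pct <- dig * 100
  rem <- 1.123 - 4.092e-3 * de_pct + 1.126e-5 * de_pct^2 - 25.4 / de_pct
  me <- ge * dig * 0.81
  ne_avail <- me * rem
  ne_maint <- 0.322 * cow$mature_weight^0.75 * 365 * 1.05
  el <- 1.47 + 0.40 * cow$milk_fat_pct
  milk_energy <- (ne_avail - ne_maint) / el
  if (milk_energy <= 0) {
    warning("diet does not cover maintenance energy; milk set to 0")
    return(0)
  }
  intake <- diet$intake[diet$intake > 0]
  idx <- match(names(intake), feeds$name)
  dcp <- sum(intake * feeds$crude_protein[idx] *
               feeds$dm_digestibility[idx])
  maint_protein <- 1.0 * cow$mature_weight^0.75 * 365 / 1000
  milk_protein <- max((dcp * 0.64 - maint_protein), 0) /
    (cow$milk_protein_pct / 100)
  productive <- (cow$lifetime - cow$rearing_years) / cow$lifetime
  min(milk_energy, milk_protein) * productive
}

#' GHG emission intensity
#'
#' @param total_emissions kg CO2eq.
#' @param milk kg FPCM (> 0).
#' @return kg CO2eq per kg FPCM.
#' @export
emission_intensity <- function(total_emissions, milk) {
  if (any(milk <= 0)) stop("milk must be positive")
  total_emissions / milk
}

#' Per-head emission breakdown for one diet
#'
#' Runs every Tier-2 kernel for one LPS x scenario diet and returns the
#' category breakdown in kg CO2eq head⁻¹ yr⁻¹. LUC and concentrate
#' production are accounted at the herd/landscape level, not here; their
#' slots are zero in the per-head breakdown.
#'
#' @param diet a `diet`.
#' @param feeds feed table.
#' @param factors emission-factor list (means used).
#' @param cow a [cow_params()].
#' @param milk optional milk yield override (kg FPCM head⁻¹ yr⁻¹); by
#'   default [lifetime_milk()] with the diet table as calibration is the
#'   caller's responsibility.
#' @param n_fertilizer_per_head fertilizer N attributable to this cow's
#'   feed, kg N yr⁻¹.
#' @return an `emission_breakdown` (named numeric vector, kg CO2eq
#'   head⁻¹ yr⁻¹) with a `milk` attribute.
#' @export
cow_emissions <- function(diet, feeds, factors, cow = cow_params(),
                          milk = NULL, n_fertilizer_per_head = 0) {
  g <- function(nm) ef_mean(factors[[nm]])
  split <- unlist(factors$manure_split[[diet$scenario]] %||%
                    factors$manure_split[["baseline"]])
  ge <- gross_energy_intake(diet, feeds)
  dig <- diet_digestibility(diet, feeds)
  if (is.null(milk))
    milk <- lifetime_milk(diet, feeds, cow)
  ent <- enteric_ch4(ge, g("ym")) * g("gwp_ch4")
  vs <- vs_excretion(ge, dig, ash = g("ash_fraction"),
                     urinary = g("urinary_energy_fraction"))
  man_ch4 <- manure_ch4(vs, g("b0"),
                        c(pasture = g("mcf_pasture"),
                          heap = g("mcf_heap")), split) * g("gwp_ch4")
  nf <- n_flows(diet, feeds, milk,
                milk_protein_pct = g("milk_protein_pct"),
                retention_frac = g("n_retention_fraction"))
  n2o <- n2o_emissions(nf$n_excreted, n_fertilizer_per_head, factors,
                       system_split = split)
  out <- c(enteric_ch4 = ent, manure_ch4 = man_ch4,
           manure_n2o_direct = n2o$manure_direct,
           manure_n2o_indirect = n2o$manure_indirect,
           soil_n2o_direct = n2o$soil_direct,
           soil_n2o_indirect = n2o$soil_indirect,
           fertilizer_n2o = n2o$fertilizer,
           luc_co2 = 0, concentrate_co2e = 0)
  structure(out, milk = milk, class = c("emission_breakdown", "numeric"))
}

#' @export
print.emission_breakdown <- function(x, ...) {
  cat("<emission_breakdown> kg CO2eq head-1 yr-1\n")
  print(round(unclass(x), 2))
  cat(sprintf("  total: %.1f   milk: %.0f kg FPCM\n", sum(x),
              attr(x, "milk") %||% NA))
  invisible(x)
}

#' One-at-a-time Latin-hypercube uncertainty of an emission model
#'
#' Each ranged factor is perturbed on its own: in `baseline_full` mode its
#' range is sampled with a one-dimensional Latin hypercube (uniform over
#' \[min, max\]) while all other factors stay at their means; in
#' `scenario_oat` mode the model is evaluated only at the minimum and
#' maximum of each range (half the spread is taken as that factor's SD).
#' Per-factor SDs are combined in quadrature into the reported overall SD.
#'
#' @param f function taking an emission-factor list and returning a named
#'   numeric vector (e.g. category totals).
#' @param factors emission-factor list; entries with `(min, mean, max)`
#'   ranges are sampled.
#' @param n_samples LHS points per factor (>= 2), `baseline_full` mode.
#' @param mode `"baseline_full"` or `"scenario_oat"`.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return list: `mean` (model at factor means), `sd` (quadrature-combined
#'   per-output SD), `per_factor_sd` (matrix factor x output).
#' @export
lhs_uncertainty <- function(f, factors, n_samples = 50,
                            mode = c("baseline_full", "scenario_oat"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (n_samples < 2) stop("n_samples must be >= 2")
  ranged <- names(Filter(function(x) is.list(x) &&
                           all(c("min", "mean", "max") %in% names(x)),
                         factors))
  centre <- f(factors)
  per <- matrix(0, length(ranged), length(centre),
                dimnames = list(ranged, names(centre)))
  set.seed(seed)
  for (nm in ranged) {
    r <- factors[[nm]]
    if (r$max - r$min <= 0) next   # degenerate range: zero variance
    vals <- if (mode == "baseline_full") {
      as.numeric(stats::qunif(lhs::randomLHS(n_samples, 1), r$min, r$max))
    } else c(r$min, r$max)
    runs <- vapply(vals, function(v) {
      fx <- factors
      fx[[nm]]$mean <- v
      f(fx)
    }, numeric(length(centre)))
    runs <- matrix(runs, ncol = length(vals))
    per[nm, ] <- if (mode == "baseline_full") {
      apply(runs, 1, stats::sd)
    } else abs(runs[, 2] - runs[, 1]) / 2
  }
  list(mean = centre, sd = sqrt(colSums(per^2)), per_factor_sd = per)
}
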