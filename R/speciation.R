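#' Ionic strength of a solution
#'
#' Computes \eqn{I = \tfrac12 \sum_i c_i z_i^2} over all charged species.
#' Molar concentrations are treated as molal (dilute approximation).
#'
#' @param conc Named numeric vector of species concentrations (mol/L).
#' @param charge Named integer vector of species charges; every species in
#'   `conc` must have a charge.
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength(c(Na = 0.01, Cl = 0.01), c(Na = 1, Cl = -1))
#' @export
ionic_strength <- function(conc, charge) {
  if (length(conc) == 0) return(0)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  missing <- setdiff(names(conc), names(charge))
  if (length(missing)) {
    stop("missing charge for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- charge[names(conc)]
  0.5 * sum(conc * z^2)
}

#' Davies single-ion activity coefficient
#'
#' \eqn{\log_{10}\gamma = -A z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)} with
#' `A = 0.509` (25 degC). Neutral species get \eqn{\gamma = 1}. The Davies
#' equation is reliable to roughly I = 0.5 mol/L; beyond that it is still
#' returned but should be treated as an extrapolation.
#'
#' @param z Integer charge (vectorized).
#' @param I Ionic strength, mol/L (scalar, must be >= 0).
#' @param A Debye-Huckel slope; the 25 degC value is the default.
#' @return Activity coefficient(s).
#' @examples
#' davies_gamma(2, 0.1)
#' @export
davies_gamma <- function(z, I, A = 0.509) {
  if (length(I) != 1 || is.na(I) || I < 0) {
    stop("ionic strength must be a single non-negative number", call. = FALSE)
  }
  sqI <- sqrt(I)
  10^(-A * z^2 * (sqI / (1 + sqI) - 0.3 * I))
}

#' Load a thermodynamic constant set
#'
#' Reads a YAML file declaring component charges and complex definitions
#' (name, stoichiometry over components plus optionally `H`, `log10_K` at
#' 25 degC in the association convention on activities, and charge). The
#' packaged default covers 1:1 and 1:2 metal-sulfate and metal-chloride
#' complexes plus arsenic protonation states, with generic compilation
#' constants (see the file header).
#'
#' @param path YAML file; defaults to the packaged constant set.
#' @return A list with `components` (named charge vector) and `complexes`
#'   (list of complex definitions).
#' @export
load_thermo <- function(path = amdtox_extdata("thermo_default.yaml")) {
  raw <- yaml::read_yaml(path)
  comps <- unlist(raw$components)
  cplx <- lapply(raw$complexes, function(cp) {
    cp$stoichiometry <- unlist(cp$stoichiometry)
    cp
  })
  validate_complexes(cplx, names(comps))
  list(components = comps, complexes = cplx)
}

validate_complexes <- function(complexes, component_names) {
  for (cp in complexes) {
    if (is.null(cp$name) || is.null(cp$stoichiometry) || is.null(cp$log10_K)) {
      stop("complex definition needs name, stoichiometry and log10_K",
           call. = FALSE)
    }
    refs <- setdiff(names(cp$stoichiometry), c(component_names, "H"))
    if (length(refs)) {
      stop("complex ", cp$name, " references undeclared component(s): ",
           paste(refs, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Table 2-style species label for a free component, e.g. Al -> "Al3+",
# Fe(II) -> "Fe2+", SO4 -> "SO42-"; neutral components keep their name.
free_species_label <- function(component, charge) {
  base <- sub("\\(.*\\)$", "", component)
  if (charge > 0) paste0(base, if (charge > 1) charge else "", "+")
  else if (charge < 0) paste0(base, if (charge < -1) -charge else "", "-")
  else component
}

#' Solve the equilibrium speciation of a component set
#'
#' Distributes each dissolved component total over its free form and the
#' declared complexes so that mass action (on activities) and mass balance
#' hold simultaneously, with ionic strength and Davies activity coefficients
#' recomputed each iteration until self-consistent. pH is a fixed input
#' (proton activity \eqn{10^{-\mathrm{pH}}}); there is no proton mass
#' balance, matching the use of measured pH values. Redox couples are taken
#' as separate components (e.g. `Fe(II)` and `Fe(III)`), i.e. redox
#' partitioning is an input, not solved.
#'
#' The solver is a damped fixed-point iteration on the free component
#' concentrations: each sweep multiplies the free concentration by
#' `(total / implied_total)^damping`, which is robust for the small
#' component sets used here.
#'
#' @param totals Named numeric vector of total dissolved concentrations
#'   (mol/L) per component.
#' @param pH Fixed pH of the water.
#' @param thermo Constant set from [load_thermo()]; complexes referencing
#'   components absent from `totals` are dropped.
#' @param activities If `FALSE`, all activity coefficients are fixed at 1
#'   (useful for closed-form cross-checks).
#' @param damping Damping exponent in (0, 1].
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the worst relative mass-balance
#'   residual (and on ionic-strength drift).
#' @return An object of class `speciation_result`: a list with `free_conc`,
#'   `species_conc`, `fractions` (per metal, percentages summing to 100),
#'   `gamma`, `ionic_strength`, `free_activity`, `pH`, `iterations`.
#' @examples
#' th <- load_thermo()
#' res <- solve_speciation(c(Cu = 1e-4, SO4 = 0.02), pH = 3, thermo = th)
#' res$fractions$Cu
#' @export
solve_speciation <- function(totals, pH, thermo = load_thermo(),
                             activities = TRUE, damping = 0.5,
                             max_iter = 500L, tol = 1e-10) {
  stopifnot(is.numeric(totals), !is.null(names(totals)))
  if (any(totals < 0)) stop("totals must be >= 0", call. = FALSE)
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)", call. = FALSE)

  comp_charge <- thermo$components
  unknown <- setdiff(names(totals), names(comp_charge))
  if (length(unknown)) {
    stop("no charge declared for component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  comps <- names(totals)
  zc <- comp_charge[comps]

  # keep complexes whose every non-H component is present
  cplx <- Filter(function(cp) {
    all(setdiff(names(cp$stoichiometry), "H") %in% comps)
  }, thermo$complexes)
  ns <- length(cplx)
  sp_names <- vapply(cplx, `[[`, "", "name")
  sp_charge <- vapply(cplx, function(cp) as.numeric(cp$charge %||% 0), 0)
  logK <- vapply(cplx, `[[`, 0, "log10_K")
  # stoichiometry matrix: species x components, plus H column
  S <- matrix(0, nrow = ns, ncol = length(comps),
              dimnames = list(sp_names, comps))
  nu_H <- numeric(ns)
  for (i in seq_len(ns)) {
    st <- cplx[[i]]$stoichiometry
    for (nm in names(st)) {
      if (nm == "H") nu_H[i] <- st[[nm]] else S[i, nm] <- st[[nm]]
    }
  }

  aH <- 10^(-pH)
  free <- pmax(totals / 2, 1e-30)
  free[totals == 0] <- 0
  gamma_c <- rep(1, length(comps))
  gamma_s <- rep(1, ns)
  I <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # mass action on activities
    if (ns > 0) {
      log_sp <- logK + as.vector(S %*% log10(pmax(gamma_c * free, 1e-300))) +
        nu_H * log10(aH) - log10(gamma_s)
      sp <- setNames(10^log_sp, sp_names)
      sp[rowSums(S[, totals == 0, drop = FALSE] != 0) > 0] <- 0
      implied <- free + as.vector(t(S) %*% sp)
    } else {
      sp <- setNames(numeric(0), character(0))
      implied <- free
    }
    resid <- max(abs(implied - totals) / pmax(totals, 1e-30))

    if (activities) {
      all_conc <- c(setNames(free, comps), sp, H = aH)
      all_z <- c(setNames(zc, comps), setNames(sp_charge, sp_names), H = 1)
      I_new <- ionic_strength(all_conc, all_z)
    } else {
      I_new <- 0
    }
    dI <- abs(I_new - I) / max(I_new, 1e-12)
    I <- I_new
    gamma_c <- davies_gamma(zc, I)
    gamma_s <- if (ns > 0) davies_gamma(sp_charge, I) else numeric(0)
    if (!activities) {
      gamma_c[] <- 1
      gamma_s[] <- 1
    }

    if (resid < tol && dI < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "speciation did not converge in %d iterations (worst relative mass-balance residual %.3g)",
        max_iter, resid), call. = FALSE)
    }
    upd <- totals > 0
    # all component stoichiometries are positive, so the free form can never
    # exceed the total; clamping keeps the activity feedback from diverging
    free[upd] <- pmin(
      free[upd] * (totals[upd] / pmax(implied[upd], 1e-300))^damping,
      totals[upd])
  }

  names(sp) <- sp_names
  names(free) <- comps
  names(gamma_c) <- comps

  # per-metal fractions: free form plus every complex containing the metal,
  # weighted by stoichiometry, as % of the declared total
  fractions <- list()
  for (cc in comps[totals > 0]) {
    contrib <- c(free[[cc]])
    names(contrib) <- free_species_label(cc, zc[[cc]])
    if (ns > 0) {
      has <- S[, cc] != 0
      if (any(has)) {
        contrib <- c(contrib, setNames(S[has, cc] * sp[has], sp_names[has]))
      }
    }
    fractions[[cc]] <- 100 * contrib / totals[[cc]]
  }

  structure(list(
    free_conc = free,
    species_conc = sp,
    fractions = fractions,
    gamma = c(setNames(gamma_c, comps),
              if (ns > 0) setNames(gamma_s, sp_names)),
    ionic_strength = I,
    free_activity = setNames(gamma_c * free, comps),
    pH = pH,
    iterations = iter
  ), class = "speciation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.speciation_result <- function(x, ...) {
  cat("Equilibrium speciation (pH ", x$pH, ", I = ",
      signif(x$ionic_strength, 4), " mol/L, ", x$iterations,
      " iterations)\n", sep = "")
  tab <- free_cation_table(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarize free-cation fractions and predominant species
#'
#' For each component of a [solve_speciation()] result, reports the
#' free-ion percentage, the predominant species (the largest single
#' fraction; ties broken alphabetically by species label), and the free-ion
#' activity.
#'
#' @param result A `speciation_result`.
#' @return A data frame with `component`, `free_percent`,
#'   `predominant_species`, `predominant_percent`, `free_activity`.
#' @export
free_cation_table <- function(result) {
  stopifnot(inherits(result, "speciation_result"))
  comps <- names(result$fractions)
  rows <- lapply(comps, function(cc) {
    fr <- result$fractions[[cc]]
    ord <- order(-fr, names(fr))
    data.frame(
      component = cc,
      free_percent = unname(fr[[1]]),
      predominant_species = names(fr)[ord[1]],
      predominant_percent = unname(fr[ord[1]]),
      free_activity = unname(result$free_activity[[cc]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run speciation for each lake layer
#'
#' Convenience wrapper: converts a per-layer chemistry table from ug/L to
#' mol/L, pulls the layer pH from the layer-properties table, and solves
#' each layer with [solve_speciation()].
#'
#' @param chem Data frame with `layer`, `element`, `conc_ug_per_L`.
#' @param properties Data frame with `layer` and `pH`.
#' @param thermo Constant set from [load_thermo()].
#' @param ... Passed on to [solve_speciation()].
#' @return Named list of `speciation_result`, one per layer.
#' @export
speciate_layers <- function(chem, properties = load_cm_layer_properties(),
                            thermo = load_thermo(), ...) {
  layers <- unique(chem$layer)
  out <- list()
  for (ly in layers) {
    sub <- chem[chem$layer == ly, ]
    keep <- sub$element %in% names(thermo$components)
    totals <- setNames(
      ug_per_L_to_mol_per_L(sub$conc_ug_per_L[keep], sub$element[keep]),
      sub$element[keep])
    pH <- properties$pH[properties$layer == ly]
    if (length(pH) != 1) stop("no pH for layer ", ly, call. = FALSE)
    out[[ly]] <- solve_speciation(totals, pH = pH, thermo = thermo, ...)
  }
  out
}

# molar masses (g/mol) of the dissolved entities the chemistry tables use;
# SO4 and Cl as the anion, As as elemental As (concentrations reported as As)
MOLAR_MASS <- c(
  Al = 26.98, Fe = 55.85, "Fe(II)" = 55.85, "Fe(III)" = 55.85,
  Cu = 63.55, Zn = 65.38, Mn = 54.94, Ni = 58.69, Co = 58.93, Cd = 112.41,
  As = 74.92, "As(III)" = 74.92, "As(V)" = 74.92,
  SO4 = 96.06, Cl = 35.45
)

#' Convert ug/L to mol/L for the supported elements
#'
#' @param x Concentrations in ug/L.
#' @param element Element labels (redox-state suffixes allowed).
#' @return Concentrations in mol/L.
#' @export
ug_per_L_to_mol_per_L <- function(x, element) {
  mm <- MOLAR_MASS[element]
  if (anyNA(mm)) {
    stop("no molar mass for: ",
         paste(unique(element[is.na(mm)]), collapse = ", "), call. = FALSE)
  }
  unname(x * 1e-6 / mm)
}
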