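#' Isotope-dilution inversion of erythrocyte iron patterns
#'
#' Functions that turn measured erythrocyte isotope patterns into per-tracer
#' incorporated iron and fractional iron absorption (FIA): anthropometric
#' blood-volume estimation, circulating-iron bookkeeping, the constrained
#' least-squares mixing-model solver, and the trial-level driver that applies
#' them to every participant of a cross-over study.
#'
#' @name tracer_core
NULL

#' Absorption model configuration
#'
#' @param incorporation_factor fraction of absorbed iron assumed to appear in
#'   circulating erythrocytes ~14 days after dosing. Default 0.80, the
#'   standard assumption of the erythrocyte-incorporation method.
#' @param fe_per_hb mg iron per g haemoglobin (haemoglobin iron
#'   stoichiometry). Default 3.47.
#' @param bv_formula named blood-volume convention, see [blood_volume()].
#' @return a list of class `absorption_config`.
#' @export
absorption_config <- function(incorporation_factor = 0.80,
                              fe_per_hb = 3.47,
                              bv_formula = "nadler_female") {
  if (!(incorporation_factor > 0 && incorporation_factor <= 1)) {
    stop("incorporation_factor must be in (0, 1]")
  }
  if (fe_per_hb <= 0) stop("fe_per_hb must be positive")
  structure(list(incorporation_factor = incorporation_factor,
                 fe_per_hb = fe_per_hb,
                 bv_formula = bv_formula),
            class = "absorption_config")
}

#' Blood volume from height and weight
#'
#' Height--weight regression estimate of total blood volume. The default
#' convention is the adult-female regression
#' `BV(L) = 0.3561 H(m)^3 + 0.03308 W(kg) + 0.1833`; the corresponding male
#' regression is selectable by name.
#'
#' @param height_cm standing height in cm.
#' @param weight_kg body weight in kg.
#' @param formula `"nadler_female"` (default) or `"nadler_male"`.
#' @return blood volume in litres.
#' @export
#' @examples
#' blood_volume(160, 55) # 3.461 L
blood_volume <- function(height_cm, weight_kg, formula = "nadler_female") {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  h_m <- height_cm / 100
  switch(formula,
    nadler_female = 0.3561 * h_m^3 + 0.03308 * weight_kg + 0.1833,
    nadler_male   = 0.3669 * h_m^3 + 0.03219 * weight_kg + 0.6041,
    stop(sprintf("unknown blood-volume formula '%s'", formula))
  )
}

#' Circulating iron mass
#'
#' Total iron bound in circulating haemoglobin, from blood volume, haemoglobin
#' concentration, and the haemoglobin iron stoichiometry.
#'
#' @param bv_l blood volume in litres.
#' @param hb_g_l haemoglobin concentration in g/L.
#' @param config an [absorption_config()] supplying `fe_per_hb`.
#' @return circulating iron in mg.
#' @export
circulating_iron <- function(bv_l, hb_g_l, config = absorption_config()) {
  if (any(bv_l < 0) || any(hb_g_l < 0)) stop("bv and hb must be non-negative")
  bv_l * hb_g_l * config$fe_per_hb
}

# circulating iron in mol, converting mass with the pool pattern's molar mass
circulating_iron_mol <- function(height_cm, weight_kg, hb_g_l, pool_pattern,
                                 config = absorption_config()) {
  bv <- blood_volume(height_cm, weight_kg, config$bv_formula)
  mg <- circulating_iron(bv, hb_g_l, config)
  mg / 1000 / pattern_molar_mass(pool_pattern)
}

#' Solve the tracer mixing model for incorporated moles
#'
#' Inverts the isotopic-dilution mixing model
#' `measured ~ (N * baseline + sum_i q_i * tracer_i) / (N + sum_i q_i)` with
#' `N + sum_i q_i = total_mol` for the incorporated moles `q_i` of each
#' enriched tracer. The model is linear in `q` once the pool size is fixed and
#' is solved by least squares with non-negativity enforced by active-set
#' clipping and refit (a small negative solution is measurement noise, not
#' physics).
#'
#' Two equivalent formulations are available: `space = "ratio"` (default)
#' works on the three isotope ratios to 56Fe, matching the quantity on which
#' multi-collector ICP-MS noise acts; `space = "abundance"` works on the four
#' fractional abundances directly. Noiseless data give identical answers.
#'
#' @param measured,baseline `iso_pattern`s for the post- and pre-dosing pool.
#' @param tracer_patterns named list of `iso_pattern`s, one per dosed tracer
#'   (1--3 tracers).
#' @param total_mol total circulating iron at the measurement day, mol.
#' @param space `"ratio"` or `"abundance"`.
#' @param nonneg clip negative solutions to zero and refit (default TRUE).
#' @param cond_max maximum acceptable condition number of the design matrix.
#' @return list with `q_mol` (named, mol per tracer), `residual` (norm of the
#'   model residual) and `kappa` (condition number).
#' @export
solve_tracer_increments <- function(measured, baseline, tracer_patterns,
                                    total_mol, space = c("ratio", "abundance"),
                                    nonneg = TRUE, cond_max = 1e10) {
  space <- match.arg(space)
  if (total_mol <= 0) stop("total_mol must be positive")
  if (length(tracer_patterns) < 1 || length(tracer_patterns) > 3) {
    stop("between 1 and 3 tracers are supported")
  }
  if (is.null(names(tracer_patterns)) || any(names(tracer_patterns) == "")) {
    stop("tracer_patterns must be a named list")
  }
  m <- unclass(as_iso_pattern(measured))
  b <- unclass(as_iso_pattern(baseline))
  tr <- lapply(tracer_patterns, function(p) unclass(as_iso_pattern(p)))

  if (space == "ratio") {
    r <- pattern_to_ratios(measured)
    ks <- c("a54", "a57", "a58")
    A <- vapply(tr, function(t) {
      r * (t[["a56"]] - b[["a56"]]) - (t[ks] - b[ks])
    }, numeric(3))
    A <- matrix(A, nrow = 3, dimnames = list(ks, names(tr)))
    y <- total_mol * (b[ks] - r * b[["a56"]])
  } else {
    ks <- .ISO_NAMES
    A <- vapply(tr, function(t) t[ks] - b[ks], numeric(4))
    A <- matrix(A, nrow = 4, dimnames = list(ks, names(tr)))
    y <- total_mol * (m[ks] - b[ks])
  }

  s <- svd(A)$d
  kap <- if (min(s) <= 0) Inf else max(s) / min(s)
  if (!is.finite(kap) || kap > cond_max) {
    stop(sprintf(
      "mixing system is ill-conditioned (condition number %.3g): tracer patterns not distinguishable from baseline", kap))
  }

  q <- .lsq_nonneg(A, y, nonneg = nonneg)
  if (all(q < 0)) stop("mixing model has a negative-only solution")
  res <- sqrt(sum((A %*% q - y)^2))
  list(q_mol = stats::setNames(as.numeric(q), colnames(A)),
       residual = res, kappa = kap)
}

# least squares with optional active-set non-negativity (clip worst, refit)
.lsq_nonneg <- function(A, y, nonneg = TRUE, tol = 0) {
  solve_ls <- function(Asub) qr.coef(qr(Asub), y)
  active <- seq_len(ncol(A))
  q <- rep(0, ncol(A))
  repeat {
    qa <- solve_ls(A[, active, drop = FALSE])
    if (!nonneg || all(qa >= tol) || length(active) == 1) {
      q[active] <- pmax(qa, if (nonneg) 0 else -Inf)
      break
    }
    drop_i <- active[which.min(qa)]
    active <- setdiff(active, drop_i)
  }
  q
}

#' Fractional absorption from an incorporated-tracer increment
#'
#' `FIA = q / (F * dose_mol)` where `F` is the erythrocyte incorporation
#' factor and `dose_mol` the administered tracer in moles
#' (`fe_mass_mg / (1000 * molar mass of the tracer pattern)`). A value above 1
#' is physically impossible and is flagged, never clipped: it is evidence of a
#' mass-balance or model failure that must stay visible.
#'
#' @param q_mol incorporated tracer, mol.
#' @param fe_mass_mg administered elemental iron, mg (study dose 4.0).
#' @param tracer_pattern `iso_pattern` of the administered tracer.
#' @param config an [absorption_config()].
#' @return list with `fia` and logical `flag_gt1`.
#' @export
fia_from_increment <- function(q_mol, fe_mass_mg, tracer_pattern,
                               config = absorption_config()) {
  if (q_mol < 0) stop("q_mol must be non-negative")
  if (fe_mass_mg <= 0) stop("dose mass must be positive")
  dose_mol <- fe_mass_mg / (1000 * pattern_molar_mass(tracer_pattern))
  fia <- q_mol / (config$incorporation_factor * dose_mol)
  list(fia = fia, flag_gt1 = fia > 1)
}

#' Process a complete cross-over trial into absorption records
#'
#' Applies the isotope-dilution inversion to every participant of the
#' two-phase, three-tracer cross-over design. Phase-1 FIA comes from the
#' day-19 pattern against the day-1 baseline and the phase-1 doses; phase-2
#' FIA from the day-37 pattern against the day-19 baseline (sequential
#' baselining) and the phase-2 doses. Circulating iron is evaluated with the
#' participant's anthropometry and haemoglobin. Duplicate measurement rows for
#' the same participant and day are averaged before inversion. Participants
#' missing a sampling day are skipped with a logged reason (attribute
#' `"skipped"` of the result).
#'
#' @param measurements data.frame with columns `participant_id`, `day`,
#'   `a54`, `a56`, `a57`, `a58` (sampling days 1, 19, 37).
#' @param design cross-over design as from [assign_crossover_design()].
#' @param cohort participant table with `participant_id`, `height_cm`,
#'   `weight_kg`, `hb_g_l`.
#' @param config an [absorption_config()].
#' @param tracer_patterns named list of tracer `iso_pattern`s.
#' @param fe_mass_mg elemental iron per dose, mg.
#' @param space solver formulation passed to [solve_tracer_increments()].
#' @return data.frame of absorption records (`participant_id`, `condition_id`,
#'   `compound`, `matrix`, `tracer`, `phase`, `fia`, `q_mol`, `flag_gt1`),
#'   6 rows per complete participant, with attribute `"skipped"` listing
#'   participant/reason pairs.
#' @export
process_trial <- function(measurements, design, cohort,
                          config = absorption_config(),
                          tracer_patterns = default_tracer_patterns(),
                          fe_mass_mg = 4.0, space = "ratio") {
  need <- c("participant_id", "day", .ISO_NAMES)
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  # average duplicates (patterns measured in duplicate are averaged)
  measurements <- stats::aggregate(
    measurements[.ISO_NAMES],
    by = measurements[c("participant_id", "day")], FUN = mean)

  records <- list()
  skipped <- list()
  for (pid in unique(cohort$participant_id)) {
    pm <- measurements[measurements$participant_id == pid, ]
    pat <- function(d) {
      row <- pm[pm$day == d, ]
      if (nrow(row) != 1) return(NULL)
      v <- as.numeric(row[.ISO_NAMES])
      iso_pattern(v[1], v[2], v[3], v[4], tol = 1e-6)
    }
    pdes <- design[design$participant_id == pid, ]
    who <- cohort[cohort$participant_id == pid, ]
    base_days <- c(`1` = 1, `2` = 19)
    draw_days <- c(`1` = 19, `2` = 37)
    for (phase in 1:2) {
      baseline <- pat(base_days[[phase]])
      measured <- pat(draw_days[[phase]])
      if (is.null(baseline) || is.null(measured)) {
        skipped[[length(skipped) + 1]] <- data.frame(
          participant_id = pid, phase = phase,
          reason = sprintf("missing sampling day %d or %d",
                           base_days[[phase]], draw_days[[phase]]))
        next
      }
      ph <- pdes[pdes$phase == phase, ]
      trs <- tracer_patterns[ph$tracer]
      total_mol <- circulating_iron_mol(who$height_cm, who$weight_kg,
                                        who$hb_g_l, baseline, config)
      sol <- solve_tracer_increments(measured, baseline, trs, total_mol,
                                     space = space)
      for (i in seq_len(nrow(ph))) {
        lab <- ph$tracer[i]
        f <- fia_from_increment(sol$q_mol[[lab]], fe_mass_mg,
                                tracer_patterns[[lab]], config)
        records[[length(records) + 1]] <- data.frame(
          participant_id = pid, condition_id = ph$condition_id[i],
          compound = ph$compound[i], matrix = ph$matrix[i],
          tracer = lab, phase = phase,
          fia = f$fia, q_mol = sol$q_mol[[lab]], flag_gt1 = f$flag_gt1)
      }
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(participant_id = character(), condition_id = character(),
               compound = character(), matrix = character(),
               tracer = character(), phase = integer(), fia = numeric(),
               q_mol = numeric(), flag_gt1 = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Screening eligibility criteria
#'
#' Thresholds applied at screening: serum ferritin below `sf_max` (iron
#' stores low enough to benefit), haemoglobin at or above `hb_min` (not
#' anaemic), BMI and weight limits reducing inter-individual variation in iron
#' kinetics and per-mass dosing, adult non-elderly age range, and CRP at or
#' below `crp_max` (no acute inflammation, which suppresses absorption).
#'
#' @param sf_max serum ferritin exclusive upper bound, ug/L.
#' @param hb_min haemoglobin inclusive lower bound, g/L.
#' @param bmi_range inclusive BMI range, kg/m^2.
#' @param weight_max exclusive weight upper bound, kg.
#' @param age_range inclusive age range, years.
#' @param crp_max inclusive CRP upper bound, mg/L.
#' @return list of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(sf_max = 50, hb_min = 120,
                                 bmi_range = c(18.5, 24.9), weight_max = 70,
                                 age_range = c(18, 45), crp_max = 5) {
  stopifnot(bmi_range[1] < bmi_range[2], age_range[1] < age_range[2],
            is.finite(sf_max), is.finite(hb_min), is.finite(weight_max),
            is.finite(crp_max))
  structure(list(sf_max = sf_max, hb_min = hb_min, bmi_range = bmi_range,
                 weight_max = weight_max, age_range = age_range,
                 crp_max = crp_max),
            class = "eligibility_criteria")
}

#' Screen one participant record for eligibility
#'
#' @param record list or one-row data.frame with `sf_ug_l`, `hb_g_l`,
#'   `height_cm`, `weight_kg`, `age_y`, `crp_mg_l`.
#' @param criteria an [eligibility_criteria()].
#' @return list with logical `eligible` and character `reasons` naming every
#'   failed rule (empty when eligible).
#' @export
check_eligibility <- function(record, criteria = eligibility_criteria()) {
  need <- c("sf_ug_l", "hb_g_l", "height_cm", "weight_kg", "age_y", "crp_mg_l")
  missing_f <- need[!need %in% names(record)]
  if (length(missing_f)) {
    stop("record missing fields: ", paste(missing_f, collapse = ", "))
  }
  bmi <- record$weight_kg / (record$height_cm / 100)^2
  reasons <- character()
  if (!(record$sf_ug_l < criteria$sf_max)) reasons <- c(reasons, "SF")
  if (!(record$hb_g_l >= criteria$hb_min)) reasons <- c(reasons, "anaemia")
  if (!(bmi >= criteria$bmi_range[1] && bmi <= criteria$bmi_range[2])) {
    reasons <- c(reasons, "BMI")
  }
  if (!(record$weight_kg < criteria$weight_max)) reasons <- c(reasons, "weight")
  if (!(record$age_y >= criteria$age_range[1] &&
        record$age_y <= criteria$age_range[2])) {
    reasons <- c(reasons, "age")
  }
  if (!(record$crp_mg_l <= criteria$crp_max)) {
    reasons <- c(reasons, "inflammation")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}
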